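#' Breakpoint-anchored match of a deletion to an intron
#'
#' A deletion supports a processed pseudogene only when *both* of its
#' breakpoints fall within `tol` bp of the corresponding intron boundary —
#' the signature left by exon-junction-spanning reads of the intronless copy.
#' Mere overlap does not count: a deletion spanning several introns is a
#' genomic deletion, not a retrocopy signature, and matches none of them.
#'
#' @param del_start,del_end deletion interval, 0-based half-open (vectorized).
#' @param intron_start,intron_end intron interval, 0-based half-open.
#' @param tol breakpoint tolerance in bp (callers place SV breakpoints
#'   imprecisely); default 10.
#' @return logical vector.
#' @export
match_deletion_to_intron <- function(del_start, del_end, intron_start, intron_end,
                                     tol = 10) {
  stopifnot(tol >= 0)
  abs(del_start - intron_start) <= tol & abs(del_end - intron_end) <= tol
}

#' Detect candidate processed pseudogenes from deletion calls
#'
#' For each (sample, gene) pair, counts the gene's introns that are
#' breakpoint-matched by at least one of the sample's deletion calls
#' ([match_deletion_to_intron()]). A gene whose intron count reaches
#' `min_matched_introns` matched introns is called `PP_present` for that
#' sample; genes with fewer introns than the threshold are `undetectable`.
#' One intronic deletion alone is a common true structural variant — multiple
#' intron-exact deletions in one gene are the pseudogene-specific signature,
#' hence the default threshold of 2.
#'
#' @param deletions tibble of deletion calls ([read_sv_deletions()] output,
#'   possibly row-bound across samples).
#' @param models a `pp_gene_models` tibble.
#' @param min_matched_introns minimum matched introns for a `PP_present`
#'   verdict (default 2).
#' @param tol breakpoint tolerance in bp (default 10).
#' @return A `pp_calls` tibble, one row per (sample, gene) with at least one
#'   matched intron: `sample_id`, `gene_id`, `n_introns_total`,
#'   `n_introns_matched`, `matched_introns` (list of intron indices),
#'   `verdict` in `PP_present` / `no_PP` / `undetectable`.
#' @export
detect_pp <- function(deletions, models, min_matched_introns = 2, tol = 10) {
  stopifnot(inherits(models, "pp_gene_models"), min_matched_introns >= 1, tol >= 0)
  if (nrow(models) == 0L) {
    warn("empty gene set: no PP calls possible")
    return(empty_pp_calls())
  }
  if (nrow(deletions) == 0L) {
    return(empty_pp_calls())
  }

  introns <- models |>
    select("gene_id", "chrom", n_introns_total = "n_introns", "introns") |>
    unnest_introns()

  hits <- introns |>
    inner_join(
      deletions |> select("sample_id", "chrom", del_start = "start", del_end = "end"),
      by = "chrom", relationship = "many-to-many"
    ) |>
    filter(match_deletion_to_intron(
      .data$del_start, .data$del_end, .data$intron_start, .data$intron_end,
      tol = tol
    )) |>
    distinct(.data$sample_id, .data$gene_id, .data$n_introns_total, .data$intron_index)

  calls <- hits |>
    group_by(.data$sample_id, .data$gene_id, .data$n_introns_total) |>
    summarise(
      n_introns_matched = dplyr::n_distinct(.data$intron_index),
      matched_introns = list(sort(unique(.data$intron_index))),
      .groups = "drop"
    ) |>
    mutate(verdict = pp_verdict(
      .data$n_introns_total, .data$n_introns_matched, min_matched_introns
    )) |>
    arrange(.data$sample_id, .data$gene_id)

  attr(calls, "min_matched_introns") <- min_matched_introns
  attr(calls, "tol") <- tol
  new_tibble_subclass(calls, "pp_calls")
}

pp_verdict <- function(n_total, n_matched, min_matched) {
  dplyr::case_when(
    n_total < min_matched ~ "undetectable",
    n_matched >= min_matched ~ "PP_present",
    .default = "no_PP"
  )
}

unnest_introns <- function(x) {
  x |>
    mutate(introns = map(.data$introns, ~ mutate(.x, intron_index = dplyr::row_number()))) |>
    unnest("introns") |>
    rename(intron_start = "start", intron_end = "end")
}

empty_pp_calls <- function() {
  new_tibble_subclass(tibble(
    sample_id = character(), gene_id = character(), n_introns_total = integer(),
    n_introns_matched = integer(), matched_introns = list(), verdict = character()
  ), "pp_calls")
}

#' Cohort presence matrix of processed-pseudogene calls
#'
#' Pivots `PP_present` verdicts into a binary sample-by-gene table. The sample
#' universe defaults to the samples seen in `calls`; pass `samples` explicitly
#' when non-carrier samples produced no calls at all (the usual case), since
#' per-gene frequencies are computed over this universe.
#'
#' @param calls a `pp_calls` tibble from [detect_pp()].
#' @param samples character vector: all samples in the cohort.
#' @param genes character vector: genes to tabulate (default: genes appearing
#'   in `calls`).
#' @return A `pp_matrix` tibble: `sample_id` plus one 0/1 integer column per
#'   gene. Summaries: [pp_frequency()], [glance()][glance.pp_matrix].
#' @export
cohort_pp_matrix <- function(calls, samples = NULL, genes = NULL) {
  stopifnot(nrow(calls) >= 0)
  samples <- samples %||% sort(unique(calls$sample_id))
  if (length(samples) == 0L) abort("no samples: pp matrix needs >= 1 sample")
  present <- calls |> filter(.data$verdict == "PP_present")
  if (anyDuplicated(present[c("sample_id", "gene_id")])) {
    warn("duplicate (sample, gene) PP calls deduplicated")
    present <- distinct(present, .data$sample_id, .data$gene_id, .keep_all = TRUE)
  }
  genes <- genes %||% sort(unique(present$gene_id))
  mat <- tibble(sample_id = samples)
  for (g in genes) {
    mat[[g]] <- as.integer(samples %in% present$sample_id[present$gene_id == g])
  }
  out <- new_tibble_subclass(mat, "pp_matrix")
  attr(out, "genes") <- genes
  out
}

pp_matrix_genes <- function(mat) {
  attr(mat, "genes") %||% setdiff(names(mat), "sample_id")
}

#' Per-gene processed-pseudogene carrier frequency
#'
#' @param mat a `pp_matrix` from [cohort_pp_matrix()].
#' @return tibble: `gene_id`, `n_carriers`, `n_samples`, `frequency` (percent
#'   of samples carrying a PP of that gene).
#' @export
pp_frequency <- function(mat) {
  stopifnot(inherits(mat, "pp_matrix"))
  genes <- pp_matrix_genes(mat)
  tibble(
    gene_id = genes,
    n_carriers = map_int(genes, ~ sum(mat[[.x]])),
    n_samples = nrow(mat)
  ) |>
    mutate(frequency = 100 * .data$n_carriers / .data$n_samples)
}

#' @describeIn pp_frequency cohort-level one-row summary: sample and gene
#'   counts, mean PPs per sample, and the percent of samples carrying at
#'   least one PP.
#' @param x a `pp_matrix`.
#' @param ... unused.
#' @export
glance.pp_matrix <- function(x, ...) {
  genes <- pp_matrix_genes(x)
  per_sample <- if (length(genes)) {
    rowSums(as.matrix(x[, genes, drop = FALSE]))
  } else {
    rep(0, nrow(x))
  }
  tibble(
    n_samples = nrow(x),
    n_genes = length(genes),
    mean_pp_per_sample = mean(per_sample),
    pct_samples_with_pp = 100 * mean(per_sample >= 1)
  )
}

#' @export
tidy.pp_matrix <- function(x, ...) {
  genes <- pp_matrix_genes(x)
  x |>
    pivot_longer(all_of(genes), names_to = "gene_id", values_to = "pp_present") |>
    as_tibble()
}

#' Compare detected PP genes with an annotated pseudogene list
#'
#' Splits the detected gene set into genes whose processed pseudogene is
#' already annotated (e.g. in GENCODE) and novel ones.
#'
#' @param detected character vector of gene ids with detected PPs.
#' @param known character vector of gene ids with annotated PPs.
#' @return one-row tibble: `n_detected`, `n_known`, `n_novel`, plus list
#'   columns `known_genes` and `novel_genes`.
#' @export
pp_novel_report <- function(detected, known) {
  detected <- unique(detected)
  overlap <- intersect(detected, unique(known))
  novel <- setdiff(detected, overlap)
  tibble(
    n_detected = length(detected),
    n_known = length(overlap),
    n_novel = length(novel),
    known_genes = list(sort(overlap)),
    novel_genes = list(sort(novel))
  )
}

#' Write a cohort PP call table and per-gene frequency summary
#'
#' @param calls a `pp_calls` tibble.
#' @param mat a `pp_matrix`.
#' @param tsv_path output TSV for per-(sample, gene) calls.
#' @param json_path optional JSON with per-gene frequencies and cohort summary.
#' @return `tsv_path`, invisibly.
#' @export
write_pp_calls <- function(calls, mat, tsv_path, json_path = NULL) {
  calls |>
    mutate(matched_introns = map_chr(.data$matched_introns, paste, collapse = ",")) |>
    readr::write_tsv(tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        per_gene = pp_frequency(mat),
        cohort = glance(mat)
      ),
      json_path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(tsv_path)
}

#' @export
print.pp_calls <- function(x, ...) {
  cat(sprintf(
    "# PP calls: %d (sample, gene) pair(s), %d PP_present\n",
    nrow(x), sum(x$verdict == "PP_present")
  ))
  NextMethod()
}
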