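#' 2x2 carrier-by-PP contingency table
#'
#' Splits the cohort, for one gene, into variant carriers / non-carriers
#' (rows) and PP carriers / non-carriers (columns). A variant whose calls are
#' pseudogene artifacts is confined to the PP-carrier column.
#'
#' @param carriers character vector of sample ids carrying the variant
#'   (non-empty).
#' @param mat a `pp_matrix` from [cohort_pp_matrix()].
#' @param gene_id the parent gene.
#' @return 2x2 integer matrix, rows `carrier` yes/no, columns `pp` yes/no;
#'   cells sum to the cohort size.
#' @export
pp_contingency <- function(carriers, mat, gene_id) {
  stopifnot(inherits(mat, "pp_matrix"))
  if (length(carriers) == 0L) abort("variant has no carriers; contingency undefined")
  if (!gene_id %in% names(mat)) abort(paste0("gene not in PP matrix: ", gene_id))
  if (nrow(mat) < 2L) abort("cohort size must be >= 2")
  unknown <- setdiff(carriers, mat$sample_id)
  if (length(unknown)) {
    abort(paste0("carrier sample(s) absent from cohort: ", paste(head(unknown, 5L), collapse = ", ")))
  }
  is_carrier <- mat$sample_id %in% carriers
  has_pp <- mat[[gene_id]] == 1L
  tab <- matrix(
    c(
      sum(is_carrier & has_pp), sum(is_carrier & !has_pp),
      sum(!is_carrier & has_pp), sum(!is_carrier & !has_pp)
    ),
    nrow = 2L, byrow = TRUE,
    dimnames = list(carrier = c("yes", "no"), pp = c("yes", "no"))
  )
  storage.mode(tab) <- "integer"
  tab
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Computes the Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margin products, and the p-value from the chi-squared
#' distribution with 1 df. The Yates continuity correction is available but
#' off by default.
#'
#' @param table 2x2 matrix of non-negative counts; both margins must be
#'   positive.
#' @param correct apply the Yates continuity correction.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chi_squared_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("need a 2x2 table")
  if (any(table < 0) || anyNA(table)) abort("cells must be non-negative counts")
  rs <- rowSums(table)
  cs <- colSums(table)
  n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    abort("zero margin: chi-squared test undefined")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  tibble::new_tibble(
    list(
      statistic = stat,
      df = 1L,
      p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
      method = if (correct) "pearson_yates" else "pearson"
    ),
    nrow = 1L
  )
}

#' Flag clinically labelled variants as likely pseudogene artifacts
#'
#' For each clinical variant, evaluates three independent criteria and flags
#' the variant `likely_pp_artifact` when all evaluable criteria hold:
#'
#' 1. **Junction proximity** — distance from the position to the nearest
#'    intron-exon junction is at most `junction_window` bp (artifact calls sit
#'    on junctions, where PP-derived junction-spanning reads disagree with
#'    the intron).
#' 2. **Cohort association** — variant carriers are enriched among PP
#'    carriers, chi-squared p-value below `alpha` with the enrichment in the
#'    PP direction.
#' 3. **Allelic balance** — mean AB across carriers at most `ab_ceiling`
#'    (PP-derived calls are diluted to ~25-33%, well below the het 50%).
#'
#' A criterion that cannot be computed (no AB data; degenerate contingency
#' margin; intron-less gene) is marked unevaluable (`NA`) and dropped from the
#' conjunction.
#'
#' @param clinical tibble of clinically labelled variants: `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `gene_id`, `label` (e.g. `P` / `LP`); see
#'   [read_clinical_variants()].
#' @param models a `pp_gene_models` tibble.
#' @param mat a `pp_matrix` over the cohort.
#' @param variants cohort small-variant observations (row-bound
#'   [read_small_variants()] output) used to find carriers and their AB.
#' @param junction_window junction-proximity window in bp (default 10,
#'   covering canonical splice regions).
#' @param ab_ceiling carrier mean-AB ceiling (default 0.40, between the
#'   PP-shifted ~25-33% and the het 50% mode).
#' @param alpha association significance level (default 0.05).
#' @param correct Yates correction for the chi-squared test (default off).
#' @param p_adjust multiple-testing adjustment across the variant list
#'   (`"none"`, default, or any [stats::p.adjust] method such as
#'   `"bonferroni"`).
#' @return A `pp_verdicts` tibble, one row per clinical variant, with each
#'   criterion reported independently plus the final `flag`.
#' @export
flag_variants <- function(clinical, models, mat, variants,
                          junction_window = 10, ab_ceiling = 0.40, alpha = 0.05,
                          correct = FALSE, p_adjust = "none") {
  stopifnot(inherits(models, "pp_gene_models"), inherits(mat, "pp_matrix"))
  clinical <- as_tibble(clinical)
  if (nrow(clinical) == 0L) {
    warn("empty clinical variant list")
  }
  obs <- variants |>
    as_tibble() |>
    filter(.data$genotype %in% c("het", "hom_alt"))
  ab_obs <- suppressWarnings(allelic_balance(obs))

  rows <- purrr::map(seq_len(nrow(clinical)), function(i) {
    cv <- clinical[i, ]
    hits <- obs |>
      filter(
        .data$chrom == cv$chrom, .data$pos == cv$pos,
        .data$ref == cv$ref, .data$alt == cv$alt
      )
    carriers <- unique(hits$sample_id)
    gi <- match(cv$gene_id, models$gene_id)
    if (is.na(gi)) abort(paste0("clinical variant in unknown gene: ", cv$gene_id))
    g <- models[gi, ]
    if (cv$pos - 1L < g$span_start || cv$pos - 1L >= g$span_end) {
      abort(sprintf("variant %s:%d outside span of gene %s", cv$chrom, cv$pos, cv$gene_id))
    }

    jd <- if (g$n_introns >= 1L) {
      nearest_junction_distance(models, cv$gene_id, cv$pos)
    } else {
      NA_integer_
    }

    has_pp_col <- cv$gene_id %in% names(mat)
    in_pp <- if (has_pp_col) mat$sample_id[mat[[cv$gene_id]] == 1L] else character(0)
    n_with <- sum(carriers %in% in_pp)
    n_without <- length(carriers) - n_with

    assoc <- tryCatch(
      {
        tab <- pp_contingency(carriers, mat, cv$gene_id)
        res <- chi_squared_test(tab, correct = correct)
        p_carrier <- tab["yes", "yes"] / sum(tab["yes", ])
        p_noncarrier <- tab["no", "yes"] / sum(tab["no", ])
        list(stat = res$statistic, p = res$p_value, enriched = p_carrier > p_noncarrier)
      },
      error = function(e) list(stat = NA_real_, p = NA_real_, enriched = NA)
    )

    carrier_ab <- ab_obs |>
      filter(
        .data$chrom == cv$chrom, .data$pos == cv$pos,
        .data$ref == cv$ref, .data$alt == cv$alt
      )
    mean_ab <- if (nrow(carrier_ab)) mean(carrier_ab$ab) else NA_real_

    tibble(
      gene_id = cv$gene_id, chrom = cv$chrom, pos = cv$pos,
      ref = cv$ref, alt = cv$alt,
      label = if ("label" %in% names(cv)) cv$label else NA_character_,
      n_carriers = length(carriers),
      junction_distance = jd,
      n_carriers_with_pp = n_with,
      n_carriers_without_pp = n_without,
      chi2_stat = as.numeric(assoc$stat),
      p_value = as.numeric(assoc$p),
      pp_enriched = as.logical(assoc$enriched),
      mean_carrier_ab = mean_ab
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(new_tibble_subclass(out, "pp_verdicts"))
  }

  out <- out |>
    mutate(
      p_adjusted = stats::p.adjust(.data$p_value, method = p_adjust),
      junction_ok = .data$junction_distance <= junction_window,
      assoc_ok = .data$p_adjusted < alpha & .data$pp_enriched,
      ab_ok = .data$mean_carrier_ab <= ab_ceiling,
      flag = ifelse(
        conjunction_evaluable(.data$junction_ok, .data$assoc_ok, .data$ab_ok),
        "likely_pp_artifact", "not_flagged"
      )
    )
  attr(out, "params") <- list(
    junction_window = junction_window, ab_ceiling = ab_ceiling,
    alpha = alpha, correct = correct, p_adjust = p_adjust
  )
  new_tibble_subclass(out, "pp_verdicts")
}

# all-of conjunction over criteria, NAs (unevaluable) dropped; at least one
# criterion must be evaluable
conjunction_evaluable <- function(...) {
  crit <- cbind(...)
  apply(crit, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0L && all(r)
  })
}

#' @export
glance.pp_verdicts <- function(x, ...) {
  tibble(
    n_variants = nrow(x),
    n_flagged = sum(x$flag == "likely_pp_artifact"),
    n_junction = sum(x$junction_ok, na.rm = TRUE),
    n_assoc = sum(x$assoc_ok, na.rm = TRUE),
    n_low_ab = sum(x$ab_ok, na.rm = TRUE)
  )
}

#' Read a clinically labelled variant list (TSV)
#'
#' Columns: `chrom`, `pos` (1-based), `ref`, `alt`, `gene_id`, `label`.
#'
#' @param path TSV file.
#' @return tibble suitable for [flag_variants()].
#' @export
read_clinical_variants <- function(path) {
  if (!file.exists(path)) abort(paste0("clinical variant list not found: ", path))
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene_id = readr::col_character(), label = readr::col_character()
  ), progress = FALSE)
}

#' Per-caller, per-gene false-positive report
#'
#' Tabulates flagged variant carriers by caller and gene (long format) and
#' summarises, per caller, the number and percentage of unique cohort samples
#' affected. Callers with zero flags are retained as all-zero rows when
#' listed in `callers`.
#'
#' @param flags tibble with one row per flagged carrier: `caller`, `gene_id`,
#'   `sample_id`.
#' @param n_samples cohort size (denominator for percentages).
#' @param callers,genes optional levels to keep even when unobserved.
#' @return A `pp_fp_report` object: list with `counts` (caller x gene x
#'   `n_flagged`) and `by_caller` (`n_flagged_samples`, `pct_samples`).
#'   `tidy()` returns the counts, `glance()` the per-caller summary.
#' @export
fp_report <- function(flags, n_samples, callers = NULL, genes = NULL) {
  stopifnot(n_samples >= 1)
  flags <- as_tibble(flags)
  callers <- union(callers, unique(flags$caller))
  genes <- union(genes, unique(flags$gene_id))
  if (length(callers) == 0L) abort("need at least one caller result set")
  counts <- flags |>
    distinct(.data$caller, .data$gene_id, .data$sample_id) |>
    count(.data$caller, .data$gene_id, name = "n_flagged")
  if (length(genes)) {
    counts <- counts |>
      complete(
        caller = callers, gene_id = genes,
        fill = list(n_flagged = 0L)
      )
  } else {
    counts <- tibble(caller = callers, gene_id = NA_character_, n_flagged = 0L)
  }
  by_caller <- tibble(caller = callers) |>
    left_join(
      flags |>
        distinct(.data$caller, .data$sample_id) |>
        count(.data$caller, name = "n_flagged_samples"),
      by = "caller"
    ) |>
    mutate(
      n_flagged_samples = coalesce(.data$n_flagged_samples, 0L),
      pct_samples = 100 * .data$n_flagged_samples / n_samples
    )
  structure(
    list(counts = arrange(counts, .data$caller, .data$gene_id),
         by_caller = by_caller, n_samples = n_samples),
    class = "pp_fp_report"
  )
}

#' @export
tidy.pp_fp_report <- function(x, ...) x$counts

#' @export
glance.pp_fp_report <- function(x, ...) x$by_caller

#' @export
print.pp_fp_report <- function(x, ...) {
  cat(sprintf("# FP report over %d sample(s)\n", x$n_samples))
  print(x$by_caller)
  print(x$counts, n = 20)
  invisible(x)
}

#' Write artifact verdicts and FP report as TSV
#'
#' @param verdicts a `pp_verdicts` tibble.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  readr::write_tsv(as_tibble(verdicts), path)
  invisible(path)
}
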