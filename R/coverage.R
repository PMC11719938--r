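#' Read a depth track (bedGraph / mosdepth-style BED)
#'
#' Four tab-separated columns: chrom, start, end (0-based half-open), mean
#' depth over the interval. Intervals must be non-overlapping per chromosome.
#'
#' @param path bedGraph file.
#' @param sample_id sample label; defaults to the file's base name.
#' @return tibble: `sample_id`, `chrom`, `start`, `end`, `depth`.
#' @export
read_depth_track <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("depth track not found: ", path))
  sample_id <- sample_id %||% sub("\\.(bed|bedgraph)(\\.gz)?$", "", basename(path))
  d <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "depth"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), depth = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
  if (any(d$depth < 0)) abort("negative depth in track")
  mutate(d, sample_id = sample_id, .before = 1L)
}

#' Length-weighted mean depth over a set of intervals
#'
#' Averages track depth over the union of the query intervals, weighting each
#' base equally. Bases absent from the track are counted as depth 0 under the
#' default `"zero"` policy (complete mosdepth-style tracks make this safe) or
#' dropped from the denominator under `"ignore"`.
#'
#' @param track depth-track tibble ([read_depth_track()]).
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param missing `"zero"` or `"ignore"`.
#' @return mean depth (single number).
#' @export
mean_depth_over <- function(track, intervals, missing = c("zero", "ignore")) {
  missing <- match.arg(missing)
  if (nrow(intervals) == 0L) abort("no intervals given")
  total_len <- sum(intervals$end - intervals$start)
  if (total_len <= 0) abort("intervals have zero total length")

  ov <- intervals |>
    select("chrom", q_start = "start", q_end = "end") |>
    inner_join(
      track |> select("chrom", t_start = "start", t_end = "end", "depth"),
      by = "chrom", relationship = "many-to-many"
    ) |>
    mutate(
      o_start = pmax(.data$q_start, .data$t_start),
      o_end = pmin(.data$q_end, .data$t_end),
      o_len = pmax(0L, .data$o_end - .data$o_start)
    ) |>
    filter(.data$o_len > 0L)

  covered <- sum(ov$o_len)
  reads <- sum(ov$depth * ov$o_len)
  denom <- if (missing == "zero") total_len else covered
  if (denom == 0) abort("zero covered bases under missing = 'ignore'")
  reads / denom
}

#' Exon/intron mean-depth ratio per gene
#'
#' The coverage diagnostic for processed pseudogenes: PP-derived reads map
#' only onto the parent's exons, so in a carrier with `c` extra copies the
#' exon mean rises to about `(2+c)/2` times the intron mean, while
#' non-carriers sit near 1. Genes without introns are skipped (the ratio is
#' undefined for them); genes whose intron mean is 0 are kept with `ratio =
#' NA` and `undefined = TRUE`.
#'
#' @param track depth-track tibble for one sample ([read_depth_track()]).
#' @param models a `pp_gene_models` tibble.
#' @param missing missing-depth policy, see [mean_depth_over()].
#' @return A `pp_coverage` tibble: `sample_id`, `gene_id`, `exon_mean`,
#'   `intron_mean`, `ratio`, `undefined`.
#' @export
exon_intron_ratio <- function(track, models, missing = c("zero", "ignore")) {
  stopifnot(inherits(models, "pp_gene_models"))
  missing <- match.arg(missing)
  usable <- filter(models, .data$n_introns >= 1L)
  if (nrow(usable) < nrow(models)) {
    inform(sprintf(
      "%d intron-less gene(s) skipped: exon/intron ratio undefined",
      nrow(models) - nrow(usable)
    ))
  }
  sample_id <- if (nrow(track)) track$sample_id[[1]] else NA_character_
  out <- usable |>
    as_tibble() |>
    mutate(
      exon_mean = map2_dbl(
        .data$exons, .data$chrom,
        ~ mean_depth_over(track, mutate(.x, chrom = .y), missing = missing)
      ),
      intron_mean = map2_dbl(
        .data$introns, .data$chrom,
        ~ mean_depth_over(track, mutate(.x, chrom = .y), missing = missing)
      )
    ) |>
    transmute(
      sample_id = sample_id,
      gene_id = .data$gene_id,
      exon_mean = .data$exon_mean,
      intron_mean = .data$intron_mean,
      ratio = ifelse(.data$intron_mean > 0, .data$exon_mean / .data$intron_mean, NA_real_),
      undefined = .data$intron_mean == 0
    )
  new_tibble_subclass(out, "pp_coverage")
}

#' @importFrom purrr map2_dbl
NULL
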