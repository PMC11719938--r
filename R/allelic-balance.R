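#' Allelic balance per variant observation
#'
#' Allelic balance (AB) is the fraction of reads supporting the alternative
#' allele: `ad_alt / (ad_ref + ad_alt)`. The denominator is the sum of the AD
#' entries, not DP — DP counts uninformative reads. True heterozygous variants
#' cluster near 0.5 and homozygous ones near 1.0; variants whose reads
#' actually come from a processed pseudogene are diluted by the parent gene's
#' reads and sit near `c/(2+c)` for `c` extra copies (1/3 for a het carrier).
#'
#' @param variants tibble with `ad_ref`, `ad_alt` columns
#'   ([read_small_variants()] output).
#' @return the input with an `ab` column appended; rows with zero total AD are
#'   dropped with a warning (AB undefined).
#' @export
allelic_balance <- function(variants) {
  variants <- as_tibble(variants)
  total <- variants$ad_ref + variants$ad_alt
  bad <- is.na(total) | total <= 0L
  if (any(bad)) {
    warn(sprintf("%d variant(s) with zero/missing total AD excluded (AB undefined)", sum(bad)))
    variants <- variants[!bad, , drop = FALSE]
    total <- total[!bad]
  }
  mutate(variants, ab = .data$ad_alt / total)
}

#' Expected allelic balance under the copy-number model
#'
#' Idealized expectation for a variant present on `variant_copies` of the
#' `gene_copies + pp_copies` near-identical sequence copies that all map onto
#' the parent gene: `variant_copies / (gene_copies + pp_copies)`. A het
#' variant with no PP gives 1/2; a PP-borne variant in a het PP carrier 1/3;
#' on one copy of a hom PP carrier 1/4.
#'
#' @param gene_copies,pp_copies,variant_copies non-negative integers
#'   (vectorized); `variant_copies <= gene_copies + pp_copies` and the total
#'   copy number must be positive.
#' @return expected AB fraction in `[0, 1]`.
#' @export
expected_ab <- function(gene_copies, pp_copies, variant_copies) {
  n <- max(length(gene_copies), length(pp_copies), length(variant_copies))
  gene_copies <- rep_len(gene_copies, n)
  pp_copies <- rep_len(pp_copies, n)
  variant_copies <- rep_len(variant_copies, n)
  if (any(gene_copies < 0 | pp_copies < 0 | variant_copies < 0)) {
    abort("copy numbers must be non-negative")
  }
  total <- gene_copies + pp_copies
  if (any(total <= 0)) abort("total copy number must be positive")
  if (any(variant_copies > total)) {
    abort("variant_copies cannot exceed gene_copies + pp_copies")
  }
  variant_copies / total
}

# 20 right-open 5% bins over [0, 1]; the last bin is closed so AB = 1 lands
# in [0.95, 1.00]. The small epsilon keeps exact edge values (e.g. 9/30 = 0.3)
# on the left-closed side despite floating-point division.
ab_bin_index <- function(ab, binwidth = 0.05) {
  nb <- round(1 / binwidth)
  pmin(nb, floor(ab / binwidth + 1e-9) + 1L)
}

#' Histogram of allelic-balance values in 5% bins
#'
#' @param ab numeric vector of AB fractions in `[0, 1]`.
#' @param binwidth bin width as a fraction (default 0.05).
#' @return tibble with one row per bin: `bin_lo`, `bin_hi`, `center`
#'   (fraction), `count`; counts sum to `length(ab)`.
#' @export
ab_histogram <- function(ab, binwidth = 0.05) {
  stopifnot(all(ab >= 0 & ab <= 1))
  nb <- round(1 / binwidth)
  idx <- ab_bin_index(ab, binwidth)
  tibble(
    bin_lo = round((seq_len(nb) - 1L) * binwidth, 9),
    bin_hi = round(seq_len(nb) * binwidth, 9),
    center = round((seq_len(nb) - 0.5) * binwidth, 9),
    count = as.integer(tabulate(idx, nbins = nb))
  )
}

#' Modes of an allelic-balance histogram
#'
#' A mode is a bin whose count is strictly greater than both neighbours (edge
#' bins compare against their single neighbour). A plateau — a run of equal
#' counts strictly higher than the bins flanking the run — yields one mode at
#' the run's lowest-AB bin.
#'
#' @param histogram tibble from [ab_histogram()].
#' @return numeric vector of mode bin centers (fractions).
#' @export
ab_modes <- function(histogram) {
  counts <- histogram$count
  n <- length(counts)
  if (n == 0L || all(counts == 0L)) {
    return(numeric(0))
  }
  # collapse runs of equal counts, keep each run's first bin
  r <- rle(counts)
  run_start <- cumsum(c(1L, head(r$lengths, -1L)))
  k <- length(r$values)
  is_mode <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k || r$values[i] > r$values[i + 1L]
    left_ok && right_ok && r$values[i] > 0L
  }, logical(1))
  histogram$center[run_start[is_mode]]
}

#' @describeIn ab_modes the dominant mode: the local maximum with the highest
#'   count (`NA` for an empty histogram). With discrete read counts the AB
#'   values live on a lattice (multiples of 1/depth), so 5% bins alternate
#'   between holding one and two achievable values and minor comb maxima can
#'   appear beside the main peak; the dominant mode is the meaningful one.
#' @export
ab_top_mode <- function(histogram) {
  m <- ab_modes(histogram)
  if (length(m) == 0L) {
    return(NA_real_)
  }
  m[which.max(histogram$count[match(m, histogram$center)])]
}

#' Summarise allelic-balance distributions per group
#'
#' Groups variant observations (typically by gene and PP-carrier status),
#' keeps het and hom_alt genotypes, and reports per group the variant count,
#' mean AB, the 5%-bin histogram and its modes. The diploid background is
#' bimodal with modes in the bins holding 50% and 100%; a PP-shifted group
#' shows a single low mode near `c/(2+c)`.
#'
#' @param variants tibble with `ad_ref`, `ad_alt`, `genotype` and the grouping
#'   columns.
#' @param ... grouping columns (tidy-select style bare names), e.g. `gene_id,
#'   pp_present`. With none, one overall summary row is returned.
#' @param binwidth histogram bin width (default 0.05).
#' @return An `ab_summary` tibble: grouping columns plus `n_variants`,
#'   `mean_ab`, `histogram` (list), `modes` (list of bin-center fractions).
#' @export
summarize_ab <- function(variants, ..., binwidth = 0.05) {
  variants <- as_tibble(variants)
  if (nrow(variants) == 0L) {
    warn("no variants to summarise")
  }
  keep <- variants$genotype %in% c("het", "hom_alt")
  dropped <- sum(!keep)
  if (dropped > 0L) {
    inform(sprintf("%d variant(s) with genotype outside {het, hom_alt} excluded", dropped))
  }
  ab_tbl <- allelic_balance(variants[keep, , drop = FALSE])
  out <- ab_tbl |>
    group_by(...) |>
    summarise(
      n_variants = dplyr::n(),
      mean_ab = mean(.data$ab),
      histogram = list(ab_histogram(.data$ab, binwidth = binwidth)),
      modes = list(ab_modes(ab_histogram(.data$ab, binwidth = binwidth))),
      .groups = "drop"
    )
  new_tibble_subclass(out, "ab_summary")
}

#' Variant-count excess in PP carriers
#'
#' Samples carrying a processed pseudogene accumulate extra (PP-derived)
#' variant calls in the parent gene. This compares the mean number of variant
#' observations per sample between carrier and non-carrier groups, per gene,
#' counting zero for member samples with no variants.
#'
#' @param variants tibble with `sample_id`, `gene_id` (one row per observed
#'   variant).
#' @param membership tibble with `sample_id`, `gene_id`, `pp_present`
#'   (logical or 0/1): every cohort sample's carrier status per gene (e.g.
#'   `tidy()` of a [cohort_pp_matrix()]).
#' @return tibble per gene: group sizes, mean counts and `excess` = carrier
#'   mean / non-carrier mean (`Inf` with a warning when the non-carrier mean
#'   is 0).
#' @export
variant_excess <- function(variants, membership) {
  membership <- membership |>
    as_tibble() |>
    mutate(pp_present = as.logical(.data$pp_present))
  if (nrow(membership) == 0L) abort("empty membership table")
  counts <- membership |>
    left_join(
      variants |> count(.data$sample_id, .data$gene_id, name = "n_variants"),
      by = c("sample_id", "gene_id")
    ) |>
    mutate(n_variants = coalesce(.data$n_variants, 0L))
  out <- counts |>
    group_by(.data$gene_id) |>
    summarise(
      n_pp_samples = sum(.data$pp_present),
      n_nopp_samples = sum(!.data$pp_present),
      mean_pp = mean(.data$n_variants[.data$pp_present]),
      mean_nopp = mean(.data$n_variants[!.data$pp_present]),
      .groups = "drop"
    ) |>
    mutate(excess = .data$mean_pp / .data$mean_nopp)
  zero_denom <- !is.na(out$mean_nopp) & out$mean_nopp == 0
  if (any(zero_denom)) {
    warn("non-carrier group has zero mean variant count; excess reported as Inf")
    out$excess[zero_denom] <- Inf
  }
  out
}

#' Write per-group AB summaries (and optionally per-variant ABs) as TSV
#'
#' @param summary an `ab_summary` tibble.
#' @param path output TSV; histograms are flattened to long format.
#' @return `path`, invisibly.
#' @export
write_ab_summary <- function(summary, path) {
  flat <- summary |>
    mutate(modes = map_chr(.data$modes, ~ paste(format(.x), collapse = ","))) |>
    unnest("histogram")
  readr::write_tsv(flat, path)
  invisible(path)
}
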