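#' Plot an allelic-balance summary
#'
#' Bar-chart of the 5%-bin AB histogram, one facet per group, with mode bins
#' marked. The diploid background shows the bimodal 50%/100% pattern; a
#' PP-shifted group shows a single low mode.
#'
#' @param object an `ab_summary` from [summarize_ab()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ab_summary <- function(object, ...) {
  group_cols <- setdiff(names(object), c("n_variants", "mean_ab", "histogram", "modes"))
  object <- as_tibble(object)
  object$.group <- if (length(group_cols)) {
    do.call(paste, c(as.list(object[group_cols]), sep = " / "))
  } else {
    rep("all variants", nrow(object))
  }
  flat <- tidyr::unnest(object, "histogram")
  modes <- object |>
    select(".group", "modes") |>
    tidyr::unnest_longer("modes", values_to = "center")
  ggplot2::ggplot(flat, ggplot2::aes(x = 100 * .data$center, y = .data$count)) +
    ggplot2::geom_col(width = 4.5, fill = "grey35") +
    ggplot2::geom_vline(
      data = modes, ggplot2::aes(xintercept = 100 * .data$center),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~.group, scales = "free_y") +
    ggplot2::labs(
      x = "allelic balance (%)", y = "variants",
      title = "Allelic-balance distribution (modes dashed)"
    )
}

#' Plot exon/intron coverage ratios
#'
#' Boxplot of per-gene ratios; when a `group` column is present (e.g. PP
#' carrier status) one box per group is drawn. Carriers are expected near
#' `(2+c)/2`, non-carriers near 1 (dotted line).
#'
#' @param object a `pp_coverage` tibble ([exon_intron_ratio()]), optionally
#'   with an added `group` column.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pp_coverage <- function(object, ...) {
  d <- as_tibble(object) |> filter(!.data$undefined)
  if (!"group" %in% names(d)) d$group <- "all samples"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(
      x = NULL, y = "exon / intron mean depth",
      title = "Exon-intron coverage ratio"
    )
}

#' Plot per-gene processed-pseudogene carrier frequencies
#'
#' @param object a `pp_matrix` from [cohort_pp_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pp_matrix <- function(object, ...) {
  freq <- pp_frequency(object)
  ggplot2::ggplot(freq, ggplot2::aes(
    x = stats::reorder(.data$gene_id, -.data$frequency), y = .data$frequency
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "carrier frequency (%)",
      title = "Processed-pseudogene carrier frequency per gene"
    )
}
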