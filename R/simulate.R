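#' Parameters for a synthetic cohort
#'
#' Bundles and validates the generative settings for [simulate_cohort()]. The
#' simulator emits the downstream evidence the pipeline consumes — SV deletion
#' records, depth tracks and AD counts — rather than reads: a carrier of `c`
#' extra gene copies gets one deletion record per intron (breakpoints jittered
#' within `sv_jitter` bp), exon depth scaled by `(2+c)/2`, and PP-divergence
#' variants whose allelic balance is diluted to `c(1-l)/(2+c(1-l))` for
#' read-loss fraction `l`.
#'
#' @param n_samples cohort size (default 200).
#' @param genes per-gene geometry and PP allele frequency: tibble with
#'   `gene_id`, `n_exons`, `exon_len`, `intron_len`, `pp_allele_freq`.
#'   Defaults to a five-gene panel spanning 1 to 8 exons, including an
#'   intron-less (undetectable) control gene.
#' @param depth mean sequencing depth in reads (default 30, standard WGS).
#' @param depth_noise `"poisson"` (default) draws interval depths and site
#'   totals from Poisson; `"none"` emits exact means.
#' @param ad_sampling `"binomial"` (default) draws `ad_alt ~ Binomial(D, AB)`;
#'   `"exact"` rounds `D * AB` (a fully noiseless forward model together with
#'   `depth_noise = "none"`).
#' @param sv_jitter uniform breakpoint jitter half-width in bp (default 3;
#'   must satisfy `intron_len > 2 * sv_jitter`).
#' @param pp_divergence_variants divergence variants carried by each PP
#'   (default 8; with the default background rates the carrier group then
#'   harbours 5x more variants per sample, the cohort-scale excess reported
#'   for real data).
#' @param read_loss fraction of PP-derived reads that fail to map back onto
#'   the parent gene (default 0.15, placing simulated PP-variant AB in the
#'   observed 25-30% band; a tuning knob, not a measured quantity).
#' @param het_rate,hom_rate Poisson means of background heterozygous /
#'   homozygous variants per gene per sample (defaults 1.5 / 0.5).
#' @param background_dels non-PP deletion records per sample (default 2),
#'   placed at random coordinates as detection decoys.
#' @param clinical_artifacts when `TRUE` (default) the first divergence
#'   variant of each PP gene sits exactly on the first intron-exon junction
#'   and is listed as a clinically labelled (`LP`) variant.
#' @param true_clinical_rate carrier probability of a genuine mid-exon
#'   pathogenic-like het variant listed as `P` (default 0.05).
#' @param carrier_fraction optional named vector (by gene_id) of exact
#'   carrier fractions; quota-sampled (`round(f * n)` carriers, one PP copy
#'   each) instead of Hardy-Weinberg draws from `pp_allele_freq`.
#' @param seed integer seed; the same params + seed reproduce byte-identical
#'   output files.
#' @return a `pp_sim_params` list.
#' @export
sim_params <- function(n_samples = 200,
                       genes = default_sim_genes(),
                       depth = 30,
                       depth_noise = c("poisson", "none"),
                       ad_sampling = c("binomial", "exact"),
                       sv_jitter = 3,
                       pp_divergence_variants = 8,
                       read_loss = 0.15,
                       het_rate = 1.5,
                       hom_rate = 0.5,
                       background_dels = 2,
                       clinical_artifacts = TRUE,
                       true_clinical_rate = 0.05,
                       carrier_fraction = NULL,
                       seed = 1L) {
  depth_noise <- match.arg(depth_noise)
  ad_sampling <- match.arg(ad_sampling)
  genes <- as_tibble(genes)
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (depth <= 0) abort("depth must be positive")
  if (any(genes$pp_allele_freq < 0 | genes$pp_allele_freq > 1)) {
    abort("pp_allele_freq must lie in [0, 1]")
  }
  if (read_loss < 0 || read_loss >= 1) abort("read_loss must lie in [0, 1)")
  multi <- genes$n_exons > 1L
  if (any(genes$intron_len[multi] <= 2 * sv_jitter)) {
    abort("infeasible geometry: intron_len must exceed 2 * sv_jitter")
  }
  if (any(genes$exon_len < 40)) abort("exon_len must be >= 40")
  if (!is.null(carrier_fraction)) {
    if (is.null(names(carrier_fraction)) || !all(names(carrier_fraction) %in% genes$gene_id)) {
      abort("carrier_fraction must be named by gene_id")
    }
    if (any(carrier_fraction < 0 | carrier_fraction > 1)) {
      abort("carrier_fraction must lie in [0, 1]")
    }
  }
  structure(list(
    n_samples = as.integer(n_samples), genes = genes, depth = depth,
    depth_noise = depth_noise, ad_sampling = ad_sampling,
    sv_jitter = as.integer(sv_jitter),
    pp_divergence_variants = as.integer(pp_divergence_variants),
    read_loss = read_loss, het_rate = het_rate, hom_rate = hom_rate,
    background_dels = as.integer(background_dels),
    clinical_artifacts = isTRUE(clinical_artifacts),
    true_clinical_rate = true_clinical_rate,
    carrier_fraction = carrier_fraction, seed = as.integer(seed)
  ), class = "pp_sim_params")
}

#' @describeIn sim_params the default five-gene panel.
#' @export
default_sim_genes <- function() {
  tibble(
    gene_id = c("GENA", "GENB", "GENC", "GEND", "GENE1X"),
    n_exons = c(6L, 4L, 8L, 2L, 1L),
    exon_len = c(150L, 200L, 120L, 300L, 500L),
    intron_len = c(1200L, 1500L, 1000L, 2000L, 0L),
    pp_allele_freq = c(0.30, 0.20, 0.10, 0.25, 0.20)
  )
}

sim_gene_layout <- function(genes, gap = 10000L) {
  offset <- 0L
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    starts <- offset + (seq_len(g$n_exons) - 1L) * (g$exon_len + g$intron_len)
    ex <- tibble(
      gene_id = g$gene_id, gene_name = g$gene_id, chrom = "chr1", strand = "+",
      start = as.integer(starts), end = as.integer(starts + g$exon_len)
    )
    offset <<- max(ex$end) + gap
    ex
  })
  bind_rows(rows)
}

#' Simulate a synthetic cohort with processed-pseudogene signatures
#'
#' Generates, per sample: SV deletion calls (one intron-matched record per
#' intron for PP carriers plus random background deletions), a depth track
#' with exon-only coverage excess, and small-variant observations combining a
#' bimodal diploid background (het at AB 0.5, hom at 1.0) with PP-divergence
#' variants at junction-anchored positions and copy-number-correct AB. Every
#' emitted record traces back to a ground-truth row.
#'
#' @param params a `pp_sim_params` from [sim_params()].
#' @return a `pp_cohort_sim` list: `params`, `gene_models`, `deletions`,
#'   `depth`, `variants`, `clinical`, `truth_pp` (sample, gene, `pp_copies`),
#'   `truth_variants` (origin and expected AB per emitted record).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "pp_sim_params"))
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  samples <- sprintf("S%04d", seq_len(p$n_samples))
  exons <- sim_gene_layout(p$genes)
  models <- gene_models(exons)
  # keep the panel's declared order
  models <- models[match(p$genes$gene_id, models$gene_id), ]
  models <- new_tibble_subclass(models, "pp_gene_models")

  catalog <- sim_divergence_catalog(models, p)
  pools <- sim_gene_pools(models)
  truth_pp <- sim_pp_genotypes(p, samples)

  del_rows <- list()
  depth_rows <- list()
  var_rows <- list()
  truth_var_rows <- list()

  for (s in samples) {
    copies <- truth_pp$pp_copies[truth_pp$sample_id == s]
    names(copies) <- truth_pp$gene_id[truth_pp$sample_id == s]
    for (gi in seq_len(nrow(models))) {
      g <- models[gi, ]
      c_pp <- copies[[g$gene_id]]
      sim <- sim_sample_gene(s, g, c_pp, p, catalog[[g$gene_id]], pools[[g$gene_id]])
      del_rows[[length(del_rows) + 1L]] <- sim$deletions
      depth_rows[[length(depth_rows) + 1L]] <- sim$depth
      var_rows[[length(var_rows) + 1L]] <- sim$variants
      truth_var_rows[[length(truth_var_rows) + 1L]] <- sim$truth
    }
    del_rows[[length(del_rows) + 1L]] <- sim_background_dels(s, models, p)
  }

  clinical <- sim_clinical_table(models, p, catalog)
  structure(list(
    params = p,
    gene_models = models,
    deletions = bind_rows(del_rows),
    depth = bind_rows(depth_rows),
    variants = bind_rows(var_rows),
    clinical = clinical,
    truth_pp = truth_pp,
    truth_variants = bind_rows(truth_var_rows)
  ), class = "pp_cohort_sim")
}

# cheap tibble constructor for the simulator's hot path: columns are known
# valid, scalars are recycled to n
fast_tbl <- function(n, ...) {
  cols <- lapply(list(...), function(x) if (length(x) == 1L && n != 1L) rep(x, n) else x)
  tibble::new_tibble(cols, nrow = n)
}

carrier_fraction_for <- function(p, gene_id) {
  cf <- p$carrier_fraction
  if (!is.null(cf) && gene_id %in% names(cf)) cf[[gene_id]] else NULL
}

sim_pp_genotypes <- function(p, samples) {
  rows <- purrr::map(seq_len(nrow(p$genes)), function(i) {
    g <- p$genes[i, ]
    quota_f <- carrier_fraction_for(p, g$gene_id)
    copies <- if (!is.null(quota_f)) {
      n_carriers <- round(quota_f * length(samples))
      carrier_idx <- sample(seq_along(samples), n_carriers)
      ifelse(seq_along(samples) %in% carrier_idx, 1L, 0L)
    } else {
      stats::rbinom(length(samples), 2L, g$pp_allele_freq)
    }
    tibble(sample_id = samples, gene_id = g$gene_id, pp_copies = as.integer(copies))
  })
  bind_rows(rows)
}

# fixed per-gene catalog of divergence variants: junction-anchored first
# (1-based position b+1 sits on the 0-based junction boundary b), then random
# exon-interior positions; shared across carriers like a real PP haplotype
sim_divergence_catalog <- function(models, p) {
  k <- p$pp_divergence_variants
  out <- list()
  for (gi in seq_len(nrow(models))) {
    g <- models[gi, ]
    if (k == 0L || g$n_introns == 0L) {
      out[[g$gene_id]] <- tibble(pos = integer(), ref = character(), alt = character())
      next
    }
    junc_pos <- g$junctions[[1]] + 1L
    interior <- exon_interior_positions(g, margin = 15L)
    n_extra <- max(0L, k - length(junc_pos))
    pos <- c(
      head(junc_pos, k),
      if (n_extra > 0L) sample(interior, n_extra) else integer(0)
    )
    out[[g$gene_id]] <- tibble(
      pos = as.integer(pos),
      ref = sample(c("A", "C", "G", "T"), length(pos), replace = TRUE),
      alt = "N"
    ) |>
      mutate(alt = map_chr(.data$ref, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1L)))
  }
  out
}

min_junction_dist <- function(p0, junctions) {
  if (length(junctions) == 0L) {
    return(rep(Inf, length(p0)))
  }
  Reduce(pmin, lapply(junctions, function(j) abs(p0 - j)))
}

exon_interior_positions <- function(g, margin = 15L) {
  ex <- g$exons[[1]]
  pos1 <- unlist(purrr::map2(ex$start, ex$end, ~ seq(.x + 1L, .y)))
  pos1[min_junction_dist(pos1 - 1L, g$junctions[[1]]) > margin]
}

in_exon <- function(pos1, g) {
  ex <- g$exons[[1]]
  p0 <- pos1 - 1L
  idx <- findInterval(p0, ex$start)
  idx >= 1L & p0 < c(ex$end, 0L)[pmax(idx, 1L)]
}

# sample-independent per-gene sampling pools, computed once per cohort
sim_gene_pools <- function(models) {
  out <- list()
  for (gi in seq_len(nrow(models))) {
    g <- models[gi, ]
    bg <- background_positions(g, margin = 15L)
    out[[g$gene_id]] <- list(bg = bg, bg_exonic = in_exon(bg, g))
  }
  out
}

sim_depth_value <- function(mean_depth, len, noise) {
  if (noise == "poisson") {
    stats::rpois(length(len), mean_depth * len) / len
  } else {
    rep_len(mean_depth, length(len))
  }
}

sim_site_depth <- function(mean_depth, noise) {
  d <- if (noise == "poisson") stats::rpois(length(mean_depth), mean_depth) else round(mean_depth)
  pmax(1L, as.integer(d))
}

sim_ad_alt <- function(depth, ab, sampling) {
  if (sampling == "binomial") {
    stats::rbinom(length(depth), depth, ab)
  } else {
    as.integer(round(depth * ab))
  }
}

sim_sample_gene <- function(s, g, c_pp, p, catalog, pool) {
  lam <- p$read_loss
  c_eff <- c_pp * (1 - lam)
  exon_scale <- (2 + c_pp) / 2 # PP reads pile onto exons only
  ad_scale <- (2 + c_eff) / 2 # mapped-read total at variant sites

  # --- deletions: one intron-matched record per intron for carriers ---
  dels <- empty_deletions()
  if (c_pp >= 1L && g$n_introns >= 1L) {
    intr <- g$introns[[1]]
    jit <- function(n) {
      if (p$sv_jitter == 0L) rep(0L, n) else sample(seq(-p$sv_jitter, p$sv_jitter), n, replace = TRUE)
    }
    dels <- fast_tbl(nrow(intr),
      sample_id = s, chrom = g$chrom,
      start = as.integer(intr$start + jit(nrow(intr))),
      end = as.integer(intr$end + jit(nrow(intr))),
      sv_id = sprintf("%s_%s_i%d", s, g$gene_id, seq_len(nrow(intr))),
      qual = 99, filter = "PASS"
    )
  }

  # --- depth track: exon and intron intervals ---
  ex <- g$exons[[1]]
  intr <- g$introns[[1]]
  iv_start <- c(ex$start, intr$start)
  iv_end <- c(ex$end, intr$end)
  iv_depth <- c(
    sim_depth_value(p$depth * exon_scale, ex$end - ex$start, p$depth_noise),
    sim_depth_value(p$depth, intr$end - intr$start, p$depth_noise)
  )
  ord <- order(iv_start)
  depth <- fast_tbl(length(iv_start),
    sample_id = s, chrom = g$chrom, start = iv_start[ord], end = iv_end[ord],
    depth = as.numeric(iv_depth)[ord]
  )

  # --- small variants: assemble vectors, then draw depths/AD in one go ---
  bases <- c("A", "C", "G", "T")
  n_het <- stats::rpois(1L, p$het_rate)
  n_hom <- stats::rpois(1L, p$hom_rate)
  n_bg <- min(n_het + n_hom, length(pool$bg))
  bg_idx <- if (n_bg > 0L) sample(length(pool$bg), n_bg) else integer(0)
  bg_is_het <- seq_len(n_bg) <= min(n_het, n_bg)
  bg_exonic <- pool$bg_exonic[bg_idx]
  bg_dilution <- 2 + ifelse(bg_exonic, c_eff, 0) # mapped copies at the site
  bg_ref <- sample(bases, n_bg, replace = TRUE)
  bg_alt <- unname(vapply(bg_ref, function(r) sample(setdiff(bases, r), 1L), character(1)))

  pos <- pool$bg[bg_idx]
  ref <- bg_ref
  alt <- bg_alt
  genotype <- rep("hom_alt", n_bg)
  genotype[bg_is_het] <- "het"
  ab_exp <- ifelse(bg_is_het, 1, 2) / bg_dilution
  origin <- rep("gene_hom", n_bg)
  origin[bg_is_het] <- "gene_het"
  exonic <- bg_exonic

  # PP divergence variants: present on every PP copy of a carrier
  if (c_pp >= 1L && nrow(catalog)) {
    pos <- c(pos, catalog$pos)
    ref <- c(ref, catalog$ref)
    alt <- c(alt, catalog$alt)
    genotype <- c(genotype, rep("het", nrow(catalog)))
    ab_exp <- c(ab_exp, rep(c_eff / (2 + c_eff), nrow(catalog)))
    origin <- c(origin, rep("pp_divergence", nrow(catalog)))
    exonic <- c(exonic, rep(TRUE, nrow(catalog)))
  }

  # genuine mid-exon pathogenic-like het variant
  if (p$true_clinical_rate > 0 && stats::runif(1L) < p$true_clinical_rate) {
    tc <- true_clinical_site(g)
    pos <- c(pos, tc$pos)
    ref <- c(ref, tc$ref)
    alt <- c(alt, tc$alt)
    genotype <- c(genotype, "het")
    ab_exp <- c(ab_exp, 1 / (2 + c_eff))
    origin <- c(origin, "gene_het_clinical")
    exonic <- c(exonic, TRUE)
  }

  d <- sim_site_depth(p$depth * ifelse(exonic, ad_scale, 1), p$depth_noise)
  ad_alt <- sim_ad_alt(d, ab_exp, p$ad_sampling)
  n <- length(pos)
  vars <- fast_tbl(n,
    sample_id = s, chrom = g$chrom, pos = as.integer(pos), ref = ref, alt = alt,
    genotype = genotype, ad_ref = as.integer(d - ad_alt), ad_alt = as.integer(ad_alt)
  )
  truth <- fast_tbl(n,
    sample_id = s, gene_id = g$gene_id, chrom = g$chrom, pos = as.integer(pos),
    ref = ref, alt = alt, origin = origin, expected_ab = as.numeric(ab_exp)
  )

  list(deletions = dels, depth = depth, variants = vars, truth = truth)
}

# positions > margin bp from every junction and distinct from the fixed
# clinical site, so background truth never collides with signature positions
background_positions <- function(g, margin = 15L) {
  pos1 <- seq(g$span_start + 1L, g$span_end)
  pos1 <- pos1[min_junction_dist(pos1 - 1L, g$junctions[[1]]) > margin]
  setdiff(pos1, true_clinical_site(g)$pos)
}

# deterministic mid-exon site per gene for the genuine clinical variant
true_clinical_site <- function(g) {
  ex <- g$exons[[1]]
  mid <- ceiling(nrow(ex) / 2)
  list(pos = as.integer((ex$start[mid] + ex$end[mid]) %/% 2 + 1L), ref = "C", alt = "T")
}

sim_background_dels <- function(s, models, p) {
  if (p$background_dels == 0L) {
    return(empty_deletions())
  }
  n <- p$background_dels
  gi <- sample(nrow(models), n, replace = TRUE)
  len <- sample(50:3000, n, replace = TRUE)
  span <- models$span_end[gi] - models$span_start[gi] - 60L
  start <- models$span_start[gi] + floor(stats::runif(n) * pmax(1L, span))
  fast_tbl(n,
    sample_id = s, chrom = models$chrom[gi], start = as.integer(start),
    end = as.integer(start + len), sv_id = sprintf("%s_bg%d", s, seq_len(n)),
    qual = 40, filter = "PASS"
  )
}

sim_clinical_table <- function(models, p, catalog) {
  rows <- list()
  for (gi in seq_len(nrow(models))) {
    g <- models[gi, ]
    freq <- p$genes$pp_allele_freq[p$genes$gene_id == g$gene_id]
    has_pp <- freq > 0 || !is.null(carrier_fraction_for(p, g$gene_id))
    if (p$clinical_artifacts && has_pp && nrow(catalog[[g$gene_id]])) {
      cv <- catalog[[g$gene_id]][1L, ]
      rows[[length(rows) + 1L]] <- tibble(
        chrom = g$chrom, pos = cv$pos, ref = cv$ref, alt = cv$alt,
        gene_id = g$gene_id, label = "LP", truth = "pp_artifact"
      )
    }
    if (p$true_clinical_rate > 0) {
      tc <- true_clinical_site(g)
      rows[[length(rows) + 1L]] <- tibble(
        chrom = g$chrom, pos = tc$pos, ref = tc$ref, alt = tc$alt,
        gene_id = g$gene_id, label = "P", truth = "true_variant"
      )
    }
  }
  bind_rows(rows)
}

#' Detection performance of the pipeline against the simulator's truth
#'
#' Compares [detect_pp()] calls with the ground-truth PP genotypes over all
#' (sample, gene) pairs of genes detectable at the detector's threshold.
#'
#' @param sim a `pp_cohort_sim`.
#' @param calls a `pp_calls` tibble produced from the same cohort.
#' @return one-row tibble: `n_true`, `n_negative`, `sensitivity`,
#'   `false_call_rate`.
#' @export
sim_detection_metrics <- function(sim, calls) {
  min_matched <- attr(calls, "min_matched_introns") %||% 2
  detectable <- sim$gene_models$gene_id[sim$gene_models$n_introns >= min_matched]
  truth <- sim$truth_pp |>
    filter(.data$gene_id %in% detectable) |>
    mutate(truth_pp = .data$pp_copies >= 1L)
  pred <- calls |>
    as_tibble() |>
    filter(.data$verdict == "PP_present") |>
    distinct(.data$sample_id, .data$gene_id) |>
    mutate(called = TRUE)
  joined <- truth |>
    left_join(pred, by = c("sample_id", "gene_id")) |>
    mutate(called = coalesce(.data$called, FALSE))
  tibble(
    n_true = sum(joined$truth_pp),
    n_negative = sum(!joined$truth_pp),
    sensitivity = mean(joined$called[joined$truth_pp]),
    false_call_rate = mean(joined$called[!joined$truth_pp])
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the file formats the pipeline consumes: a GTF of the gene panel, one
#' Smoove-dialect SV VCF, one depth bedGraph and one GT:AD small-variant VCF
#' per sample, the clinical-variant TSV, the two truth tables, and a JSON
#' with the full parameter provenance.
#'
#' @param sim a `pp_cohort_sim`.
#' @param dir output directory (created if needed).
#' @return tibble manifest of written files, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "pp_cohort_sim"))
  for (d in file.path(dir, c("", "sv", "depth", "variants"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  files <- character(0)
  gtf <- file.path(dir, "genes.gtf")
  write_gene_gtf(sim$gene_models, gtf)
  files <- c(files, gtf)

  samples <- sprintf("S%04d", seq_len(sim$params$n_samples))
  for (s in samples) {
    svp <- file.path(dir, "sv", paste0(s, ".sv.vcf"))
    write_sv_vcf(filter(sim$deletions, .data$sample_id == s), svp, sample_id = s)
    dp <- file.path(dir, "depth", paste0(s, ".depth.bed"))
    sim$depth |>
      filter(.data$sample_id == s) |>
      select("chrom", "start", "end", "depth") |>
      readr::write_tsv(dp, col_names = FALSE)
    vp <- file.path(dir, "variants", paste0(s, ".vcf"))
    write_small_vcf(filter(sim$variants, .data$sample_id == s), vp, sample_id = s)
    files <- c(files, svp, dp, vp)
  }

  clin <- file.path(dir, "clinical_variants.tsv")
  readr::write_tsv(sim$clinical, clin)
  tp <- file.path(dir, "truth_pp.tsv")
  readr::write_tsv(sim$truth_pp, tp)
  tv <- file.path(dir, "truth_variants.tsv")
  readr::write_tsv(sim$truth_variants, tv)
  pj <- file.path(dir, "params.json")
  jsonlite::write_json(
    sim$params[setdiff(names(sim$params), "genes")],
    pj,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  files <- c(files, clin, tp, tv, pj)
  invisible(tibble(path = files))
}

#' Write the canonical deterministic mini-cohort fixture
#'
#' A 5-gene, 20-sample cohort used by the test suite, including a
#' high-frequency PP gene with an exact 47% carrier quota (mirroring the
#' frequency reported for PRKRA-class pseudogenes as a scenario parameter).
#' Repeated invocation with the same seed reproduces identical files.
#'
#' @param dir output directory.
#' @param n_samples cohort size (default 20).
#' @param seed seed (default 101).
#' @return the `pp_cohort_sim`, invisibly.
#' @export
write_fixture_suite <- function(dir, n_samples = 20, seed = 101) {
  genes <- default_sim_genes()
  p <- sim_params(
    n_samples = n_samples, genes = genes, seed = seed,
    carrier_fraction = c(GENA = 0.47)
  )
  sim <- simulate_cohort(p)
  write_cohort(sim, dir)
  invisible(sim)
}

#' @export
print.pp_cohort_sim <- function(x, ...) {
  cat(sprintf(
    "# Simulated cohort: %d samples x %d genes; %d deletion(s), %d variant record(s)\n",
    x$params$n_samples, nrow(x$gene_models), nrow(x$deletions), nrow(x$variants)
  ))
  invisible(x)
}
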