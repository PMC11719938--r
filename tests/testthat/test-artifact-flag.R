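pp_matrix_fixture <- function(samples, carriers, gene = "G1") {
  calls <- tibble::tibble(
    sample_id = carriers, gene_id = gene, n_introns_total = 4L,
    n_introns_matched = 4L, matched_introns = list(1:4), verdict = "PP_present"
  )
  class(calls) <- c("pp_calls", class(tibble::tibble()))
  cohort_pp_matrix(calls, samples = samples, genes = gene)
}

test_that("the contingency table partitions the cohort and sums to its size", {
  samples <- paste0("S", 1:10)
  mat <- pp_matrix_fixture(samples, carriers = paste0("S", 1:6))
  tab <- pp_contingency(paste0("S", 1:3), mat, "G1")
  expect_equal(sum(tab), 10)
  expect_equal(tab["yes", "yes"], 3L)
  expect_equal(tab["yes", "no"], 0L)
  expect_equal(tab["no", "yes"], 3L)
  expect_equal(tab["no", "no"], 4L)

  # every sample a carrier: bottom row zeros
  tab_all <- pp_contingency(samples, mat, "G1")
  expect_equal(unname(tab_all["no", ]), c(0L, 0L))

  expect_error(pp_contingency(character(0), mat, "G1"), "no carriers")
  expect_error(pp_contingency("S1", mat, "NOPE"), "not in PP matrix")
})

test_that("the cohort-scale worked example forces the published cell counts", {
  samples <- sprintf("P%05d", 1:13307)
  pp_carriers <- samples[1:6234]
  mat <- pp_matrix_fixture(samples, pp_carriers, gene = "PRKRA")
  carriers <- samples[1:461] # all variant carriers sit inside the PP group
  tab <- pp_contingency(carriers, mat, "PRKRA")
  expect_equal(unname(tab), matrix(c(461L, 0L, 5773L, 7073L), nrow = 2, byrow = TRUE))
  res <- chi_squared_test(tab)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 0.05)
  # cross-checks: stats::chisq.test and a permutation null under fixed margins
  expect_equal(
    res$statistic,
    unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
  )
  withr::with_seed(101, {
    sims <- stats::r2dtable(1e5, rowSums(tab), colSums(tab))
    stat_sim <- vapply(sims, function(t) chi_squared_test(t)$statistic, numeric(1))
    p_perm <- (1 + sum(stat_sim >= res$statistic)) / (1e5 + 1)
    expect_lt(p_perm, 0.05)
  })
})

test_that("closed-form chi-squared values match hand arithmetic", {
  r <- chi_squared_test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(r$statistic, 20.0)
  expect_lt(r$p_value, 0.05)

  r0 <- chi_squared_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  expect_error(chi_squared_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "zero margin")
})

test_that("chi-squared is invariant under swapping both row and column labels", {
  withr::with_seed(111, {
    for (i in 1:25) {
      tab <- matrix(rpois(4, 8) + 1, 2)
      swapped <- tab[2:1, 2:1]
      expect_equal(
        chi_squared_test(tab)$statistic,
        chi_squared_test(swapped)$statistic
      )
    }
  })
})

test_that("junction-adjacent, PP-restricted, low-AB variants are flagged; ordinary hets are not", {
  m <- three_exon_gene(gene_id = "G1")
  samples <- paste0("S", 1:40)
  pp_carriers <- paste0("S", 1:20)
  mat <- pp_matrix_fixture(samples, pp_carriers)

  # artifact: sits on the junction at 0-based 100 (pos 101), carried only by
  # PP carriers, AB near 0.3
  artifact_obs <- tibble::tibble(
    sample_id = pp_carriers, chrom = "chr1", pos = 101L, ref = "G", alt = "A",
    genotype = "het", ad_ref = 31L, ad_alt = 13L
  )
  # genuine variant: mid-exon (pos 251, distance 50), carriers split across
  # groups, AB 0.5
  true_obs <- tibble::tibble(
    sample_id = c("S1", "S2", "S21", "S22"), chrom = "chr1", pos = 251L,
    ref = "C", alt = "T", genotype = "het", ad_ref = 15L, ad_alt = 15L
  )
  clinical <- tibble::tibble(
    chrom = "chr1", pos = c(101L, 251L), ref = c("G", "C"), alt = c("A", "T"),
    gene_id = "G1", label = c("LP", "P")
  )
  v <- flag_variants(clinical, m, mat, dplyr::bind_rows(artifact_obs, true_obs))
  expect_equal(v$flag, c("likely_pp_artifact", "not_flagged"))
  expect_equal(v$junction_distance, c(0L, 50L))
  expect_equal(v$n_carriers_with_pp, c(20L, 2L))
  expect_equal(round(v$mean_carrier_ab, 2), c(0.30, 0.50))
  expect_true(v$p_value[1] < 0.05)
  expect_false(isTRUE(v$assoc_ok[2]))
})

test_that("an unevaluable criterion is dropped from the conjunction, not failed", {
  m <- three_exon_gene(gene_id = "G1")
  samples <- paste0("S", 1:10)
  mat <- pp_matrix_fixture(samples, carriers = paste0("S", 1:4))
  # observations lack usable AD (zero depth) -> AB criterion unevaluable
  obs <- tibble::tibble(
    sample_id = paste0("S", 1:4), chrom = "chr1", pos = 101L, ref = "G", alt = "A",
    genotype = "het", ad_ref = 0L, ad_alt = 0L
  )
  clinical <- tibble::tibble(
    chrom = "chr1", pos = 101L, ref = "G", alt = "A", gene_id = "G1", label = "LP"
  )
  v <- flag_variants(clinical, m, mat, obs)
  expect_true(is.na(v$mean_carrier_ab))
  expect_equal(v$flag, "likely_pp_artifact") # junction + association still hold
})

test_that("moving a carrier into the PP group never unflags an artifact", {
  m <- three_exon_gene(gene_id = "G1")
  samples <- paste0("S", 1:30)
  obs <- tibble::tibble(
    sample_id = paste0("S", 1:10), chrom = "chr1", pos = 101L, ref = "G", alt = "A",
    genotype = "het", ad_ref = 30L, ad_alt = 14L
  )
  clinical <- tibble::tibble(
    chrom = "chr1", pos = 101L, ref = "G", alt = "A", gene_id = "G1", label = "LP"
  )
  # start with 9 of 10 carriers in the PP group (plus 5 non-carrier PP samples)
  for (k in 9:10) {
    mat <- pp_matrix_fixture(samples, carriers = c(paste0("S", 1:k), paste0("S", 26:30)))
    v <- flag_variants(clinical, m, mat, obs)
    if (k == 9) expect_equal(v$flag, "likely_pp_artifact")
    if (k == 10) expect_equal(v$flag, "likely_pp_artifact") # strictly more enriched
  }
})

test_that("simulated artifacts are all flagged and genuine variants all pass", {
  genes <- tibble::tibble(
    gene_id = sprintf("FG%02d", 1:50), n_exons = 4L, exon_len = 150L,
    intron_len = 1000L, pp_allele_freq = 0.3
  )
  p <- sim_params(
    n_samples = 60, genes = genes, true_clinical_rate = 0.4, seed = 121
  )
  sim <- simulate_cohort(p)
  calls <- detect_pp(sim$deletions, sim$gene_models)
  mat <- cohort_pp_matrix(calls,
    samples = sprintf("S%04d", 1:60),
    genes = sim$gene_models$gene_id
  )
  v <- flag_variants(sim$clinical, sim$gene_models, mat, sim$variants)
  joined <- dplyr::inner_join(
    dplyr::as_tibble(v), sim$clinical,
    by = c("chrom", "pos", "ref", "alt", "gene_id")
  ) |>
    dplyr::filter(n_carriers > 0)
  artifacts <- dplyr::filter(joined, truth == "pp_artifact")
  genuine <- dplyr::filter(joined, truth == "true_variant")
  expect_equal(nrow(artifacts), 50L)
  expect_true(all(artifacts$flag == "likely_pp_artifact"))
  expect_true(all(genuine$flag == "not_flagged"))
})

test_that("the FP report keeps zero-flag callers and shared flags tabulate identically", {
  flags <- tibble::tibble(
    caller = c(rep("GATK-HC", 5), rep("DRAGEN-EM", 4)),
    gene_id = c("RBBP7", "RBBP7", "WDR43", "MTMR2", "CLIP1", "RBBP7", "RBBP7", "WDR43", "MTMR2"),
    sample_id = c("a", "b", "c", "d", "e", "a", "b", "c", "d")
  )
  rep <- fp_report(flags, n_samples = 100, callers = "DeepVariant")
  counts <- tidy(rep)
  dv <- dplyr::filter(counts, caller == "DeepVariant")
  expect_true(all(dv$n_flagged == 0L))
  shared <- counts |>
    dplyr::filter(gene_id %in% c("RBBP7", "WDR43", "MTMR2"), caller != "DeepVariant") |>
    tidyr::pivot_wider(names_from = caller, values_from = n_flagged)
  expect_equal(shared$`GATK-HC`, shared$`DRAGEN-EM`)
  summ <- glance(rep)
  expect_equal(summ$n_flagged_samples[summ$caller == "GATK-HC"], 5L)
  expect_equal(summ$pct_samples[summ$caller == "GATK-HC"], 5)
  expect_equal(summ$pct_samples[summ$caller == "DeepVariant"], 0)

  one <- fp_report(
    tibble::tibble(caller = "GATK-HC", gene_id = "PRKRA", sample_id = c("x", "y", "z")),
    n_samples = 10
  )
  expect_equal(tidy(one)$n_flagged, 3L)
})
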