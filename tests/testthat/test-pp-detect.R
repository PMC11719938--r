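test_that("SV VCF parsing converts coordinates and filters by SVTYPE", {
  vcf <- write_tmp_vcf(c(
    "chr1\t1001\td1\tN\t<DEL>\t99\tPASS\tSVTYPE=DEL;END=2000\tGT\t0/1",
    "chr1\t300\tu1\tN\t<DUP>\t99\tPASS\tSVTYPE=DUP;END=900\tGT\t0/1",
    "chr1\t101\td2\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;SVLEN=-500\tGT\t0/1"
  ))
  d <- read_sv_deletions(vcf, sample_id = "S1")
  expect_equal(d$sv_id, c("d1", "d2")) # record order preserved
  expect_equal(d$start, c(1000L, 100L))
  expect_equal(d$end, c(2000L, 600L))
  expect_false("u1" %in% d$sv_id)
})

test_that("records without END or SVLEN are skipped with a warning", {
  vcf <- write_tmp_vcf(c(
    "chr1\t1001\td1\tN\t<DEL>\t99\tPASS\tSVTYPE=DEL;END=2000\tGT\t0/1",
    "chr1\t5000\tbad\tN\t<DEL>\t99\tPASS\tSVTYPE=DEL\tGT\t0/1"
  ))
  expect_warning(d <- read_sv_deletions(vcf, sample_id = "S1"), "without END or SVLEN")
  expect_equal(d$sv_id, "d1")
})

test_that("FILTER policy excludes failing records unless 'all' is requested", {
  vcf <- write_tmp_vcf(c(
    "chr1\t1001\tok\tN\t<DEL>\t99\tPASS\tSVTYPE=DEL;END=2000\tGT\t0/1",
    "chr1\t3001\tlowq\tN\t<DEL>\t5\tLowQual\tSVTYPE=DEL;END=4000\tGT\t0/1"
  ))
  expect_equal(read_sv_deletions(vcf, "S1")$sv_id, "ok")
  expect_setequal(read_sv_deletions(vcf, "S1", filter = "all")$sv_id, c("ok", "lowq"))
})

test_that("a non-VCF stream is rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines("this is not a vcf", path)
  expect_error(read_sv_deletions(path), "not a VCF")
})

test_that("breakpoint-anchored matching accepts tolerance but rejects spanning deletions", {
  expect_true(match_deletion_to_intron(100, 200, 100, 200, tol = 10))
  expect_true(match_deletion_to_intron(95, 206, 100, 200, tol = 10))
  expect_false(match_deletion_to_intron(89, 200, 100, 200, tol = 10))
  # deletion spanning both introns of a two-intron gene matches neither
  m <- three_exon_gene()
  intr <- m$introns[[1]]
  expect_equal(
    match_deletion_to_intron(50, 400, intr$start, intr$end, tol = 10),
    c(FALSE, FALSE)
  )
})

test_that("matching agrees with brute-force enumeration over random (deletion, intron) pairs", {
  withr::with_seed(21, {
    intr <- tibble::tibble(start = c(100L, 300L, 800L), end = c(200L, 400L, 1200L))
    for (i in 1:300) {
      ds <- sample(0:1300, 1)
      de <- ds + sample(1:1300, 1)
      tol <- sample(0:25, 1)
      got <- match_deletion_to_intron(ds, de, intr$start, intr$end, tol)
      want <- vapply(
        seq_len(nrow(intr)),
        function(k) abs(ds - intr$start[k]) <= tol && abs(de - intr$end[k]) <= tol,
        logical(1)
      )
      expect_identical(got, want)
    }
  })
})

test_that("verdicts follow the matched-intron threshold", {
  # gene with 4 introns at known places
  m <- gene_models(tibble::tibble(
    gene_id = "G4I", chrom = "chr1",
    start = seq(0L, 4000L, by = 1000L), end = seq(100L, 4100L, by = 1000L)
  ))
  intr <- m$introns[[1]]
  all4 <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = intr$start + 2L, end = intr$end - 3L,
    sv_id = paste0("d", 1:4), qual = 99, filter = "PASS"
  )
  calls <- detect_pp(all4, m)
  expect_equal(calls$verdict, "PP_present")
  expect_equal(calls$n_introns_matched, 4L)
  expect_equal(calls$matched_introns[[1]], 1:4)

  one <- all4[1, ]
  expect_equal(detect_pp(one, m)$verdict, "no_PP")
  expect_equal(detect_pp(one, m, min_matched_introns = 1)$verdict, "PP_present")

  # single-intron gene can never reach a 2-intron threshold
  m1 <- gene_models(tibble::tibble(
    gene_id = "G1I", chrom = "chr1", start = c(0L, 200L), end = c(100L, 300L)
  ))
  d1 <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = 100L, end = 200L,
    sv_id = "d", qual = 99, filter = "PASS"
  )
  expect_equal(detect_pp(d1, m1)$verdict, "undetectable")
})

test_that("empty gene set warns and yields no calls", {
  empty <- gene_models(tibble::tibble(
    gene_id = character(), chrom = character(), start = integer(), end = integer()
  ))
  d <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = 1L, end = 10L,
    sv_id = "d", qual = 1, filter = "PASS"
  )
  expect_warning(calls <- detect_pp(d, empty), "empty gene set")
  expect_equal(nrow(calls), 0L)
})

test_that("detection matches a brute-force oracle on random small cohorts", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n_genes <- sample(3:8, 1)
      exons <- purrr::map(seq_len(n_genes), function(g) {
        n_ex <- sample(2:5, 1)
        base <- (g - 1) * 20000L
        starts <- base + (seq_len(n_ex) - 1L) * 1000L
        tibble::tibble(
          gene_id = paste0("g", g), chrom = "chr1",
          start = starts, end = starts + 300L
        )
      })
      m <- gene_models(dplyr::bind_rows(exons))
      all_introns <- dplyr::bind_rows(purrr::map2(
        m$introns, m$chrom, ~ dplyr::mutate(.x, chrom = .y)
      ))
      dels <- purrr::map(1:15, function(s) {
        n_d <- sample(0:6, 1)
        if (n_d == 0) {
          return(NULL)
        }
        picked <- all_introns[sample(nrow(all_introns), n_d, replace = TRUE), ]
        tibble::tibble(
          sample_id = sprintf("s%02d", s), chrom = picked$chrom,
          start = picked$start + sample(-15:15, n_d, replace = TRUE),
          end = picked$end + sample(-15:15, n_d, replace = TRUE),
          sv_id = paste0("d", seq_len(n_d)), qual = 99, filter = "PASS"
        )
      })
      dels <- dplyr::bind_rows(dels)
      got <- detect_pp(dels, m) |>
        dplyr::as_tibble() |>
        dplyr::select(sample_id, gene_id, n_introns_matched, verdict)
      want <- brute_force_pp(dels, m)
      expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
    }
  })
})

test_that("detection is invariant to VCF record order and monotone in added evidence", {
  withr::with_seed(41, {
    m <- three_exon_gene()
    intr <- m$introns[[1]]
    dels <- tibble::tibble(
      sample_id = "S1", chrom = "chr1",
      start = c(intr$start + 1L, 700L), end = c(intr$end - 1L, 900L),
      sv_id = paste0("d", 1:3), qual = 99, filter = "PASS"
    )
    base <- detect_pp(dels, m)
    shuffled <- detect_pp(dels[sample(nrow(dels)), ], m)
    expect_equal(as.data.frame(base), as.data.frame(shuffled))

    # adding one more matching intronic deletion never demotes PP_present
    for (k in seq_len(nrow(intr))) {
      extra <- tibble::tibble(
        sample_id = "S1", chrom = "chr1",
        start = intr$start[k] + 2L, end = intr$end[k] + 1L,
        sv_id = "extra", qual = 99, filter = "PASS"
      )
      augmented <- detect_pp(dplyr::bind_rows(dels, extra), m)
      expect_equal(augmented$verdict, "PP_present")
      expect_gte(augmented$n_introns_matched, base$n_introns_matched)
    }
  })
})

test_that("the cohort matrix counts carriers and deduplicates repeated calls", {
  calls <- detect_pp(
    tibble::tibble(
      sample_id = c("S1", "S1", "S2"), chrom = "chr1",
      start = c(100L, 300L, 700L), end = c(200L, 400L, 900L),
      sv_id = paste0("d", 1:3), qual = 99, filter = "PASS"
    ),
    three_exon_gene()
  )
  mat <- cohort_pp_matrix(calls, samples = c("S1", "S2", "S3"))
  expect_equal(mat$G3X, c(1L, 0L, 0L))
  freq <- pp_frequency(mat)
  expect_equal(freq$frequency, 100 / 3)

  dup <- dplyr::bind_rows(calls, calls)
  class(dup) <- class(calls)
  expect_warning(cohort_pp_matrix(dup, samples = c("S1", "S2")), "deduplicated")

  # degenerate frequencies: no carriers and universal carriage
  none <- cohort_pp_matrix(calls[0, ], samples = c("S1", "S2"), genes = "G3X")
  expect_equal(pp_frequency(none)$frequency, 0)
  all_s <- calls |>
    dplyr::mutate(sample_id = "S1") |>
    dplyr::bind_rows(dplyr::mutate(calls, sample_id = "S2"))
  class(all_s) <- class(calls)
  expect_equal(pp_frequency(cohort_pp_matrix(all_s))$frequency, 100)
})

test_that("glance and tidy summarise the cohort matrix", {
  calls <- detect_pp(
    tibble::tibble(
      sample_id = "S1", chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L),
      sv_id = c("a", "b"), qual = 99, filter = "PASS"
    ),
    three_exon_gene()
  )
  mat <- cohort_pp_matrix(calls, samples = c("S1", "S2"))
  g <- glance(mat)
  expect_equal(g$n_samples, 2L)
  expect_equal(g$pct_samples_with_pp, 50)
  long <- tidy(mat)
  expect_equal(nrow(long), 2L)
  expect_setequal(names(long), c("sample_id", "gene_id", "pp_present"))
})

test_that("novelty report splits detected genes into annotated and novel", {
  rep <- pp_novel_report(c("a", "b", "c", "d"), known = c("b", "z"))
  expect_equal(rep$n_detected, 4L)
  expect_equal(rep$n_known, 1L)
  expect_equal(rep$n_novel, 3L)
  expect_equal(rep$novel_genes[[1]], c("a", "c", "d"))
})
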