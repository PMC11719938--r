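# shared in-code fixtures and independent oracles

# three-exon gene on [0,100) [200,300) [400,500): introns [100,200) [300,400)
three_exon_gene <- function(gene_id = "G3X", chrom = "chr1", offset = 0L) {
  gene_models(tibble::tibble(
    gene_id = gene_id, chrom = chrom,
    start = offset + c(0L, 200L, 400L),
    end = offset + c(100L, 300L, 500L)
  ))
}

write_tmp_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_vcf <- function(body, header = sv_vcf_header()) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(header, body), path)
  path
}

sv_vcf_header <- function(sample = "S1") {
  c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##INFO=<ID=SVLEN,Number=.,Type=Integer,Description="Length">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
}

small_vcf_header <- function(sample = "S1") {
  c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
}

# variant-observation tibble straight from AD counts
ad_variants <- function(ad_ref, ad_alt, genotype = "het", sample_id = "S1",
                        gene_id = "G1", pos = seq_along(ad_ref)) {
  tibble::tibble(
    sample_id = sample_id, gene_id = gene_id, chrom = "chr1", pos = pos,
    ref = "A", alt = "G", genotype = genotype,
    ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt)
  )
}

# brute-force PP caller: loops over every (deletion, intron) pair
brute_force_pp <- function(deletions, models, min_matched_introns = 2, tol = 10) {
  rows <- list()
  for (s in unique(deletions$sample_id)) {
    ds <- deletions[deletions$sample_id == s, , drop = FALSE]
    for (gi in seq_len(nrow(models))) {
      g <- models[gi, ]
      intr <- g$introns[[1]]
      matched <- integer(0)
      if (nrow(intr) > 0 && nrow(ds) > 0) {
        for (k in seq_len(nrow(intr))) {
          for (r in seq_len(nrow(ds))) {
            if (ds$chrom[r] == g$chrom &&
              abs(ds$start[r] - intr$start[k]) <= tol &&
              abs(ds$end[r] - intr$end[k]) <= tol) {
              matched <- union(matched, k)
            }
          }
        }
      }
      if (length(matched) > 0) {
        verdict <- if (g$n_introns < min_matched_introns) {
          "undetectable"
        } else if (length(matched) >= min_matched_introns) "PP_present" else "no_PP"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = s, gene_id = g$gene_id,
          n_introns_matched = length(matched), verdict = verdict
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), sample_id, gene_id)
}

# independent Pearson statistic via the n(ad-bc)^2 / product-of-margins identity
chisq_by_margins_identity <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
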