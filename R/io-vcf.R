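#' Read deletion calls from a structural-variant VCF
#'
#' Parses a Smoove/LUMPY-dialect SV VCF and returns the deletion records
#' (`SVTYPE=DEL`) as 0-based half-open intervals. The deleted region is taken
#' as `[POS-1, END)` when INFO `END` is present, otherwise `[POS-1,
#' POS-1+|SVLEN|)`; records carrying neither are skipped with a warning.
#' Records failing the FILTER policy are excluded.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param sample_id sample label for the returned calls; defaults to the VCF's
#'   single genotype column name, or the file's base name if it has none.
#' @param filter `"pass"` keeps records with FILTER `PASS` or `.` (default);
#'   `"all"` keeps everything.
#' @return tibble with one row per deletion: `sample_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `sv_id`, `qual`, `filter`.
#' @export
read_sv_deletions <- function(path, sample_id = NULL, filter = c("pass", "all")) {
  filter <- match.arg(filter)
  v <- read_vcfr(path)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(sample_id)) sample_id <- default_sample_id(v, path)
  if (nrow(fix) == 0L) {
    return(empty_deletions())
  }
  info <- vcfR::extract_info_tidy(v)
  info_col <- function(nm) {
    if (nm %in% names(info)) info[[nm]] else rep(NA, nrow(fix))
  }
  svtype <- as.character(info_col("SVTYPE"))
  endi <- suppressWarnings(as.integer(as.character(info_col("END"))))
  svlen <- suppressWarnings(as.integer(as.character(info_col("SVLEN"))))

  keep <- !is.na(svtype) & svtype == "DEL"
  if (filter == "pass") {
    keep <- keep & (is.na(fix$FILTER) | fix$FILTER %in% c("PASS", "."))
  }
  pos <- as.integer(fix$POS)
  no_coords <- keep & is.na(endi) & is.na(svlen)
  if (any(no_coords)) {
    warn(sprintf("%d DEL record(s) without END or SVLEN skipped", sum(no_coords)))
    keep <- keep & !no_coords
  }
  start0 <- pos - 1L
  end0 <- ifelse(!is.na(endi), endi, start0 + abs(svlen))
  out <- tibble(
    sample_id = sample_id,
    chrom = fix$CHROM[keep],
    start = as.integer(start0[keep]),
    end = as.integer(end0[keep]),
    sv_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
      paste0("del", which(keep)), fix$ID[keep]
    ),
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    filter = coalesce(fix$FILTER[keep], ".")
  )
  if (any(out$end <= out$start)) abort("DEL record with non-positive length")
  out
}

empty_deletions <- function() {
  tibble(
    sample_id = character(), chrom = character(), start = integer(),
    end = integer(), sv_id = character(), qual = numeric(), filter = character()
  )
}

#' Read small-variant observations from a VCF
#'
#' Extracts per-variant genotype and allelic-depth context from a VCF with
#' `GT` and `AD` FORMAT fields. Multiallelic records are split per ALT allele,
#' with `ad_alt` taken from that allele's AD entry. The genotype is classified
#' per ALT: two copies of the allele give `hom_alt`, one copy `het`, none (or
#' missing GT) `other`.
#'
#' @inheritParams read_sv_deletions
#' @return tibble: `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `genotype`, `ad_ref`, `ad_alt`.
#' @export
read_small_variants <- function(path, sample_id = NULL) {
  v <- read_vcfr(path)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(sample_id)) sample_id <- default_sample_id(v, path)
  if (nrow(fix) == 0L) {
    return(empty_variants())
  }
  gt <- as.character(vcfR::extract.gt(v, element = "GT")[, 1L])
  ad <- as.character(vcfR::extract.gt(v, element = "AD")[, 1L])

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- suppressWarnings(as.integer(strsplit(ad[i] %||% "", ",", fixed = TRUE)[[1]]))
    alleles <- gt_alleles(gt[i])
    purrr::map(seq_along(alts), function(k) {
      geno <- classify_genotype(alleles, k)
      tibble(
        sample_id = sample_id,
        chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i],
        alt = alts[[k]],
        genotype = geno,
        ad_ref = if (length(ads) >= 1L) ads[[1L]] else NA_integer_,
        ad_alt = if (length(ads) >= k + 1L) ads[[k + 1L]] else NA_integer_
      )
    })
  })
  bind_rows(purrr::flatten(rows))
}

empty_variants <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), genotype = character(),
    ad_ref = integer(), ad_alt = integer()
  )
}

gt_alleles <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
    return(integer())
  }
  suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
}

classify_genotype <- function(alleles, alt_index) {
  if (length(alleles) == 0L || anyNA(alleles)) {
    return("other")
  }
  n_alt <- sum(alleles == alt_index)
  if (n_alt >= 2L) "hom_alt" else if (n_alt == 1L) "het" else "other"
}

read_vcfr <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, "##fileformat=VCF")) {
    abort(paste0("not a VCF stream: ", path))
  }
  vcfR::read.vcfR(path, verbose = FALSE)
}

default_sample_id <- function(v, path) {
  samples <- colnames(v@gt)
  samples <- setdiff(samples, "FORMAT")
  if (length(samples) == 1L) samples else sub("\\.vcf(\\.gz)?$", "", basename(path))
}

# ---- writers (Smoove-style SV dialect and GT:AD small-variant dialect) ----

vcf_header <- function(chrom_len, extra = character(), sample_id = "SAMPLE") {
  c(
    "##fileformat=VCFv4.2",
    "##source=ppsieve",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_len), as.integer(chrom_len)),
    extra,
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id
    )
  )
}

#' Write deletion calls as a Smoove-dialect SV VCF
#'
#' Inverse of [read_sv_deletions()]: each 0-based half-open interval becomes a
#' `SVTYPE=DEL` record with `POS = start+1`, INFO `END` and negative `SVLEN`.
#'
#' @param deletions tibble as returned by [read_sv_deletions()].
#' @param path output file.
#' @param sample_id genotype column name; defaults to the calls' sample_id.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(deletions, path, sample_id = NULL) {
  sample_id <- sample_id %||%
    (if (nrow(deletions)) deletions$sample_id[[1]] else "SAMPLE")
  chrom_len <- chrom_lengths(deletions$chrom, deletions$end)
  hdr <- vcf_header(chrom_len, extra = c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVLEN,Number=.,Type=Integer,Description="Difference in length between REF and ALT">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), sample_id = sample_id)
  body <- character(0)
  if (nrow(deletions)) {
    d <- arrange(deletions, .data$chrom, .data$start)
    body <- sprintf(
      "%s\t%d\t%s\tN\t<DEL>\t%s\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d\tGT\t0/1",
      d$chrom, d$start + 1L, d$sv_id,
      ifelse(is.na(d$qual), ".", format(d$qual, trim = TRUE)),
      d$end, d$end - d$start
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write small-variant observations as a GT:AD VCF
#'
#' Inverse of [read_small_variants()] for biallelic records.
#'
#' @param variants tibble as returned by [read_small_variants()].
#' @param path output file.
#' @param sample_id genotype column name; defaults to the variants' sample_id.
#' @return `path`, invisibly.
#' @export
write_small_vcf <- function(variants, path, sample_id = NULL) {
  sample_id <- sample_id %||%
    (if (nrow(variants)) variants$sample_id[[1]] else "SAMPLE")
  chrom_len <- chrom_lengths(variants$chrom, variants$pos)
  hdr <- vcf_header(chrom_len, extra = c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">'
  ), sample_id = sample_id)
  body <- character(0)
  if (nrow(variants)) {
    d <- arrange(variants, .data$chrom, .data$pos)
    gt <- dplyr::case_match(d$genotype,
      "het" ~ "0/1", "hom_alt" ~ "1/1", .default = "./."
    )
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t99\tPASS\t.\tGT:AD\t%s:%d,%d",
      d$chrom, d$pos, d$ref, d$alt, gt, d$ad_ref, d$ad_alt
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

chrom_lengths <- function(chrom, last_coord) {
  if (length(chrom) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tapply(as.integer(last_coord) + 1000L, chrom, max)
}
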