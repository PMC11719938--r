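#' Build gene models from an exon table
#'
#' Constructs one gene model per gene from a table of exon intervals. Exons
#' from all transcripts are unioned into a merged, non-overlapping, sorted
#' projection; introns are the gaps between consecutive merged exons; junctions
#' are the exon boundaries interior to the gene (two per intron). Coordinates
#' are 0-based half-open throughout (the BED / depth-track convention);
#' [read_gene_models()] converts from the 1-based GTF/GFF3 convention on entry.
#'
#' Genes whose merged projection has a single exon have no introns and are
#' marked not detectable: the intronic-deletion signature of a processed
#' pseudogene cannot exist for them.
#'
#' @param exons data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `gene_name`, `strand`.
#' @return A `pp_gene_models` tibble with one row per gene: `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `span_start`, `span_end`, `n_exons`,
#'   `n_introns`, `detectable`, and list-columns `exons`, `introns` (tibbles
#'   with `start`, `end`) and `junctions` (integer positions).
#' @examples
#' ex <- tibble::tibble(
#'   gene_id = "G1", chrom = "chr1",
#'   start = c(0, 200, 400), end = c(100, 300, 500)
#' )
#' gene_models(ex)$introns[[1]]
#' @export
gene_models <- function(exons) {
  exons <- as_tibble(exons)
  req <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols)) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"gene_name" %in% names(exons)) exons$gene_name <- exons$gene_id
  if (!"strand" %in% names(exons)) exons$strand <- "*"
  if (any(exons$start >= exons$end)) abort("exon intervals must satisfy start < end")
  if (any(!nzchar(exons$chrom))) abort("chrom must be non-empty")
  if (nrow(exons) == 0L) {
    return(new_tibble_subclass(tibble(
      gene_id = character(), gene_name = character(), chrom = character(),
      strand = character(), span_start = integer(), span_end = integer(),
      n_exons = integer(), n_introns = integer(), detectable = logical(),
      exons = list(), introns = list(), junctions = list()
    ), "pp_gene_models"))
  }

  models <- exons |>
    group_by(.data$gene_id) |>
    group_modify(function(d, key) {
      if (length(unique(d$chrom)) > 1L) {
        abort(paste0("gene ", key$gene_id, " has exons on multiple chromosomes"))
      }
      merged <- merge_intervals(d$start, d$end)
      introns <- interval_gaps(merged)
      junctions <- sort(c(introns$start, introns$end))
      tibble(
        gene_name = d$gene_name[[1]],
        chrom = d$chrom[[1]],
        strand = d$strand[[1]],
        span_start = min(merged$start),
        span_end = max(merged$end),
        n_exons = nrow(merged),
        n_introns = nrow(introns),
        detectable = nrow(introns) > 0L,
        exons = list(merged),
        introns = list(introns),
        junctions = list(as.integer(junctions))
      )
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$span_start, .data$gene_id)

  new_tibble_subclass(models, "pp_gene_models")
}

# merged union of intervals, sorted; IRanges does the reduction
merge_intervals <- function(start, end) {
  r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = as.integer(IRanges::start(r) - 1L), end = as.integer(IRanges::end(r)))
}

interval_gaps <- function(merged) {
  if (nrow(merged) < 2L) {
    return(tibble(start = integer(), end = integer()))
  }
  tibble(
    start = merged$end[-nrow(merged)],
    end = merged$start[-1L]
  )
}

#' Read gene models from a GTF or GFF3 annotation
#'
#' Parses an annotation file (GENCODE-style GTF with `gene_id` / `gene_name`
#' attributes, or GFF3 carrying `gene_id`), keeps `exon` features, and builds
#' merged gene models with [gene_models()]. Genes that appear only as `gene`
#' features with no exon rows are skipped with a warning.
#'
#' @param path annotation file (`.gtf`, `.gff`, `.gff3`; format sniffed from
#'   the extension unless given).
#' @param format `"auto"`, `"gtf"` or `"gff3"`.
#' @param chr_prefix chromosome-name normalization: `"asis"` (exact match,
#'   default), `"add"` (prefix bare names with `"chr"`), or `"strip"`.
#' @return A `pp_gene_models` tibble (see [gene_models()]).
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "gff3"),
                             chr_prefix = c("asis", "add", "strip")) {
  format <- match.arg(format)
  chr_prefix <- match.arg(chr_prefix)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  gr <- if (format == "auto") {
    rtracklayer::import(path)
  } else {
    rtracklayer::import(path, format = ifelse(format == "gff3", "gff3", "gtf"))
  }
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% names(mc) || !"gene_id" %in% names(mc)) {
    abort("annotation lacks feature types or gene_id attributes")
  }
  is_exon <- as.character(mc$type) == "exon"
  exon_gr <- gr[is_exon]
  exon_mc <- S4Vectors::mcols(exon_gr)
  gene_feature_ids <- unique(as.character(mc$gene_id[as.character(mc$type) == "gene"]))
  exon_gene_ids <- unique(as.character(exon_mc$gene_id))
  orphans <- setdiff(gene_feature_ids, exon_gene_ids)
  if (length(orphans)) {
    warn(paste0(
      length(orphans), " gene(s) with zero exon features skipped: ",
      paste(head(orphans, 5L), collapse = ", ")
    ))
  }
  if (length(exon_gr) == 0L) abort("annotation contains no exon features")
  gname <- if ("gene_name" %in% names(exon_mc)) as.character(exon_mc$gene_name) else NA_character_
  exons <- tibble(
    gene_id = as.character(exon_mc$gene_id),
    gene_name = coalesce(gname, as.character(exon_mc$gene_id)),
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(exon_gr)), chr_prefix),
    strand = as.character(GenomicRanges::strand(exon_gr)),
    start = as.integer(GenomicRanges::start(exon_gr) - 1L),
    end = as.integer(GenomicRanges::end(exon_gr))
  )
  gene_models(exons)
}

normalize_chrom <- function(chrom, chr_prefix = c("asis", "add", "strip")) {
  chr_prefix <- match.arg(chr_prefix)
  switch(chr_prefix,
    asis = chrom,
    add = ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom)),
    strip = sub("^chr", "", chrom)
  )
}

#' Write gene models as a GENCODE-style GTF
#'
#' Emits one `gene` line and one `exon` line per merged exon, with `gene_id`
#' and `gene_name` attributes, 1-based inclusive coordinates. Re-reading the
#' output with [read_gene_models()] reproduces the models exactly.
#'
#' @param models a `pp_gene_models` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(models, path) {
  stopifnot(inherits(models, "pp_gene_models"))
  lines <- c("##format: gtf")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    attr_str <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    st <- if (g$strand %in% c("+", "-")) g$strand else "."
    lines <- c(lines, sprintf(
      "%s\tppsieve\tgene\t%d\t%d\t.\t%s\t.\t%s",
      g$chrom, g$span_start + 1L, g$span_end, st, attr_str
    ))
    ex <- g$exons[[1]]
    lines <- c(lines, sprintf(
      "%s\tppsieve\texon\t%d\t%d\t.\t%s\t.\t%s transcript_id \"%s.t1\";",
      g$chrom, ex$start + 1L, ex$end, st, attr_str, g$gene_id
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Dump gene models as a BED12-like table
#'
#' One row per gene: chrom, span (0-based half-open), gene_id, gene_name,
#' strand, exon count and comma-separated exon block sizes/starts — handy for
#' eyeballing models or loading them in a genome browser.
#'
#' @param models a `pp_gene_models` tibble.
#' @param path output TSV; when `NULL` the tibble is returned instead.
#' @return the dump tibble (invisibly when written to `path`).
#' @export
write_gene_models <- function(models, path = NULL) {
  stopifnot(inherits(models, "pp_gene_models"))
  dump <- models |>
    mutate(
      block_sizes = map_chr(.data$exons, ~ paste(.x$end - .x$start, collapse = ",")),
      block_starts = map2_chr(.data$exons, .data$span_start, ~ paste(.x$start - .y, collapse = ","))
    ) |>
    transmute(
      chrom = .data$chrom, start = .data$span_start, end = .data$span_end,
      gene_id = .data$gene_id, gene_name = .data$gene_name, strand = .data$strand,
      n_exons = .data$n_exons, block_sizes = .data$block_sizes,
      block_starts = .data$block_starts
    )
  if (is.null(path)) {
    return(dump)
  }
  readr::write_tsv(dump, path)
  invisible(dump)
}

#' Distance from a position to the nearest intron-exon junction
#'
#' Junctions are the exon boundaries interior to the gene (0-based boundary
#' coordinates; two per intron). The 1-based input position is converted to
#' 0-based and the minimum absolute distance to any junction is returned; a
#' position sitting on a junction boundary base scores 0. Pseudogene-derived
#' artifact variants characteristically sit on these junctions.
#'
#' @param models a `pp_gene_models` tibble.
#' @param gene_id gene identifier(s), recycled against `pos`.
#' @param pos 1-based position(s); must fall within the gene span.
#' @return integer vector of distances in bp.
#' @export
nearest_junction_distance <- function(models, gene_id, pos) {
  stopifnot(inherits(models, "pp_gene_models"))
  n <- max(length(gene_id), length(pos))
  gene_id <- rep_len(gene_id, n)
  pos <- rep_len(as.numeric(pos), n)
  idx <- match(gene_id, models$gene_id)
  if (anyNA(idx)) {
    abort(paste0("unknown gene_id: ", paste(unique(gene_id[is.na(idx)]), collapse = ", ")))
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    g <- models[idx[i], ]
    p0 <- pos[i] - 1
    if (p0 < g$span_start || p0 >= g$span_end) {
      abort(sprintf("position %d outside span of gene %s", as.integer(pos[i]), gene_id[i]))
    }
    j <- g$junctions[[1]]
    if (length(j) == 0L) {
      abort(paste0("gene ", gene_id[i], " has no junctions (single merged exon)"))
    }
    out[i] <- as.integer(min(abs(p0 - j)))
  }
  out
}

#' @importFrom purrr map2_chr
new_tibble_subclass <- function(x, cls) {
  class(x) <- c(cls, class(tibble()))
  x
}

#' @export
print.pp_gene_models <- function(x, ...) {
  cat(sprintf(
    "# Gene models: %d gene(s), %d detectable (>=1 intron)\n",
    nrow(x), sum(x$detectable)
  ))
  NextMethod()
}
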