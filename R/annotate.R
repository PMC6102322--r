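# Candidate-gene annotation of called regions.
#
# Gene models come in as BED (0-based half-open) or GFF3 (1-based
# inclusive); both are converted to the package-wide 1-based inclusive
# convention at the parser boundary. A gene is reported for a region when
# their closed intervals share at least one base pair — partial overlap
# suffices.

#' Read gene intervals from BED or GFF3
#'
#' BED coordinates are shifted to 1-based inclusive on input; GFF3 is
#' already 1-based inclusive. For GFF3, rows with `type == "gene"` are
#' used when present (otherwise all rows), and the gene name is taken
#' from the first available of the `Name`, `gene`, `ID` attributes.
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Data frame with columns `gene_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `strand` (1-based inclusive coordinates).
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff3"
  }
  if (format == "bed") {
    bed <- utils::read.table(path, header = FALSE, sep = "\t",
                             colClasses = "character", comment.char = "#")
    genes <- data.frame(
      gene_id = if (ncol(bed) >= 4) bed[[4]] else paste0("iv", seq_len(nrow(bed))),
      chromosome = bed[[1]],
      start_bp = as.integer(bed[[2]]) + 1L,   # 0-based half-open -> 1-based
      end_bp = as.integer(bed[[3]]),
      strand = if (ncol(bed) >= 6) bed[[6]] else "*",
      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md) && any(md$type == "gene"))
      gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
    name <- rep(NA_character_, length(gr))
    for (field in c("ID", "gene", "Name"))   # increasing preference
      if (field %in% names(md)) {
        v <- as.character(md[[field]])
        name[!is.na(v) & nzchar(v)] <- v[!is.na(v) & nzchar(v)]
      }
    name[is.na(name)] <- paste0("iv", which(is.na(name)))
    genes <- data.frame(
      gene_id = name,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  }
  if (any(genes$start_bp > genes$end_bp)) stopf("gene interval with start > end")
  genes
}

#' Genes overlapping called regions
#'
#' Reports every (region, gene) pair whose closed 1-based intervals on the
#' same chromosome intersect in at least one base pair. Implemented with
#' `GenomicRanges::findOverlaps`. Region chromosome labels absent from
#' the gene set (a symptom of mismatched naming schemes such as `"chr1"`
#' vs `"1"`) trigger a warning listing the unmatched labels.
#'
#' @param regions A `region_set` from [call_regions()] (or any data frame
#'   with `chromosome`, `start_bp`, `end_bp`).
#' @param genes Gene intervals from [read_gene_intervals()].
#' @return Data frame with one row per overlapping pair: `region_index`,
#'   `chromosome`, `start_bp`, `end_bp`, `gene_id`, `gene_start_bp`,
#'   `gene_end_bp`.
#' @export
overlap_genes <- function(regions, genes) {
  empty <- data.frame(region_index = integer(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      gene_id = character(), gene_start_bp = integer(),
                      gene_end_bp = integer())
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(empty)
  mism <- setdiff(unique(regions$chromosome), unique(genes$chromosome))
  if (length(mism))
    warnf("region chromosome labels absent from the gene set: %s",
          paste(mism, collapse = ", "))

  seqs <- union(unique(regions$chromosome), unique(genes$chromosome))
  gr_r <- GenomicRanges::GRanges(
    factor(regions$chromosome, levels = seqs),
    IRanges::IRanges(regions$start_bp, regions$end_bp))
  gr_g <- GenomicRanges::GRanges(
    factor(genes$chromosome, levels = seqs),
    IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(region_index = ri,
                    chromosome = regions$chromosome[ri],
                    start_bp = regions$start_bp[ri],
                    end_bp = regions$end_bp[ri],
                    gene_id = genes$gene_id[gi],
                    gene_start_bp = genes$start_bp[gi],
                    gene_end_bp = genes$end_bp[gi])
  out[order(out$region_index, out$gene_start_bp), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}
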