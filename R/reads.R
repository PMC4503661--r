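#' Read aligned reads from BAM or BED
#'
#' Reads are represented as a `GRangesList` with one element per read holding
#' its aligned blocks (split/junction-spanning reads have more than one
#' block). For BAM the blocks come from the CIGAR (`N` gaps separate blocks);
#' for BED12 from the block fields; BED6 lines are single-block reads.
#'
#' @param path Path to a BAM or BED file.
#' @param format `"auto"` (from extension), `"bam"` or `"bed"`.
#' @param sample_id Sample label stored in `metadata()`; defaults to the file
#'   name without extension.
#' @param min_mapq Optional minimum mapping quality (BAM only); `NULL`
#'   (default) keeps all records, matching an unfiltered analysis.
#' @return A `GRangesList` of read blocks; `metadata()` holds `sample_id`.
#' @export
read_alignments <- function(path, format = c("auto", "bam", "bed"),
                            sample_id = NULL, min_mapq = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bam = "bam", bed = "bed",
                     stop("cannot infer alignment format from '", ext, "'"))
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "bam") {
    param <- Rsamtools::ScanBamParam(
      mapqFilter = if (is.null(min_mapq)) NA_integer_ else as.integer(min_mapq))
    aln <- GenomicAlignments::readGAlignments(path, param = param)
    reads <- GenomicAlignments::grglist(aln)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (!is.null(mcols(gr)$blocks)) {
      reads <- rtracklayer::blocks(gr)
    } else {
      ex <- granges(gr)
      mcols(ex) <- NULL
      reads <- GenomicRanges::split(ex, seq_along(ex))
      names(reads) <- NULL
    }
  }
  reads <- validate_reads(reads)
  metadata(reads)$sample_id <- sample_id
  reads
}

#' Validate a set of read blocks
#'
#' Checks the block invariants: every read has at least one block, all blocks
#' of a read share one chromosome and strand, and blocks are sorted and
#' non-overlapping. Blocks are re-sorted into genomic order if needed.
#'
#' @param reads A `GRangesList` (blocks per read) or a `GRanges` of
#'   single-block reads (converted).
#' @return The validated `GRangesList`.
#' @export
validate_reads <- function(reads) {
  if (is(reads, "GRanges")) {
    reads <- as(reads, "GRangesList")
  }
  if (!is(reads, "GRangesList")) stop("reads must be a GRangesList or GRanges")
  if (any(lengths(reads) == 0L)) stop("read with zero blocks")
  if (any(lengths(unique(seqnames(reads))) != 1L) ||
      any(lengths(unique(strand(reads))) != 1L))
    stop("read with blocks on multiple chromosomes or strands")
  reads <- sort(reads)
  multi <- lengths(reads) > 1L
  if (any(multi) && !all(IRanges::isDisjoint(reads[multi])))
    stop("read with overlapping blocks")
  reads
}

#' Extend single-block reads to a fixed length
#'
#' ChIP-seq fragments are longer than the sequenced read; each read is
#' therefore anchored at its 5' end (strand-aware) and lengthened in the 3'
#' direction to `target_len` before computing coverage. Reads already at
#' least `target_len` long are returned unchanged, and multi-block (split)
#' reads are an error: extension applies only to contiguous ChIP reads.
#'
#' @param reads `GRanges` of single-block reads, or a `GRangesList` whose
#'   elements all have exactly one block.
#' @param target_len Target read length in bp (default 150).
#' @param chrom_sizes Optional named vector of chromosome lengths; extended
#'   reads are clipped at chromosome bounds.
#' @return Object of the same class as `reads` with extended coordinates.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 136), "+")
#' extend_reads(gr)  # 101..250 (150 bp, 5' anchored)
#' @export
extend_reads <- function(reads, target_len = 150L, chrom_sizes = NULL) {
  if (!is.numeric(target_len) || target_len <= 0)
    stop("target_len must be > 0")
  was_list <- is(reads, "GRangesList")
  if (was_list) {
    if (any(lengths(reads) > 1L))
      stop("cannot extend multi-block (split) reads")
    meta <- metadata(reads)
    nm <- names(reads)
    reads <- unlist(reads, use.names = FALSE)
  }
  out <- suppressWarnings(
    resize(reads, width = pmax(width(reads), as.integer(target_len)),
           fix = "start"))   # strand-aware: fix = 5' end
  if (!is.null(chrom_sizes)) {
    sl <- unname(chrom_sizes[as.character(seqnames(out))])
    suppressWarnings({
      end(out) <- pmin(end(out), sl)
      start(out) <- pmax(start(out), 1L)
    })
  } else if (!any(is.na(seqlengths(out)))) {
    out <- trim(out)
  }
  if (was_list) {
    out <- as(out, "GRangesList")
    names(out) <- nm
    metadata(out) <- meta
  }
  out
}
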