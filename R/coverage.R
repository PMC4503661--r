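#' Per-base coverage from read blocks
#'
#' The value at a base is the number of read blocks overlapping it, so the
#' genome-wide sum of the track equals the summed block lengths. Reads
#' extending past a declared chromosome end are clipped with a warning.
#'
#' @param reads `GRangesList` of read blocks (or `GRanges` of single-block
#'   reads).
#' @param chrom_sizes Named integer vector of chromosome lengths. If `NULL`,
#'   lengths are taken from the reads' `seqinfo` or, failing that, the
#'   largest end coordinate observed per chromosome.
#' @return An `RleList` (one `Rle` per chromosome) of raw counts;
#'   `metadata()` carries `library_size` (number of reads) and
#'   `units = "raw"`.
#' @export
coverage_from_reads <- function(reads, chrom_sizes = NULL) {
  reads <- validate_reads(reads)
  n_reads <- length(reads)
  blocks <- unlist(reads, use.names = FALSE)
  if (is.null(chrom_sizes)) {
    sl <- GenomeInfoDb::seqlengths(blocks)
    if (any(is.na(sl))) {
      obs <- tapply(end(blocks), as.character(seqnames(blocks)), max)
      sl[is.na(sl)] <- obs[names(sl)[is.na(sl)]]
    }
    chrom_sizes <- sl
  }
  chroms <- as.character(seqnames(blocks))
  if (length(blocks) && !all(chroms %in% names(chrom_sizes)))
    stop("reads on undeclared chromosomes: ",
         paste(unique(setdiff(chroms, names(chrom_sizes))), collapse = ", "))
  if (length(blocks)) {
    beyond <- end(blocks) > chrom_sizes[chroms] | start(blocks) < 1L
    if (any(beyond)) {
      warning(sum(beyond), " read block(s) beyond chromosome ends were clipped")
      end(blocks) <- pmin(end(blocks), chrom_sizes[chroms])
      start(blocks) <- pmax(start(blocks), 1L)
    }
  }
  ir_by_chr <- S4Vectors::split(ranges(blocks),
                                factor(chroms, levels = names(chrom_sizes)))
  track <- IRanges::coverage(ir_by_chr, width = as.list(chrom_sizes))
  metadata(track) <- list(library_size = n_reads, units = "raw")
  track
}

#' Normalise a coverage track to reads per million (RPM)
#'
#' @param track An `RleList` from [coverage_from_reads()].
#' @param library_size Total mapped reads; defaults to the value recorded on
#'   the track. Must be > 0.
#' @return The track scaled by `1e6 / library_size`, `units = "rpm"`.
#' @export
rpm_normalize <- function(track, library_size = NULL) {
  library_size <- library_size %||% metadata(track)$library_size
  if (is.null(library_size) || !is.numeric(library_size) || library_size <= 0)
    stop("library_size must be a positive number")
  meta <- metadata(track)
  out <- track * (1e6 / library_size)
  meta$units <- "rpm"
  meta$library_size <- library_size
  metadata(out) <- meta
  out
}

#' Count reads per annotated feature
#'
#' A read increments a feature when any of its blocks overlaps the feature by
#' at least 1 bp; a read overlapping several features increments all of them
#' (any-overlap, multi-assignment). Counting uses the raw, unextended reads.
#'
#' @param reads `GRangesList` of read blocks (or `GRanges`).
#' @param features Named `GRanges` (one row per feature) or `GRangesList`
#'   (exons per feature; length is then the summed exon length). Feature IDs
#'   must be unique.
#' @return A `data.frame` with columns `feature_id`, `length_bp`, `count`,
#'   ordered lexicographically by feature ID.
#' @export
count_reads_per_feature <- function(reads, features) {
  reads <- validate_reads(reads)
  ids <- names(features)
  if (is.null(ids)) stop("features must be named")
  if (anyDuplicated(ids)) stop("duplicate feature IDs: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  counts <- countOverlaps(features, reads, ignore.strand = TRUE)
  len <- if (is(features, "GRangesList")) sum(width(features)) else width(features)
  out <- data.frame(feature_id = ids, length_bp = as.integer(len),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  out[order(out$feature_id), , drop = FALSE]
}

#' Reads per kilobase of feature per million mapped reads
#'
#' `RPKM = count * 1e9 / (length_bp * library_size)`.
#'
#' @param count Non-negative read count(s).
#' @param length_bp Feature length(s) in bp, > 0.
#' @param library_size Total mapped reads, > 0.
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(count < 0)) stop("counts must be non-negative")
  if (any(length_bp <= 0)) stop("feature length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count * 1e9 / (length_bp * library_size)
}
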