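#' Extract a strand-oriented coverage window around an anchor
#'
#' Returns the `2 * width + 1` coverage values centred on the anchor. For `-`
#' strand anchors the vector is reversed so the first value is always the
#' farthest upstream position in transcription sense. Window positions that
#' fall outside the chromosome contribute 0.
#'
#' @param track `RleList` coverage track (typically RPM).
#' @param chrom Chromosome name.
#' @param anchor 1-based anchor position (e.g. a TSS from [tss()]).
#' @param strand `"+"`, `"-"` or `"*"` (treated as `"+"`).
#' @param width Half-window size W in bp (default 600).
#' @return Numeric vector of length `2 * width + 1`, offsets `-W..W` in
#'   transcription sense.
#' @export
extract_window <- function(track, chrom, anchor, strand = "+", width = 600L) {
  if (!chrom %in% names(track)) stop("chromosome '", chrom, "' not in track")
  rle <- track[[chrom]]
  chrlen <- length(rle)
  if (anchor < 1L || anchor > chrlen)
    stop("anchor ", anchor, " off chromosome '", chrom, "' (length ", chrlen, ")")
  lo <- anchor - width
  hi <- anchor + width
  vals <- numeric(2L * width + 1L)
  from <- max(1L, lo)
  to <- min(chrlen, hi)
  vals[(from - lo + 1L):(to - lo + 1L)] <-
    as.numeric(IRanges::Views(rle, start = from, end = to)[[1L]])
  if (strand == "-") vals <- rev(vals)
  vals
}

#' Metagene profile of a gene group
#'
#' Averages strand-oriented coverage windows over all anchors of a group:
#' for each offset in `-W..W` relative to the anchor (TSS), the profile is
#' the mean RPM over anchors, mirroring per-base metagene averaging of
#' ChIP-seq enrichment around transcription start sites.
#'
#' @param track `RleList` RPM coverage track.
#' @param anchors Width-1 `GRanges` of anchors (see
#'   [anchors_from_annotation()]); `metadata()` may carry `group_name` and
#'   `n_features`.
#' @param width Half-window size W in bp (default 600).
#' @param sample_id Optional sample label.
#' @return An object of class `metagene_profile`: a `data.frame` with
#'   columns `offset` (-W..W) and `mean_rpm`, with attributes `group_name`,
#'   `n_features` and `sample_id`.
#' @export
metagene_profile <- function(track, anchors, width = 600L, sample_id = NULL) {
  if (length(anchors) == 0L) stop("anchor set is empty")
  wins <- vapply(seq_along(anchors), function(i) {
    extract_window(track, as.character(seqnames(anchors)[i]),
                   start(anchors)[i], as.character(strand(anchors)[i]),
                   width = width)
  }, numeric(2L * width + 1L))
  prof <- data.frame(offset = seq(-width, width),
                     mean_rpm = rowMeans(wins))
  attr(prof, "group_name") <- metadata(anchors)$group_name %||% "group"
  attr(prof, "n_features") <- length(anchors)
  attr(prof, "sample_id") <- sample_id
  class(prof) <- c("metagene_profile", "data.frame")
  prof
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("Metagene profile: ", attr(x, "group_name"),
      " (n = ", attr(x, "n_features"), " features",
      if (!is.null(attr(x, "sample_id")))
        paste0(", sample ", attr(x, "sample_id")), ")\n", sep = "")
  w <- (nrow(x) - 1L) / 2L
  cat("  offsets ", -w, "..", w, " bp; mean RPM range [",
      signif(min(x$mean_rpm), 4), ", ", signif(max(x$mean_rpm), 4), "]\n",
      sep = "")
  invisible(x)
}
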