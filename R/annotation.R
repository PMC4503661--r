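#' Load a transcript annotation
#'
#' Reads gene/transcript models from BED (6 or 12 column), GFF3 or GTF and
#' returns exons grouped by transcript. GFF/GTF 1-based inclusive coordinates
#' and BED 0-based half-open coordinates are both converted by rtracklayer to
#' the package-internal `GRanges` (1-based inclusive) representation, so a BED
#' line `chr1 100 200` becomes the range 101..200.
#'
#' For BED, each line is one transcript; BED12 block fields become exons
#' (otherwise the whole interval is a single exon). For GFF3, `exon` features
#' are grouped by their `Parent`; for GTF by `transcript_id`.
#'
#' @param path Path to the annotation file.
#' @param format One of `"auto"` (default, from file extension), `"bed"`,
#'   `"gff3"`, `"gtf"`.
#' @return A named `GRangesList`, one element per transcript holding its exons
#'   sorted in genomic order. Strand is recorded on every exon.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tgeneA\t0\t+", bed)
#' tx <- load_annotation(bed)
#' start(tx[["geneA"]])  # 101 (BED 0-based 100)
#' @export
load_annotation <- function(path, format = c("auto", "bed", "gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bed = "bed", gff = "gff3", gff3 = "gff3", gtf = "gtf",
      stop("cannot infer annotation format from extension '", ext,
           "'; pass format= explicitly"))
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(trimws(lines), "#"))) {
    warning("annotation file '", path, "' contains no features")
    return(GRangesList())
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  tx <- switch(format,
    bed  = .transcripts_from_bed(gr),
    gff3 = .transcripts_from_gff3(gr, path),
    gtf  = .transcripts_from_gtf(gr))
  .validate_transcripts(tx)
  tx
}

.transcripts_from_bed <- function(gr) {
  ids <- mcols(gr)$name
  if (is.null(ids) || anyNA(ids)) ids <- paste0("feature_", seq_along(gr))
  if (anyDuplicated(ids)) stop("duplicate transcript IDs in BED: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(mcols(gr)$blocks)) {
    exons <- rtracklayer::blocks(gr)   # absolute genomic coordinates
    names(exons) <- ids
    exons
  } else {
    ex <- granges(gr)
    mcols(ex) <- NULL
    grl <- GenomicRanges::split(ex, factor(ids, levels = ids))
    grl
  }
}

.transcripts_from_gff3 <- function(gr, path) {
  ex <- gr[mcols(gr)$type == "exon"]
  if (length(ex) == 0L) stop("GFF3 file contains no exon features")
  parents <- mcols(ex)$Parent
  if (any(lengths(parents) == 0L)) stop("GFF3 exon without Parent attribute")
  ex <- rep(ex, lengths(parents))
  tx_id <- unlist(parents, use.names = FALSE)
  ## exons must fall inside the declared span of their parent feature
  parent_feats <- gr[!is.na(mcols(gr)$ID) & mcols(gr)$ID %in% unique(tx_id)]
  if (length(parent_feats)) {
    span <- setNames(paste0(seqnames(parent_feats), ":", start(parent_feats),
                            "-", end(parent_feats)), mcols(parent_feats)$ID)
    ps <- setNames(start(parent_feats), mcols(parent_feats)$ID)
    pe <- setNames(end(parent_feats), mcols(parent_feats)$ID)
    known <- tx_id %in% names(ps)
    bad <- known & (start(ex) < ps[tx_id] | end(ex) > pe[tx_id])
    if (any(bad)) stop("exon outside declared parent span for: ",
                       paste(unique(tx_id[bad]), collapse = ", "))
  }
  ex <- granges(ex)
  mcols(ex) <- NULL
  GenomicRanges::split(ex, tx_id)
}

.transcripts_from_gtf <- function(gr) {
  ex <- gr[mcols(gr)$type == "exon"]
  if (length(ex) == 0L) stop("GTF file contains no exon features")
  tx_id <- mcols(ex)$transcript_id
  if (is.null(tx_id) || anyNA(tx_id)) stop("GTF exon without transcript_id")
  ex <- granges(ex)
  mcols(ex) <- NULL
  GenomicRanges::split(ex, tx_id)
}

.validate_transcripts <- function(tx) {
  if (any(lengths(tx) == 0L)) stop("transcript with no exons")
  one_chr <- all(lengths(unique(GenomicRanges::seqnames(tx))) == 1L)
  one_str <- all(lengths(unique(GenomicRanges::strand(tx))) == 1L)
  if (!one_chr || !one_str)
    stop("transcript with exons on multiple chromosomes or strands")
  invisible(tx)
}

#' Transcription start sites of transcript models
#'
#' The TSS is the 5'-most exonic base in transcription sense: the lowest
#' coordinate for `+` (and unstranded) transcripts, the highest for `-`.
#'
#' @param transcripts A `GRangesList` of exons per transcript, as returned by
#'   [load_annotation()].
#' @return A named width-1 `GRanges` of TSS positions (one per transcript).
#' @export
tss <- function(transcripts) {
  if (length(transcripts) == 0L) return(GRanges())
  rng <- unlist(range(transcripts))
  minus <- as.character(strand(rng)) == "-"
  pos <- ifelse(minus, end(rng), start(rng))
  GRanges(seqnames(rng), IRanges(pos, width = 1L), strand = strand(rng),
          seqinfo = seqinfo(rng))
}

#' Build a TSS anchor set for a gene group
#'
#' Resolves a vector of feature IDs against transcript models and returns
#' their TSS positions as anchors for metagene profiling.
#'
#' @param transcripts `GRangesList` of exons per transcript.
#' @param group_ids Character vector of transcript IDs; every ID must resolve.
#' @param group_name Label stored on the result (e.g. `"RP genes"`).
#' @return A width-1 `GRanges` of anchors with `metadata()` fields
#'   `group_name` and `n_features`.
#' @export
anchors_from_annotation <- function(transcripts, group_ids,
                                    group_name = "group") {
  if (length(group_ids) == 0L) stop("empty gene group '", group_name, "'")
  missing <- setdiff(group_ids, names(transcripts))
  if (length(missing)) stop("unresolved IDs in group '", group_name, "': ",
                            paste(missing, collapse = ", "))
  anchors <- tss(transcripts[group_ids])
  metadata(anchors) <- list(group_name = group_name,
                            n_features = length(group_ids))
  anchors
}
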