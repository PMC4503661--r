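#' Enumerate splicing units from transcript models
#'
#' A splicing unit is one annotated intron together with its two flanking
#' exons (the donor exon ends at the junction's 5' side in transcription
#' sense, the acceptor exon starts at its 3' side). Intronless transcripts
#' contribute no units.
#'
#' @param transcripts `GRangesList` of exons per transcript
#'   (see [load_annotation()]).
#' @return A `GRanges` of introns (the spliced-out gap), with metadata
#'   columns `unit_id`, `transcript_id`, and the genomic coordinates of the
#'   flanking exons (`donor_start`, `donor_end`, `acceptor_start`,
#'   `acceptor_end`, 1-based inclusive). Units are numbered in transcription
#'   order within each transcript.
#' @export
units_from_annotation <- function(transcripts) {
  .validate_transcripts(transcripts)
  res <- list()
  for (tx_id in names(transcripts)) {
    ex <- sort(transcripts[[tx_id]])
    if (!IRanges::isDisjoint(ranges(ex)))
      stop("overlapping exons in transcript '", tx_id, "'")
    n <- length(ex)
    if (n < 2L) next
    minus <- as.character(strand(ex)[1L]) == "-"
    i5 <- seq_len(n - 1L)            # genomic-left exon of each gap
    gap_start <- end(ex)[i5] + 1L
    gap_end <- start(ex)[i5 + 1L] - 1L
    if (any(gap_end < gap_start))
      stop("adjacent exons without intron gap in transcript '", tx_id, "'")
    intron_no <- if (minus) rev(seq_len(n - 1L)) else seq_len(n - 1L)
    ## donor = upstream exon in transcription sense
    don <- if (minus) ex[i5 + 1L] else ex[i5]
    acc <- if (minus) ex[i5] else ex[i5 + 1L]
    gr <- GRanges(seqnames(ex)[i5], IRanges(gap_start, gap_end),
                  strand = strand(ex)[i5])
    mcols(gr) <- S4Vectors::DataFrame(
      unit_id = paste0(tx_id, ".I", intron_no),
      transcript_id = tx_id,
      donor_start = start(don), donor_end = end(don),
      acceptor_start = start(acc), acceptor_end = end(acc))
    res[[tx_id]] <- gr
  }
  if (length(res) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(
      unit_id = character(), transcript_id = character(),
      donor_start = integer(), donor_end = integer(),
      acceptor_start = integer(), acceptor_end = integer())
    return(gr)
  }
  unname(do.call(c, unname(res)))
}

#' Junction support from split reads
#'
#' Counts, per splicing unit, the reads with two consecutive blocks whose
#' inner gap matches the annotated intron exactly (a `tolerance` in bp may
#' relax the boundary match). Matching is on coordinates, ignoring strand.
#'
#' @param reads `GRangesList` of read blocks.
#' @param units `GRanges` of splicing units from [units_from_annotation()].
#' @param tolerance Maximum allowed shift (bp) of each junction boundary
#'   (default 0 = exact).
#' @return Integer vector of junction-spanning read counts, one per unit.
#' @export
junction_support <- function(reads, units, tolerance = 0L) {
  reads <- validate_reads(reads)
  if (length(units) == 0L) return(integer())
  multi <- reads[lengths(reads) > 1L]
  if (length(multi) == 0L) return(integer(length(units)))
  gaps <- unlist(IRanges::psetdiff(unlist(range(multi)), multi),
                 use.names = FALSE)
  if (tolerance == 0L) {
    counts <- countOverlaps(units, gaps, type = "equal", ignore.strand = TRUE)
  } else {
    hits <- findOverlaps(units, gaps, ignore.strand = TRUE)
    ok <- abs(start(units)[queryHits(hits)] - start(gaps)[subjectHits(hits)]) <= tolerance &
          abs(end(units)[queryHits(hits)] - end(gaps)[subjectHits(hits)]) <= tolerance
    counts <- tabulate(queryHits(hits)[ok], nbins = length(units))
  }
  as.integer(counts)
}

#' Mean per-base coverage over a unit's flanking exons
#'
#' Sums the read-block coverage over every base of the donor and acceptor
#' exons and divides by their total length, giving the exonic mean coverage
#' that forms the PSO denominator.
#'
#' @inheritParams junction_support
#' @return Numeric vector, one mean coverage value per unit.
#' @export
exonic_unit_coverage <- function(reads, units) {
  reads <- validate_reads(reads)
  if (length(units) == 0L) return(numeric())
  m <- mcols(units)
  exons <- GRanges(rep(seqnames(units), 2L),
                   IRanges(c(m$donor_start, m$acceptor_start),
                           c(m$donor_end, m$acceptor_end)))
  unit_idx <- rep(seq_along(units), 2L)
  total_len <- (m$donor_end - m$donor_start + 1L) +
               (m$acceptor_end - m$acceptor_start + 1L)
  if (any(total_len <= 0)) stop("unit with zero total exon length")
  blocks <- unlist(reads, use.names = FALSE)
  covered <- numeric(length(units))
  if (length(blocks)) {
    hits <- findOverlaps(exons, blocks, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- pmin(end(exons)[queryHits(hits)], end(blocks)[subjectHits(hits)]) -
            pmax(start(exons)[queryHits(hits)], start(blocks)[subjectHits(hits)]) + 1L
      agg <- tapply(ov, unit_idx[queryHits(hits)], sum)
      covered[as.integer(names(agg))] <- agg
    }
  }
  covered / total_len
}

#' Percent Spliced Out
#'
#' `PSO = 100 * junction_cov / exonic_cov`: the junction-spanning read count
#' relative to the mean coverage of the flanking exons. PSO is not capped at
#' 100 (short exons with deep junction support can exceed it). When the
#' exonic coverage is 0 the value is missing (`NA`, not 0) with reason
#' `"no coverage"`.
#'
#' @param junction_cov Junction support value(s) (>= 0).
#' @param exonic_cov Mean exonic coverage value(s) (>= 0).
#' @return Numeric percent vector; `NA` where `exonic_cov == 0`, with
#'   attribute `reason` marking those entries.
#' @export
pso <- function(junction_cov, exonic_cov) {
  if (any(junction_cov < 0) || any(exonic_cov < 0))
    stop("coverage values must be >= 0")
  out <- ifelse(exonic_cov > 0, 100 * junction_cov / exonic_cov, NA_real_)
  if (any(exonic_cov == 0))
    attr(out, "reason") <- ifelse(exonic_cov == 0, "no coverage", "")
  out
}

#' Per-sample PSO table for a set of splicing units
#'
#' @param reads_by_sample Named list of `GRangesList` read sets, one per
#'   sample.
#' @param units `GRanges` of splicing units.
#' @param tolerance Junction boundary tolerance passed to
#'   [junction_support()].
#' @return `data.frame`: `unit_id`, one PSO column per sample, and a
#'   `low_confidence` flag (`TRUE` when any sample's exonic coverage is below
#'   1 read-per-base equivalent).
#' @export
pso_table <- function(reads_by_sample, units, tolerance = 0L) {
  if (is.null(names(reads_by_sample)) || anyDuplicated(names(reads_by_sample)))
    stop("reads_by_sample must be a uniquely named list")
  vals <- lapply(reads_by_sample, function(rd) {
    jc <- junction_support(rd, units, tolerance = tolerance)
    ec <- exonic_unit_coverage(rd, units)
    list(pso = as.numeric(pso(jc, ec)), ec = ec)
  })
  out <- data.frame(unit_id = mcols(units)$unit_id, stringsAsFactors = FALSE)
  for (s in names(vals)) out[[s]] <- vals[[s]]$pso
  out$low_confidence <- Reduce(`|`, lapply(vals, function(v) v$ec < 1))
  out
}

#' Per-unit ANOVA on PSO across genotypes
#'
#' Fits a one-way fixed-effects ANOVA of PSO against genotype for every
#' splicing unit and adjusts the p-values across units with
#' Benjamini-Hochberg. Units with any missing PSO are dropped with a message.
#'
#' @param pso_tab `data.frame` with `unit_id` and one PSO column per sample
#'   (see [pso_table()]).
#' @param genotypes Named character vector mapping sample column names to
#'   genotype labels; at least 2 genotypes with at least 2 replicates each.
#' @return `data.frame`: `unit_id`, per-genotype mean PSO, `f_stat`, `p`,
#'   `adj_p` (BH across all tested units).
#' @export
pso_anova <- function(pso_tab, genotypes) {
  samples <- names(genotypes)
  if (is.null(samples) || !all(samples %in% names(pso_tab)))
    stop("genotypes must be named by sample columns of pso_tab")
  geno <- factor(unname(genotypes))
  if (nlevels(geno) < 2L) stop("need at least 2 genotypes")
  if (any(table(geno) < 2L)) stop("need at least 2 replicates per genotype")
  mat <- as.matrix(pso_tab[, samples, drop = FALSE])
  keep <- rowSums(is.na(mat)) == 0L
  if (any(!keep))
    message(sum(!keep), " unit(s) dropped: missing PSO (no coverage)")
  mat <- mat[keep, , drop = FALSE]
  stats_mat <- t(apply(mat, 1L, function(y) .oneway_f(y, geno)))
  means <- t(apply(mat, 1L, function(y) tapply(y, geno, mean)))
  colnames(means) <- paste0("mean_", levels(geno))
  out <- data.frame(unit_id = pso_tab$unit_id[keep], means,
                    f_stat = stats_mat[, 1L], p = stats_mat[, 2L],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$adj_p <- bh_adjust(out$p)
  out
}

## one-way fixed-effects ANOVA; degenerate variance handled explicitly
.oneway_f <- function(y, g) {
  k <- nlevels(g); n <- length(y)
  gm <- tapply(y, g, mean); ni <- tabulate(g)
  ssb <- sum(ni * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  if (ssb <= .Machine$double.eps * sum(y^2 + 1)) return(c(f = 0, p = 1))
  if (ssw == 0) return(c(f = Inf, p = 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  c(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
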