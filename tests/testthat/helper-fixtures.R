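# in-code fixtures; no files on disk except tempfiles written by the tests

library(GenomicRanges)

gr1 <- function(chrom, start, end, strand = "+") {
  GRanges(chrom, IRanges(start, end), strand = strand)
}

# single-block reads from a start/end table
mk_reads <- function(starts, ends, chrom = "chr1", strand = "+") {
  as(GRanges(chrom, IRanges(starts, ends), strand = strand), "GRangesList")
}

# one multi-block read
mk_split_read <- function(block_starts, block_ends, chrom = "chr1",
                          strand = "+") {
  GRangesList(GRanges(chrom, IRanges(block_starts, block_ends),
                      strand = strand))
}

# two-exon + strand transcript annotation around one intron
toy_two_exon_tx <- function(id = "txA", chrom = "chr1",
                            e1 = c(101, 200), intron = c(201, 300),
                            e2 = c(301, 450), strand = "+") {
  tx <- GRangesList(GRanges(chrom, IRanges(c(e1[1], e2[1]),
                                           c(e1[2], e2[2])), strand = strand))
  names(tx) <- id
  tx
}

write_bed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

write_gff3 <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}
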