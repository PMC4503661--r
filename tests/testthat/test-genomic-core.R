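test_that("BED annotation keeps coordinates and strand, GFF3 is converted", {
  bed <- write_bed("chr1\t100\t200\tgeneA\t0\t+")
  tx <- load_annotation(bed)
  expect_named(tx, "geneA")
  expect_equal(start(tx[["geneA"]]), 101)  # BED 0-based start 100
  expect_equal(end(tx[["geneA"]]), 200)
  expect_equal(start(tss(tx)), 101)

  gff <- write_gff3(c(
    "chr1\tsrc\tmRNA\t101\t200\t.\t-\t.\tID=geneB",
    "chr1\tsrc\texon\t101\t200\t.\t-\t.\tParent=geneB"))
  tx2 <- load_annotation(gff)
  expect_equal(start(tx2[["geneB"]]), 101)
  expect_equal(end(tx2[["geneB"]]), 200)
  expect_equal(start(tss(tx2)), 200)       # minus strand: TSS at high end
  expect_equal(as.character(strand(tss(tx2))), "-")
})

test_that("annotation validation catches structural errors", {
  gff <- write_gff3(c(
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=geneC",
    "chr1\tsrc\texon\t101\t250\t.\t+\t.\tParent=geneC"))
  expect_error(load_annotation(gff), "outside declared parent span")

  bed <- write_bed(c("chr1\t0\t100\tdup\t0\t+", "chr1\t200\t300\tdup\t0\t+"))
  expect_error(load_annotation(bed), "duplicate")

  empty <- write_bed("# just a comment")
  expect_warning(tx <- load_annotation(empty), "no features")
  expect_length(tx, 0)
})

test_that("read extension is 5'-anchored and strand-aware", {
  # 0-based (100,136,+) -> (100,250): 1-based 101..136 -> 101..250
  plus <- gr1("chr1", 101, 136, "+")
  expect_equal(ranges(extend_reads(plus, 150)), IRanges(101, 250))
  # 0-based (500,536,-) -> (386,536): 1-based 501..536 -> 387..536
  minus <- gr1("chr1", 501, 536, "-")
  expect_equal(ranges(extend_reads(minus, 150)), IRanges(387, 536))
  # already long enough: unchanged
  long <- gr1("chr1", 101, 250, "+")
  expect_identical(ranges(extend_reads(long, 150)), IRanges(101, 250))
  # extension preserves the 5' coordinate
  expect_equal(start(extend_reads(plus, 150)), start(plus))
  expect_equal(end(extend_reads(minus, 150)), end(minus))
  # clipping at chromosome bounds
  near_end <- gr1("chr1", 951, 986, "+")
  ext <- extend_reads(near_end, 150, chrom_sizes = c(chr1 = 1000))
  expect_equal(end(ext), 1000)
  # multi-block reads refuse extension
  split <- mk_split_read(c(1, 100), c(50, 150))
  expect_error(extend_reads(split, 150), "multi-block")
  expect_error(extend_reads(plus, 0), "target_len")
})

test_that("coverage equals brute-force per-base overlap counting", {
  # 3 staggered reads on a 20-bp toy chromosome
  starts <- c(1, 5, 10); ends <- c(8, 14, 20)
  reads <- mk_reads(starts, ends)
  track <- coverage_from_reads(reads, c(chr1 = 20))
  expect_equal(as.numeric(track[["chr1"]]), brute_coverage(starts, ends, 20))
  # additivity at a shared base and conservation of block length
  expect_equal(sum(as.numeric(track[["chr1"]])), sum(ends - starts + 1))
  expect_identical(S4Vectors::metadata(track)$library_size, 3L)
  # no reads -> all-zero track
  empty <- coverage_from_reads(GRangesList(), c(chr1 = 20))
  expect_equal(sum(as.numeric(empty[["chr1"]])), 0)
  # reads beyond the chromosome end are clipped with a warning
  expect_warning(
    tr <- coverage_from_reads(mk_reads(15, 30), c(chr1 = 20)),
    "clipped")
  expect_equal(as.numeric(tr[["chr1"]]), c(rep(0, 14), rep(1, 6)))
})

test_that("coverage conservation holds on random multi-block fixtures", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    starts <- sample(1:800, n)
    ends <- pmin(starts + sample(10:120, n, replace = TRUE), 1000)
    reads <- mk_reads(starts, ends)
    track <- coverage_from_reads(reads, c(chr1 = 1000))
    expect_equal(sum(as.numeric(track[["chr1"]])), sum(ends - starts + 1))
  }
})

test_that("RPM normalisation scales by 1e6 / library size", {
  reads <- mk_reads(c(1, 1, 1, 1), c(10, 10, 10, 10))
  track <- coverage_from_reads(reads, c(chr1 = 20))
  rpm <- rpm_normalize(track, library_size = 2e6)
  expect_equal(as.numeric(rpm[["chr1"]])[1], 4 * 1e6 / 2e6)  # value 4 -> 2
  ident <- rpm_normalize(track, library_size = 1e6)
  expect_equal(as.numeric(ident[["chr1"]]), as.numeric(track[["chr1"]]))
  expect_error(rpm_normalize(track, library_size = 0), "positive")
  # invariance: duplicating every read and doubling library size
  reads2 <- mk_reads(rep(c(1, 1, 1, 1), 2), rep(10, 8))
  rpm2 <- rpm_normalize(coverage_from_reads(reads2, c(chr1 = 20)),
                        library_size = 4e6)
  expect_equal(as.numeric(rpm2[["chr1"]]), as.numeric(rpm[["chr1"]]))
})

test_that("feature counting matches the brute-force overlap oracle", {
  feats <- GRanges("chr1", IRanges(c(1, 101, 201), c(100, 200, 300)))
  names(feats) <- c("geneA", "geneB", "geneC")
  # read inside geneA
  expect_equal(count_reads_per_feature(mk_reads(10, 50), feats)$count,
               c(1L, 0L, 0L))
  # boundary-straddling read increments both features
  expect_equal(count_reads_per_feature(mk_reads(95, 110), feats)$count,
               c(1L, 1L, 0L))
  # 10 random reads vs brute force
  set.seed(5)
  starts <- sample(1:280, 10); ends <- pmin(starts + 30, 300)
  tab <- count_reads_per_feature(mk_reads(starts, ends), feats)
  blocks <- lapply(seq_along(starts), function(i)
    data.frame(start = starts[i], end = ends[i]))
  expect_equal(tab$count,
               as.integer(brute_count(blocks, start(feats), end(feats))))
  # duplicate IDs are an error
  names(feats) <- c("dup", "dup", "geneC")
  expect_error(count_reads_per_feature(mk_reads(10, 50), feats), "duplicate")
})

test_that("rpkm follows count * 1e9 / (len * library)", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
  expect_error(rpkm(-1, 1000, 1e6), "non-negative")
  expect_error(rpkm(1, 0, 1e6), "length")
})
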