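test_that("splicing units enumerate introns with flanking exons", {
  # 2-exon transcript -> 1 unit with the right junction gap
  tx <- toy_two_exon_tx()
  u <- units_from_annotation(tx)
  expect_length(u, 1)
  expect_equal(start(u), 201)
  expect_equal(end(u), 300)
  m <- mcols(u)
  expect_equal(m$unit_id, "txA.I1")
  expect_equal(c(m$donor_start, m$donor_end), c(101, 200))
  expect_equal(c(m$acceptor_start, m$acceptor_end), c(301, 450))
  # 3-exon transcript -> 2 units; minus strand numbers in transcription order
  tx3 <- GRangesList(
    fwd = GRanges("chr1", IRanges(c(1, 201, 401), c(100, 300, 500)), "+"),
    rev = GRanges("chr1", IRanges(c(1, 201, 401), c(100, 300, 500)), "-"))
  u3 <- units_from_annotation(tx3)
  expect_length(u3, 4)
  mf <- mcols(u3)[mcols(u3)$transcript_id == "fwd", ]
  mr <- mcols(u3)[mcols(u3)$transcript_id == "rev", ]
  expect_equal(mf$unit_id, c("fwd.I1", "fwd.I2"))
  expect_equal(mr$unit_id, c("rev.I2", "rev.I1"))  # genomic-left gap is last
  # minus strand: donor exon is genomic-right of its gap
  expect_true(all(mr$donor_start > mr$acceptor_start))
  # intronless transcript -> no units
  expect_length(units_from_annotation(
    GRangesList(a = GRanges("chr1", IRanges(1, 500), "+"))), 0)
  # overlapping exons are an error
  expect_error(units_from_annotation(
    GRangesList(bad = GRanges("chr1", IRanges(c(1, 50), c(100, 200)), "+"))),
    "overlapping exons")
})

test_that("junction support requires an exact gap match", {
  u <- units_from_annotation(toy_two_exon_tx())   # intron 201..300
  hit <- mk_split_read(c(151, 301), c(200, 350))  # gap exactly 201..300
  near <- mk_split_read(c(151, 302), c(200, 350)) # gap 201..301: off by 1
  uns <- mk_reads(180, 229)                       # unspliced, over junction
  expect_equal(junction_support(hit, u), 1L)
  expect_equal(junction_support(near, u), 0L)
  expect_equal(junction_support(uns, u), 0L)
  # with tolerance the near-miss counts
  expect_equal(junction_support(near, u, tolerance = 1), 1L)
  # toy mixture equals the loop oracle: 3 matching, 2 near-miss, 3 unspliced
  reads <- c(hit, hit, hit, near,
             mk_split_read(c(151, 300), c(199, 350)),
             uns, uns, mk_reads(320, 369))
  expect_equal(junction_support(reads, u), 3L)
  blocks <- lapply(reads, function(g)
    data.frame(start = start(g), end = end(g)))
  expect_equal(junction_support(reads, u),
               as.integer(brute_junction_support(blocks, 201, 300)))
})

test_that("exonic unit coverage averages block coverage over both exons", {
  tx <- toy_two_exon_tx(e1 = c(101, 200), intron = c(201, 300),
                        e2 = c(301, 400))  # 100 + 100 bp exons
  u <- units_from_annotation(tx)
  # single 100-bp read fully inside the exon pair -> 100/200
  expect_equal(exonic_unit_coverage(mk_reads(101, 200), u), 0.5)
  expect_equal(exonic_unit_coverage(GRangesList(), u), 0)
  # 12 random reads match the per-base brute-force oracle
  set.seed(21)
  starts <- sample(50:420, 12); ends <- starts + 49
  reads <- mk_reads(starts, ends)
  percov <- brute_coverage(starts, ends, 500)
  oracle <- sum(percov[c(101:200, 301:400)]) / 200
  expect_equal(exonic_unit_coverage(reads, u), oracle)
})

test_that("PSO is the junction/exonic ratio in percent, missing when 0/0", {
  expect_equal(pso(10, 20), 50)
  expect_equal(pso(0, 20), 0)
  expect_equal(pso(20, 20), 100)
  miss <- pso(0, 0)
  expect_true(is.na(miss))
  expect_equal(attr(miss, "reason")[1], "no coverage")
  expect_error(pso(-1, 5), ">= 0")
  # read duplication invariance: numerator and denominator scale together
  u <- units_from_annotation(toy_two_exon_tx())
  reads <- c(mk_split_read(c(151, 301), c(200, 350)), mk_reads(120, 169))
  p1 <- pso(junction_support(reads, u), exonic_unit_coverage(reads, u))
  dup <- c(reads, reads)
  p2 <- pso(junction_support(dup, u), exonic_unit_coverage(dup, u))
  expect_equal(p1, p2)
})

test_that("per-unit ANOVA matches the textbook oracle and BH is applied", {
  # groups (10,12,14) vs (20,22,24): hand F
  o <- brute_anova_f(c(10, 12, 14, 20, 22, 24), rep(c("a", "b"), each = 3))
  tab <- data.frame(unit_id = "u1", s1 = 10, s2 = 12, s3 = 14,
                    s4 = 20, s5 = 22, s6 = 24)
  gt <- setNames(rep(c("WT", "MUT"), each = 3), paste0("s", 1:6))
  res <- pso_anova(tab, gt)
  expect_equal(res$f_stat, o$f)
  expect_equal(res$p, o$p)
  # identical group means with within-group variance > 0 -> F = 0, p = 1
  tab0 <- data.frame(unit_id = "u1", s1 = 10, s2 = 14, s3 = 12,
                     s4 = 10, s5 = 14, s6 = 12)
  res0 <- pso_anova(tab0, gt)
  expect_equal(res0$f_stat, 0)
  expect_equal(res0$p, 1)
  # BH across units agrees with bh_adjust
  set.seed(4)
  tabs <- data.frame(unit_id = paste0("u", 1:5),
                     matrix(runif(30, 40, 100), nrow = 5,
                            dimnames = list(NULL, paste0("s", 1:6))))
  resm <- pso_anova(tabs, gt)
  expect_equal(resm$adj_p, bh_adjust(resm$p))
  # units with missing PSO are dropped with a message
  tabs$s1[2] <- NA
  expect_message(resd <- pso_anova(tabs, gt), "dropped")
  expect_equal(nrow(resd), 4)
  # fewer than 2 genotypes is an error
  expect_error(pso_anova(tab, setNames(rep("WT", 6), paste0("s", 1:6))),
               "2 genotypes")
})

test_that("null PSO ANOVA p-values are uniform", {
  # 200 null units, two genotypes x 3 replicates from one distribution
  set.seed(77)
  p <- replicate(200, {
    y <- rnorm(6, mean = 50, sd = 5)
    tab <- data.frame(unit_id = "u", t(y))
    names(tab)[-1] <- paste0("s", 1:6)
    gt <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
    pso_anova(tab, gt)$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})
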