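test_that("generators are deterministic given (seed, config)", {
  cfg <- sim_config(seed = 42, chip = list(depth = 5000),
                    splicing = list(reads_per_unit = 50),
                    cytometry = list(n_cells = 500))
  expect_identical(gen_chip_reads(cfg)$samples, gen_chip_reads(cfg)$samples)
  expect_identical(gen_spliced_reads(cfg)$samples,
                   gen_spliced_reads(cfg)$samples)
  expect_identical(gen_cytometry(cfg)$samples, gen_cytometry(cfg)$samples)
  expect_identical(gen_luciferase(cfg)$plate, gen_luciferase(cfg)$plate)
  expect_identical(gen_growth(cfg)$curves, gen_growth(cfg)$curves)
  # a different seed changes the draws
  cfg2 <- sim_config(seed = 43, chip = list(depth = 5000))
  expect_false(identical(gen_chip_reads(cfg)$samples[[1]],
                         gen_chip_reads(cfg2)$samples[[1]]))
})

test_that("substreams are independent: one stage does not perturb another", {
  cfg <- sim_config(seed = 7, cytometry = list(n_cells = 200))
  a <- gen_cytometry(cfg)$samples
  invisible(gen_luciferase(cfg))  # interleaved call must not matter
  b <- gen_cytometry(cfg)$samples
  expect_identical(a, b)
})

test_that("unenriched ChIP coverage is flat; enrichment shows as a plateau", {
  cfg <- sim_config(seed = 5, genome = c(chrI = 100000L),
                    chip = list(depth = 100000L, n_genes = 15L,
                                target_group_size = 5L,
                                enrichment = c(WT = 1), replicates = 1L))
  sim <- gen_chip_reads(cfg)
  reads <- sim$samples[[1]]
  track <- rpm_normalize(coverage_from_reads(
    extend_reads(reads, 150, chrom_sizes = cfg$genome), cfg$genome))
  g <- sim$genes[sim$target_ids]
  anch <- GRanges(seqnames(g), IRanges(start(g), width = 1), strand(g))
  prof <- metagene_profile(track, anch, width = 600)
  expect_lt(max(prof$mean_rpm) / min(prof$mean_rpm), 1.3)
})

test_that("spliced-read generator respects theta and its geometry", {
  # theta = 0: no split reads, PSO 0
  cfg0 <- sim_config(seed = 9, splicing = list(
    theta = c(WT = 0), reads_per_unit = 200L, replicates = 1L))
  sim0 <- gen_spliced_reads(cfg0)
  expect_true(all(lengths(sim0$samples[[1]]) == 1L))
  units <- units_from_annotation(sim0$transcripts)
  expect_equal(sum(junction_support(sim0$samples[[1]], units)), 0L)
  expect_equal(sim0$truth$expected_pso_WT, rep(0, nrow(sim0$truth)))
  # expected PSO is strictly increasing in theta
  e <- sapply(seq(0, 1, by = 0.1), function(th)
    expected_pso_enum(180, 300, 100, 50, th))
  expect_true(all(diff(e) > 0))
  # theta = 1: per-unit estimates track the enumerated expectation
  cfg1 <- sim_config(seed = 9, splicing = list(
    theta = c(WT = 1), reads_per_unit = 4000L, replicates = 1L))
  sim1 <- gen_spliced_reads(cfg1)
  u1 <- units_from_annotation(sim1$transcripts)
  rd <- sim1$samples[[1]]
  est <- pso(junction_support(rd, u1), exonic_unit_coverage(rd, u1))
  ## per-unit counting noise is ~4 points here; the calibration check is
  ## that the signed error averages out across the 20 units
  expect_lt(abs(mean(est - sim1$truth$expected_pso_WT)), 2.5)
  # all reads honour the read length on the mature isoform
  expect_true(all(sum(width(rd)) == cfg1$splicing$read_length))
})

test_that("cytometry generator shifts genotype B multiplicatively", {
  cfg <- sim_config(seed = 12, cytometry = list(n_cells = 5000L))
  sim <- gen_cytometry(cfg)
  expect_length(sim$samples, 4)
  med_wt <- median(sim$samples[["WT_rep1"]])
  med_mut <- median(sim$samples[["scc2_4_rep1"]])
  expect_equal(med_mut / med_wt, 1.5, tolerance = 0.1)
})

test_that("noiseless luciferase plates return the configured truth exactly", {
  cfg <- sim_config(seed = 1, luciferase = list(cv = 0))
  plate <- gen_luciferase(cfg)$plate
  pick <- function(st, role)
    plate[plate$strain == st & plate$construct_role == role, ]
  expect_equal(frameshift_efficiency(pick("WT", "minus1_PRF"),
                                     pick("WT", "zero_frame_control")), 1.1)
  expect_equal(frameshift_efficiency(pick("scc2_4", "minus1_PRF"),
                                     pick("scc2_4", "zero_frame_control")), 3.4)
  expect_equal(ires_activity(pick("scc2_4", "IRES"), pick("WT", "IRES")), 60)
  expect_equal(readthrough_percent(pick("WT", "stop_UGA"),
                                   pick("WT", "sense_control")), 1.0)
  # gain invariance: doubling all luminescence leaves estimates unchanged
  cfg2 <- sim_config(seed = 1, luciferase = list(cv = 0.1))
  p2 <- gen_luciferase(cfg2)$plate
  p2x <- transform(p2, firefly = firefly * 2, renilla = renilla * 2)
  pick2 <- function(p, st, role)
    p[p$strain == st & p$construct_role == role, ]
  expect_equal(
    frameshift_efficiency(pick2(p2, "WT", "minus1_PRF"),
                          pick2(p2, "WT", "zero_frame_control")),
    frameshift_efficiency(pick2(p2x, "WT", "minus1_PRF"),
                          pick2(p2x, "WT", "zero_frame_control")))
})

test_that("noiseless growth curves recover r within 5%", {
  cfg <- sim_config(seed = 2, growth = list(sigma = 0, replicates = 1L))
  sim <- gen_growth(cfg)
  for (st in names(cfg$growth$r)) {
    d <- sim$curves[sim$curves$strain == st, ]
    mu <- max_growth_rate(d$time_min, d$od)$mu_max
    expect_lt(abs(mu - cfg$growth$r[[st]]) / cfg$growth$r[[st]], 0.05)
  }
})
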