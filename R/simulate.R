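#' Simulation configuration
#'
#' Bundles the parameters of every synthetic-data generator with a master
#' seed. Each generator derives an independent random substream from the
#' seed and a stable stage key, so adding one generator call never perturbs
#' another stage's draws and the same `(seed, config)` always reproduces
#' identical output.
#'
#' Defaults emulate the study conditions of a two-genotype budding-yeast
#' experiment: a 4 x 100 kb toy genome with 60 genes of which one 20-gene
#' group is ChIP-enriched (5-fold in the wild type, 2-fold in the mutant);
#' 20 two-exon spliced transcripts with high wild-type splicing; ~10,000
#' log-normal GFP intensities per cytometry sample with a 1.5-fold mutant
#' shift; dual-luciferase plates with 1.1%/3.4% -1 frameshifting, unchanged
#' +1 frameshifting and readthrough, and 60% mutant IRES activity; logistic
#' growth at 0.6/h (wild type) versus 70% of that in the mutant.
#'
#' @param seed Master seed (integer).
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = c(chrI = 100000L, chrII = 100000L,
               chrIII = 100000L, chrIV = 100000L),
    chip = list(
      n_genes = 60L, gene_width = 1500L, target_group_size = 20L,
      enrichment = c(WT = 5, scc2_4 = 2), replicates = 2L,
      read_length = 50L, depth = 200000L),
    splicing = list(
      n_units = 20L, read_length = 50L, reads_per_unit = 500L,
      theta = c(WT = 0.9, scc2_4 = 0.75), replicates = 3L),
    cytometry = list(
      meanlog = log(500), sdlog = 0.5, n_cells = 10000L, replicates = 2L,
      shift = c(WT = 1, scc2_4 = 1.5)),
    luciferase = list(
      replicates = 6L, cv = 0.1, renilla_mean = 1e5,
      zero_frame_ratio = 5, sense_ratio = 2, ires_ref_ratio = 0.8,
      fs_minus1 = c(WT = 1.1, scc2_4 = 3.4),
      fs_plus1 = c(WT = 8, scc2_4 = 8),
      readthrough = list(WT = c(UAA = 0.3, UAG = 0.6, UGA = 1.0),
                         scc2_4 = c(UAA = 0.3, UAG = 0.6, UGA = 1.0)),
      ires_activity = c(WT = 100, scc2_4 = 60)),
    growth = list(
      r = c(WT = 0.6, scc2_4 = 0.42), K = 1, N0 = 0.02, sigma = 0.005,
      t_max_min = 720, dt_min = 10, replicates = 3L))
  user <- list(...)
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      utils::modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
  }
  structure(cfg, class = "sim_config")
}

## deterministic gene layout: genes evenly spaced over the toy genome,
## alternating strand; the first `target_group_size` form the enriched group
.sim_genes <- function(cfg) {
  genome <- cfg$genome
  n <- cfg$chip$n_genes
  per_chr <- ceiling(n / length(genome))
  rows <- list()
  k <- 0L
  for (ci in seq_along(genome)) {
    margin <- 2000L
    usable <- genome[ci] - 2L * margin
    spacing <- usable %/% per_chr
    for (j in seq_len(per_chr)) {
      if (k >= n) break
      k <- k + 1L
      st <- margin + (j - 1L) * spacing + 1L
      rows[[k]] <- data.frame(
        id = sprintf("gene%03d", k), chrom = names(genome)[ci],
        start = st, end = st + cfg$chip$gene_width - 1L,
        strand = if (k %% 2L == 0L) "-" else "+")
    }
  }
  genes <- do.call(rbind, rows)
  gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                strand = genes$strand)
  names(gr) <- genes$id
  GenomeInfoDb::seqlengths(gr) <- genome
  gr
}

#' Simulate ChIP-seq reads with group-specific enrichment
#'
#' Background reads fall uniformly over the genome; reads falling in the
#' target gene group arrive at `enrichment` times the background rate.
#' Reads are single-block, `read_length` bp, random strand. One read set is
#' generated per genotype and replicate.
#'
#' @param config A [sim_config()].
#' @return List: `samples` (named list of single-block `GRanges` read sets,
#'   names `<genotype>_rep<k>`), `genes` (named `GRanges`), `target_ids`,
#'   `truth` (per-genotype enrichment factors and depth).
#' @export
gen_chip_reads <- function(config) {
  cfg <- config
  genes <- .sim_genes(cfg)
  target <- genes[seq_len(cfg$chip$target_group_size)]
  genome_len <- sum(as.numeric(cfg$genome))
  target_len <- sum(width(target))
  samples <- list()
  for (g in names(cfg$chip$enrichment)) {
    f <- cfg$chip$enrichment[[g]]
    for (rep_i in seq_len(cfg$chip$replicates)) {
      set.seed(derive_seed(cfg$seed, paste0("chip:", g, ":", rep_i)))
      n <- cfg$chip$depth
      if (n == 0L) {
        samples[[paste0(g, "_rep", rep_i)]] <- GRanges()
        next
      }
      ## target regions receive background (uniform) reads plus an extra
      ## mass of (f - 1) x their length, giving a total rate of f x background
      p_target <- (f - 1) * target_len / (genome_len + (f - 1) * target_len)
      in_target <- runif(n) < p_target
      n_t <- sum(in_target)
      ## positions inside the target group, uniform over its summed length
      offs <- floor(runif(n_t) * target_len)
      cum <- cumsum(width(target))
      gi <- findInterval(offs, c(0, cum), rightmost.closed = FALSE)
      pos_t <- start(target)[gi] + (offs - c(0, cum)[gi])
      chr_t <- as.character(seqnames(target))[gi]
      ## background positions uniform over concatenated genome
      n_b <- n - n_t
      offs_b <- floor(runif(n_b) * genome_len)
      cumg <- cumsum(as.numeric(cfg$genome))
      ci <- findInterval(offs_b, c(0, cumg), rightmost.closed = FALSE)
      pos_b <- offs_b - c(0, cumg)[ci] + 1
      chr_b <- names(cfg$genome)[ci]
      chrom <- c(chr_t, chr_b)
      pos <- c(pos_t, pos_b)
      std <- sample(c("+", "-"), n, replace = TRUE)
      ends <- pmin(pos + cfg$chip$read_length - 1L,
                   unname(cfg$genome[chrom]))
      gr <- GRanges(factor(chrom, levels = names(cfg$genome)),
                    IRanges(pos, ends), strand = std,
                    seqlengths = cfg$genome)
      samples[[paste0(g, "_rep", rep_i)]] <- gr
    }
  }
  list(samples = samples, genes = genes, target_ids = names(target),
       truth = list(enrichment = cfg$chip$enrichment,
                    depth = cfg$chip$depth,
                    read_length = cfg$chip$read_length))
}

#' Analytic expected PSO for the two-exon generator geometry
#'
#' Exhaustively enumerates every fragment start position of the spliced and
#' unspliced isoforms of a two-exon transcript (exon lengths `e1`, `e2`,
#' intron length `intron_len`, read length `L`), and returns the PSO value
#' expected when a fraction `theta` of fragments is spliced. This is the
#' independent oracle for PSO recovery tests: it never touches read data.
#'
#' @param e1,e2 Flanking exon lengths (bp).
#' @param intron_len Intron length (bp).
#' @param L Read length (bp), `L <= e1 + e2`.
#' @param theta True spliced fraction in `[0, 1]`.
#' @return Expected PSO in percent.
#' @export
expected_pso_enum <- function(e1, e2, intron_len, L, theta) {
  stopifnot(L <= e1 + e2, theta >= 0, theta <= 1)
  ## spliced isoform: starts on the e1+e2 mature sequence
  ns <- e1 + e2 - L + 1L
  s <- seq_len(ns)
  spans <- sum(s <= e1 & s + L - 1L >= e1 + 1L)
  cov_spliced <- L                      # spliced reads lie wholly in exons
  ## unspliced isoform: starts on the e1+intron+e2 precursor
  nu <- e1 + intron_len + e2 - L + 1L
  u <- seq_len(nu)
  ov1 <- pmax(0L, pmin(u + L - 1L, e1) - pmax(u, 1L) + 1L)
  ov2 <- pmax(0L, pmin(u + L - 1L, e1 + intron_len + e2) -
                  pmax(u, e1 + intron_len + 1L) + 1L)
  cov_unspliced <- mean(ov1 + ov2)
  e_junction <- theta * spans / ns
  e_exonic <- (theta * cov_spliced + (1 - theta) * cov_unspliced) / (e1 + e2)
  if (e_exonic == 0) return(NA_real_)
  100 * e_junction / e_exonic
}

## two-exon transcript layout for the splicing generator
.sim_spliced_transcripts <- function(cfg) {
  n <- cfg$splicing$n_units
  genome <- cfg$genome
  rows <- vector("list", n)
  spacing <- 4000L
  for (k in seq_len(n)) {
    e1 <- 150L + 10L * (k %% 7L)
    i_len <- 80L + 15L * (k %% 5L)
    e2 <- 250L + 20L * (k %% 6L)
    chrom <- names(genome)[(k - 1L) %% length(genome) + 1L]
    st <- 50000L + ((k - 1L) %/% length(genome)) * spacing
    strand <- if (k %% 2L == 0L) "-" else "+"
    rows[[k]] <- list(id = sprintf("sptx%02d", k), chrom = chrom, start = st,
                      e1 = e1, intron = i_len, e2 = e2, strand = strand)
  }
  rows
}

#' Simulate spliced RNA-seq reads with known splicing fractions
#'
#' Each transcript is a two-exon model; every simulated fragment is spliced
#' with probability `theta` (giving a two-block read whose gap is exactly
#' the intron when it spans the junction) or unspliced (one contiguous
#' block on the precursor). Fragment starts are uniform over the positions
#' that keep `read_length` bases within the isoform. The truth table
#' carries the analytic expected PSO from [expected_pso_enum()].
#'
#' @param config A [sim_config()].
#' @return List: `samples` (named list of `GRangesList` read sets, names
#'   `<genotype>_rep<k>`), `transcripts` (`GRangesList` of exons, an
#'   annotation usable with [units_from_annotation()]), `truth`
#'   (`data.frame`: `unit_id`, per-genotype `theta` and `expected_pso`).
#' @export
gen_spliced_reads <- function(config) {
  cfg <- config
  layout <- .sim_spliced_transcripts(cfg)
  L <- cfg$splicing$read_length
  ## annotation
  tx_list <- lapply(layout, function(tr) {
    if (L > tr$e1 + tr$e2)
      stop("read length exceeds mature transcript of ", tr$id)
    ex1 <- IRanges(tr$start, tr$start + tr$e1 - 1L)
    ex2_start <- tr$start + tr$e1 + tr$intron
    ex2 <- IRanges(ex2_start, ex2_start + tr$e2 - 1L)
    GRanges(tr$chrom, c(ex1, ex2), strand = tr$strand)
  })
  names(tx_list) <- vapply(layout, `[[`, "", "id")
  transcripts <- GRangesList(tx_list)
  genotypes <- names(cfg$splicing$theta)
  samples <- list()
  for (g in genotypes) {
    theta <- cfg$splicing$theta[[g]]
    for (rep_i in seq_len(cfg$splicing$replicates)) {
      set.seed(derive_seed(cfg$seed, paste0("rnaseq:", g, ":", rep_i)))
      starts <- integer(0); ends <- integer(0)
      starts2 <- integer(0); ends2 <- integer(0)
      chroms <- character(0); two_block <- logical(0)
      for (tr in layout) {
        nfrag <- cfg$splicing$reads_per_unit
        spliced <- runif(nfrag) < theta
        g_start <- tr$start
        junc1 <- g_start + tr$e1 - 1L        # genomic end of exon 1
        junc2 <- g_start + tr$e1 + tr$intron # genomic start of exon 2
        ## spliced fragments: start on mature coordinates 1..e1+e2-L+1
        ns <- tr$e1 + tr$e2 - L + 1L
        s <- 1L + floor(runif(sum(spliced)) * ns)
        sp_spans <- s <= tr$e1 & s + L - 1L >= tr$e1 + 1L
        ## genomic coordinates of the (up to two) blocks
        b1s <- ifelse(s <= tr$e1, g_start + s - 1L, junc2 + (s - tr$e1 - 1L))
        b1e <- ifelse(sp_spans, junc1,
                      ifelse(s <= tr$e1, g_start + s + L - 2L,
                             junc2 + (s - tr$e1 - 1L) + L - 1L))
        b2s <- ifelse(sp_spans, junc2, NA_integer_)
        b2e <- ifelse(sp_spans, junc2 + (L - (junc1 - b1s + 1L)) - 1L,
                      NA_integer_)
        ## unspliced fragments: contiguous on the precursor
        nu <- tr$e1 + tr$intron + tr$e2 - L + 1L
        u <- 1L + floor(runif(sum(!spliced)) * nu)
        u1s <- g_start + u - 1L
        u1e <- u1s + L - 1L
        starts <- c(starts, b1s, u1s); ends <- c(ends, b1e, u1e)
        starts2 <- c(starts2, b2s, rep(NA_integer_, length(u)))
        ends2 <- c(ends2, b2e, rep(NA_integer_, length(u)))
        chroms <- c(chroms, rep(tr$chrom, nfrag))
        two_block <- c(two_block, sp_spans, rep(FALSE, length(u)))
      }
      block_chrom <- c(chroms[!two_block],
                       rep(chroms[two_block], each = 2L))
      block_start <- c(starts[!two_block],
                       as.vector(rbind(starts[two_block], starts2[two_block])))
      block_end <- c(ends[!two_block],
                     as.vector(rbind(ends[two_block], ends2[two_block])))
      read_id <- c(which(!two_block), rep(which(two_block), each = 2L))
      gr <- GRanges(factor(block_chrom, levels = names(cfg$genome)),
                    IRanges(block_start, block_end),
                    seqlengths = cfg$genome)
      reads <- GenomicRanges::split(gr, factor(read_id, levels = sort(unique(read_id))))
      names(reads) <- NULL
      samples[[paste0(g, "_rep", rep_i)]] <- reads
    }
  }
  truth <- data.frame(unit_id = paste0(names(transcripts), ".I1"),
                      stringsAsFactors = FALSE)
  for (g in genotypes) {
    th <- cfg$splicing$theta[[g]]
    truth[[paste0("theta_", g)]] <- th
    truth[[paste0("expected_pso_", g)]] <- vapply(layout, function(tr)
      expected_pso_enum(tr$e1, tr$e2, tr$intron, L, th), numeric(1))
  }
  list(samples = samples, transcripts = transcripts, truth = truth)
}

#' Simulate flow-cytometry GFP intensity samples
#'
#' Log-normal intensities per cell; each genotype's distribution is scaled
#' by its multiplicative `shift`, and replicates are independent draws.
#'
#' @param config A [sim_config()].
#' @return List: `samples` (named list of intensity vectors,
#'   `<genotype>_rep<k>`), `genotypes` (named vector for
#'   [replicate_baseline_test()]), `truth` (shift factors).
#' @export
gen_cytometry <- function(config) {
  cfg <- config
  cy <- cfg$cytometry
  samples <- list()
  genotypes <- character(0)
  for (g in names(cy$shift)) {
    for (rep_i in seq_len(cy$replicates)) {
      set.seed(derive_seed(cfg$seed, paste0("cytometry:", g, ":", rep_i)))
      nm <- paste0(g, "_rep", rep_i)
      samples[[nm]] <- rlnorm(cy$n_cells, cy$meanlog + log(cy$shift[[g]]),
                              cy$sdlog)
      genotypes[nm] <- g
    }
  }
  list(samples = samples, genotypes = genotypes,
       truth = list(shift = cy$shift, n_cells = cy$n_cells))
}

#' Simulate a dual-luciferase reporter plate
#'
#' Renilla luminescence is drawn around a plate mean with log-normal noise
#' of coefficient of variation `cv`; firefly is renilla times the
#' construct's target ratio times independent log-normal noise. Target
#' ratios are chosen so the true frameshifting, readthrough and IRES
#' percentages equal the configured truth; at `cv = 0` every estimator
#' returns the truth exactly.
#'
#' @param config A [sim_config()].
#' @return List: `plate` (`data.frame`: `strain`, `construct_role`,
#'   `replicate`, `firefly`, `renilla`) and `truth` (the configured
#'   percentages).
#' @export
gen_luciferase <- function(config) {
  cfg <- config
  lc <- cfg$luciferase
  sdl <- sqrt(log(1 + lc$cv^2))
  strains <- names(lc$fs_minus1)
  rows <- list()
  for (st in strains) {
    ratios <- c(
      zero_frame_control = lc$zero_frame_ratio,
      minus1_PRF = lc$zero_frame_ratio * lc$fs_minus1[[st]] / 100,
      plus1_PRF = lc$zero_frame_ratio * lc$fs_plus1[[st]] / 100,
      sense_control = lc$sense_ratio,
      stop_UAA = lc$sense_ratio * lc$readthrough[[st]][["UAA"]] / 100,
      stop_UAG = lc$sense_ratio * lc$readthrough[[st]][["UAG"]] / 100,
      stop_UGA = lc$sense_ratio * lc$readthrough[[st]][["UGA"]] / 100,
      IRES = lc$ires_ref_ratio * lc$ires_activity[[st]] / 100)
    set.seed(derive_seed(cfg$seed, paste0("luciferase:", st)))
    for (role in names(ratios)) {
      n <- lc$replicates
      renilla <- lc$renilla_mean *
        (if (lc$cv > 0) rlnorm(n, -sdl^2 / 2, sdl) else rep(1, n))
      firefly <- renilla * ratios[[role]] *
        (if (lc$cv > 0) rlnorm(n, -sdl^2 / 2, sdl) else rep(1, n))
      rows[[paste(st, role)]] <- data.frame(
        strain = st, construct_role = role, replicate = seq_len(n),
        firefly = firefly, renilla = renilla, stringsAsFactors = FALSE)
    }
  }
  list(plate = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = list(fs_minus1 = lc$fs_minus1, fs_plus1 = lc$fs_plus1,
                    readthrough = lc$readthrough,
                    ires_activity = lc$ires_activity, cv = lc$cv))
}

#' Simulate logistic growth curves
#'
#' OD follows the logistic solution
#' `N(t) = K N0 e^{rt} / (K + N0 (e^{rt} - 1))` with additive Gaussian
#' noise of standard deviation `sigma`, sampled on a regular grid.
#'
#' @param config A [sim_config()].
#' @return List: `curves` (`data.frame`: `strain`, `condition`, `replicate`,
#'   `time_min`, `od`) and `truth` (per-strain `r`, plus `K`, `N0`,
#'   `sigma`).
#' @export
gen_growth <- function(config) {
  cfg <- config
  gw <- cfg$growth
  tmin <- seq(0, gw$t_max_min, by = gw$dt_min)
  th <- tmin / 60
  rows <- list()
  for (st in names(gw$r)) {
    r <- gw$r[[st]]
    for (rep_i in seq_len(gw$replicates)) {
      set.seed(derive_seed(cfg$seed, paste0("growth:", st, ":", rep_i)))
      od <- gw$K * gw$N0 * exp(r * th) / (gw$K + gw$N0 * (exp(r * th) - 1))
      if (gw$sigma > 0) od <- od + rnorm(length(od), 0, gw$sigma)
      rows[[paste(st, rep_i)]] <- data.frame(
        strain = st, condition = "YPD", replicate = rep_i,
        time_min = tmin, od = od, stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = list(r = gw$r, K = gw$K, N0 = gw$N0, sigma = gw$sigma))
}
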