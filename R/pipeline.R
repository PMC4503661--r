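#' Run the full analysis pipeline from a config
#'
#' Drives every stage over seeded synthetic inputs: ChIP metagene profiling,
#' PSO splicing analysis, cytometry KS comparison, dual-luciferase fidelity
#' calculators and growth-rate estimation. The YAML config has a versioned
#' schema; unknown keys are errors (fail-fast). Outputs are TSVs (with a
#' tool-version / parameter-hash header line), a JSON run summary and a log;
#' a rerun with the same config and seed is bit-identical.
#'
#' @param config Path to a YAML file, or an equivalent named list. Keys:
#'   `version` (must be 1), `seed`, `outdir`, optional `stages` (subset of
#'   `chip`, `splicing`, `cytometry`, `luciferase`, `growth`), optional
#'   `parameters` (`extension_length`, `window`, `alpha`, `fc_threshold`),
#'   optional `sim` (overrides for [sim_config()]).
#' @return (Invisibly) the summary list; also written as
#'   `summary.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("version", "seed", "outdir", "stages", "parameters", "sim")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (is.null(config$version) || config$version != 1)
    stop("config schema version must be 1")
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  seed <- config$seed %||% 1L
  all_stages <- c("chip", "splicing", "cytometry", "luciferase", "growth")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  par_defaults <- list(extension_length = 150L, window = 600L,
                       alpha = 0.05, fc_threshold = 1.5)
  pars <- utils::modifyList(par_defaults, config$parameters %||% list())
  unknown_p <- setdiff(names(pars), names(par_defaults))
  if (length(unknown_p)) stop("unknown parameters: ",
                              paste(unknown_p, collapse = ", "))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    writeLines(line, log_con)
    message(line)
  }
  par_hash <- .param_hash(c(pars, seed = seed))
  cfg <- do.call(sim_config, c(list(seed = seed), config$sim %||% list()))
  statuses <- list()
  for (st in stages) {
    out_files <- tryCatch(
      switch(st,
        chip = .stage_chip(cfg, pars, outdir, par_hash),
        splicing = .stage_splicing(cfg, pars, outdir, par_hash),
        cytometry = .stage_cytometry(cfg, pars, outdir, par_hash),
        luciferase = .stage_luciferase(cfg, pars, outdir, par_hash),
        growth = .stage_growth(cfg, pars, outdir, par_hash)),
      error = function(e) {
        for (f in list.files(outdir, full.names = TRUE))
          if (startsWith(basename(f), st)) file.rename(f, paste0(f, ".partial"))
        stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE)
      })
    sums <- tools::md5sum(out_files)
    logmsg("stage=", st, " status=ok params=", par_hash,
           " outputs=", paste(basename(out_files), collapse = ","),
           " md5=", paste(unname(sums), collapse = ","))
    statuses[[st]] <- list(status = "ok", outputs = basename(out_files))
  }
  summary <- list(version = 1L, seed = seed, parameters = pars,
                  param_hash = par_hash, stages = statuses)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

.param_hash <- function(pars) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(names(pars), vapply(pars, format, ""), sep = "="), tf)
  unname(tools::md5sum(tf))
}

.write_stage_tsv <- function(df, path, par_hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# scc2xpress ",
                    as.character(utils::packageVersion("scc2xpress")),
                    " params=", par_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_chip <- function(cfg, pars, outdir, par_hash) {
  sim <- gen_chip_reads(cfg)
  genes <- sim$genes
  target <- genes[sim$target_ids]
  other_ids <- setdiff(names(genes), sim$target_ids)
  profs <- list()
  counts <- NULL
  for (nm in names(sim$samples)) {
    reads <- sim$samples[[nm]]
    ext <- extend_reads(reads, pars$extension_length,
                        chrom_sizes = cfg$genome)
    track <- rpm_normalize(coverage_from_reads(ext, cfg$genome))
    for (grp in list(list(ids = sim$target_ids, name = "target"),
                     list(ids = other_ids, name = "background"))) {
      anch <- GRanges(seqnames(genes[grp$ids]),
                      IRanges(ifelse(as.character(strand(genes[grp$ids])) == "-",
                                     end(genes[grp$ids]), start(genes[grp$ids])),
                              width = 1L),
                      strand = strand(genes[grp$ids]))
      p <- metagene_profile(track, anch, width = pars$window, sample_id = nm)
      profs[[paste(nm, grp$name)]] <- data.frame(
        group = grp$name, sample = nm, offset = p$offset,
        mean_rpm = p$mean_rpm)
    }
    ct <- count_reads_per_feature(reads, genes)
    ct$rpkm <- rpkm(ct$count, ct$length_bp, length(reads))
    ct$sample <- nm
    counts <- rbind(counts, ct)
  }
  c(.write_stage_tsv(do.call(rbind, c(profs, list(make.row.names = FALSE))),
                     file.path(outdir, "chip_metagene.tsv"), par_hash),
    .write_stage_tsv(counts, file.path(outdir, "chip_counts.tsv"), par_hash))
}

.stage_splicing <- function(cfg, pars, outdir, par_hash) {
  sim <- gen_spliced_reads(cfg)
  units <- units_from_annotation(sim$transcripts)
  tab <- pso_table(sim$samples, units)
  genotypes <- sub("_rep[0-9]+$", "", names(sim$samples))
  names(genotypes) <- names(sim$samples)
  res <- pso_anova(tab, genotypes)
  .write_stage_tsv(merge(tab, res, by = "unit_id", sort = TRUE),
                   file.path(outdir, "splicing_pso.tsv"), par_hash)
}

.stage_cytometry <- function(cfg, pars, outdir, par_hash) {
  sim <- gen_cytometry(cfg)
  res <- replicate_baseline_test(sim$samples, sim$genotypes,
                                 alpha = pars$alpha)
  c(.write_stage_tsv(rbind(res$within, res$between),
                     file.path(outdir, "cytometry_ks_pairs.tsv"), par_hash),
    .write_stage_tsv(res$decisions,
                     file.path(outdir, "cytometry_decisions.tsv"), par_hash))
}

.stage_luciferase <- function(cfg, pars, outdir, par_hash) {
  sim <- gen_luciferase(cfg)
  plate <- sim$plate
  strains <- unique(plate$strain)
  ref <- strains[1L]
  pick <- function(st, role) plate[plate$strain == st &
                                   plate$construct_role == role, ]
  rows <- list()
  for (st in strains) {
    rows[[paste(st, "fs-1")]] <- data.frame(
      strain = st, quantity = "fs_minus1_pct",
      value = frameshift_efficiency(pick(st, "minus1_PRF"),
                                    pick(st, "zero_frame_control")))
    rows[[paste(st, "fs+1")]] <- data.frame(
      strain = st, quantity = "fs_plus1_pct",
      value = frameshift_efficiency(pick(st, "plus1_PRF"),
                                    pick(st, "zero_frame_control")))
    for (codon in c("UAA", "UAG", "UGA"))
      rows[[paste(st, codon)]] <- data.frame(
        strain = st, quantity = paste0("readthrough_", codon, "_pct"),
        value = readthrough_percent(pick(st, paste0("stop_", codon)),
                                    pick(st, "sense_control")))
    rows[[paste(st, "ires")]] <- data.frame(
      strain = st, quantity = "ires_activity_pct",
      value = ires_activity(pick(st, "IRES"), pick(ref, "IRES")))
  }
  .write_stage_tsv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   file.path(outdir, "luciferase_fidelity.tsv"), par_hash)
}

.stage_growth <- function(cfg, pars, outdir, par_hash) {
  sim <- gen_growth(cfg)
  curves <- sim$curves
  key <- unique(curves[, c("strain", "condition", "replicate")])
  key$mu_max <- vapply(seq_len(nrow(key)), function(i) {
    sel <- curves$strain == key$strain[i] &
           curves$condition == key$condition[i] &
           curves$replicate == key$replicate[i]
    max_growth_rate(curves$time_min[sel], curves$od[sel])$mu_max
  }, numeric(1))
  ref_mu <- mean(key$mu_max[key$strain == names(cfg$growth$r)[1L]])
  agg <- stats::aggregate(mu_max ~ strain + condition, key, mean)
  agg$relative_pct <- relative_growth(agg$mu_max, ref_mu)
  .write_stage_tsv(agg, file.path(outdir, "growth_rates.tsv"), par_hash)
}
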