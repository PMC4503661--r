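#' Empirical cumulative distribution function of a fluorescence sample
#'
#' Right-continuous step function `F(x) =` fraction of values `<= x`
#' (so `F(max) = 1` and `F(x) = 0` below the minimum).
#'
#' @param x Non-empty numeric vector of intensities.
#' @return A function of class `ecdf`, evaluable at any x.
#' @export
sample_ecdf <- function(x) {
  if (length(x) == 0L || anyNA(x)) stop("sample must be non-empty without NAs")
  stats::ecdf(x)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' `D = sup_x |F_a(x) - F_b(x)|`, computed over the pooled observed values.
#' D is a rank statistic: it is invariant under any strictly monotone
#' transform applied to both samples, and `D = 0` iff the ECDFs coincide.
#'
#' @param a,b Non-empty numeric samples.
#' @return D in `[0, 1]`.
#' @examples
#' ks_distance(c(1, 3), c(2, 4))  # 0.5
#' @export
ks_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  xs <- sort(unique(c(a, b)))
  fa <- sample_ecdf(a)(xs)
  fb <- sample_ecdf(b)(xs)
  max(abs(fa - fb))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided p-value for the observed D. `"exact"` uses the exact
#' small-sample null distribution and is permitted only when
#' `n * m <= 10^4`; `"asymptotic"` uses the Kolmogorov limit with effective
#' size `n * m / (n + m)`. `"auto"` (default) chooses exact when permitted.
#' With ties the exact mode falls back to the asymptotic approximation.
#'
#' @param a,b Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return List with elements `D` and `p`.
#' @export
ks_test <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("samples must be non-empty")
  small <- as.numeric(n) * m <= 1e4
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(mode,
    auto = small && !ties,
    exact = {
      if (!small) stop("exact mode permitted only when n * m <= 1e4")
      !ties
    },
    asymptotic = FALSE)
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Replicate-baseline test for a fluorescence distribution shift
#'
#' Compares all within-genotype KS distances (the replicate baseline) with
#' all between-genotype distances, for every genotype pair. A "distribution
#' shift" is flagged only when every between-genotype D exceeds the maximum
#' within-genotype D *and* every between-pair KS p-value is below `alpha`;
#' with ~10,000 cells per sample the KS test alone is significant for
#' trivial shifts, so the effect-size condition is required.
#'
#' @param samples Named list of numeric intensity vectors.
#' @param genotypes Named character vector mapping sample names to genotype
#'   labels; every genotype needs at least 2 replicates.
#' @param alpha Significance level (default 0.05).
#' @param gate Gating threshold: intensities below `gate` are excluded
#'   before ECDF construction (default 0 = effectively no gate for
#'   non-negative data).
#' @return List with `within` and `between` pairwise tables (`data.frame`s
#'   of sample pairs, D and p) and `decisions`, one row per genotype pair:
#'   `max_within_D`, `min_between_D`, `max_between_p`, `shift` flag.
#' @export
replicate_baseline_test <- function(samples, genotypes, alpha = 0.05,
                                    gate = 0) {
  if (is.null(names(samples)) || !all(names(samples) %in% names(genotypes)))
    stop("samples and genotypes must share names")
  genotypes <- genotypes[names(samples)]
  if (any(table(genotypes) < 2L))
    stop("every genotype needs >= 2 replicates (no baseline otherwise)")
  samples <- lapply(samples, function(x) x[x >= gate])
  if (any(lengths(samples) == 0L)) stop("a sample is empty after gating")
  nm <- names(samples)
  pairs <- utils::combn(nm, 2L)
  tab <- data.frame(sample_a = pairs[1L, ], sample_b = pairs[2L, ],
                    stringsAsFactors = FALSE)
  tab$class <- ifelse(genotypes[tab$sample_a] == genotypes[tab$sample_b],
                      "within_genotype", "between_genotype")
  kt <- mapply(function(a, b) unlist(ks_test(samples[[a]], samples[[b]])),
               tab$sample_a, tab$sample_b)
  tab$D <- kt["D", ]
  tab$p <- kt["p", ]
  within <- tab[tab$class == "within_genotype", , drop = FALSE]
  between <- tab[tab$class == "between_genotype", , drop = FALSE]
  gl <- sort(unique(genotypes))
  gpairs <- utils::combn(gl, 2L)
  decisions <- do.call(rbind, lapply(seq_len(ncol(gpairs)), function(i) {
    ga <- gpairs[1L, i]; gb <- gpairs[2L, i]
    w <- within[genotypes[within$sample_a] %in% c(ga, gb), , drop = FALSE]
    b <- between[(genotypes[between$sample_a] == ga &
                  genotypes[between$sample_b] == gb) |
                 (genotypes[between$sample_a] == gb &
                  genotypes[between$sample_b] == ga), , drop = FALSE]
    data.frame(genotype_a = ga, genotype_b = gb,
               max_within_D = max(w$D), min_between_D = min(b$D),
               max_between_p = max(b$p),
               shift = min(b$D) > max(w$D) && all(b$p < alpha),
               stringsAsFactors = FALSE)
  }))
  list(within = within, between = between, decisions = decisions,
       alpha = alpha)
}
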