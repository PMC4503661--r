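#' Firefly/renilla luminescence ratio
#'
#' @param firefly,renilla Luminescence readings; `renilla` must be > 0.
#' @return `firefly / renilla` (vectorised).
#' @export
fl_ratio <- function(firefly, renilla) {
  if (any(renilla <= 0)) stop("renilla readings must be > 0")
  firefly / renilla
}

.mean_ratio <- function(df) mean(fl_ratio(df$firefly, df$renilla))

.check_same_strain <- function(a, b) {
  sa <- unique(a$strain); sb <- unique(b$strain)
  if (length(sa) > 1L || length(sb) > 1L || (length(sa) && length(sb) && sa != sb))
    stop("test and control measurements must come from one common strain")
}

#' Programmed ribosomal frameshifting efficiency
#'
#' The firefly/renilla ratio of the frameshift-signal reporter relative to
#' the 0-frame control reporter, times 100: the percentage of ribosomes that
#' shifted frame. The default aggregates replicate ratios per construct
#' before dividing; `method = "paired"` divides per-replicate ratios first
#' (requires matching `replicate` labels).
#'
#' @param test `data.frame` of the frameshift construct with columns
#'   `firefly`, `renilla` (optionally `strain`, `replicate`).
#' @param control Same for the 0-frame control construct (same strain).
#' @param method `"ratio_of_means"` (default) or `"paired"`.
#' @return Frameshifting efficiency in percent.
#' @examples
#' test <- data.frame(firefly = 1, renilla = 10)      # ratio 0.1
#' ctrl <- data.frame(firefly = 50, renilla = 10)     # ratio 5
#' frameshift_efficiency(test, ctrl)                  # 2 %
#' @export
frameshift_efficiency <- function(test, control,
                                  method = c("ratio_of_means", "paired")) {
  method <- match.arg(method)
  if (nrow(test) == 0L || nrow(control) == 0L)
    stop("test and control must be non-empty")
  if (!is.null(test$strain) && !is.null(control$strain))
    .check_same_strain(test, control)
  if (method == "ratio_of_means") {
    100 * .mean_ratio(test) / .mean_ratio(control)
  } else {
    if (is.null(test$replicate) || is.null(control$replicate) ||
        !setequal(test$replicate, control$replicate))
      stop("paired mode needs matching replicate labels")
    control <- control[match(test$replicate, control$replicate), ]
    100 * mean(fl_ratio(test$firefly, test$renilla) /
               fl_ratio(control$firefly, control$renilla))
  }
}

#' IRES activity relative to a reference strain
#'
#' Firefly/renilla ratio of the IRES reporter in a strain, normalised to the
#' same reporter's ratio in the reference (wild-type) strain, times 100.
#'
#' @param strain_df IRES reporter measurements for the strain of interest
#'   (`firefly`, `renilla` columns).
#' @param reference_df Same reporter in the reference strain.
#' @return IRES activity in percent of the reference.
#' @export
ires_activity <- function(strain_df, reference_df) {
  if (nrow(strain_df) == 0L || nrow(reference_df) == 0L)
    stop("measurement sets must be non-empty")
  ref <- .mean_ratio(reference_df)
  if (ref == 0) stop("reference ratio is zero")
  100 * .mean_ratio(strain_df) / ref
}

#' Stop-codon readthrough percentage
#'
#' Firefly/renilla ratio of the stop-codon reporter divided by the ratio of
#' the sense-codon reporter, times 100. A reporter identical to the sense
#' control would read 100% (the theoretical maximum).
#'
#' @param stop_df Stop-codon reporter measurements (`firefly`, `renilla`).
#' @param sense_df Sense-codon reporter measurements (same strain).
#' @return Readthrough in percent.
#' @export
readthrough_percent <- function(stop_df, sense_df) {
  if (nrow(stop_df) == 0L || nrow(sense_df) == 0L)
    stop("measurement sets must be non-empty")
  if (!is.null(stop_df$strain) && !is.null(sense_df$strain))
    .check_same_strain(stop_df, sense_df)
  100 * .mean_ratio(stop_df) / .mean_ratio(sense_df)
}

#' Compare a fidelity quantity between two strains
#'
#' Fold change of strain B over strain A on per-replicate efficiencies, with
#' a two-tailed Student t-test (equal variances by default; set
#' `var_equal = FALSE` for Welch) and per-strain SEM. With fewer than 3
#' replicates in either strain the p-value is withheld with a warning.
#'
#' @param values_a,values_b Per-replicate efficiency values for strains A
#'   and B.
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @return List: `mean_a`, `mean_b`, `sem_a`, `sem_b`, `fold`
#'   (`mean_b / mean_a`), `p` (two-tailed; `NA` when withheld).
#' @export
fidelity_compare <- function(values_a, values_b, var_equal = TRUE) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(mean_a = mean(values_a), mean_b = mean(values_b),
              sem_a = sem(values_a), sem_b = sem(values_b),
              fold = mean(values_b) / mean(values_a), p = NA_real_)
  if (length(values_a) < 3L || length(values_b) < 3L) {
    warning("fewer than 3 replicates per strain; p-value withheld")
    return(out)
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    out$p <- if (out$mean_a == out$mean_b) 1 else 0
    return(out)
  }
  out$p <- stats::t.test(values_a, values_b, var.equal = var_equal)$p.value
  out
}
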