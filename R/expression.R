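#' MA quantities from two expression vectors
#'
#' For each feature, `M = log2((cond + pseudocount) / (ref + pseudocount))`
#' and `A` is the geometric mean of the (pseudocounted) RPKM values, the
#' usual axes of an MA plot of mutant versus wild type.
#'
#' @param rpkm_ref,rpkm_cond Non-negative expression values (e.g. RPKM),
#'   equal length.
#' @param pseudocount Positive value added before the log to tame zeros
#'   (default 0.5).
#' @param feature_id Optional feature IDs.
#' @return `data.frame` with columns `feature_id` (if given), `M`, `A`.
#' @examples
#' ma_transform(8, 16, pseudocount = 1e-9)  # M = 1, A ~ 11.31
#' @export
ma_transform <- function(rpkm_ref, rpkm_cond, pseudocount = 0.5,
                         feature_id = NULL) {
  if (length(rpkm_ref) != length(rpkm_cond))
    stop("rpkm_ref and rpkm_cond must have equal length")
  if (any(rpkm_ref < 0) || any(rpkm_cond < 0)) stop("RPKM values must be >= 0")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  r <- rpkm_ref + pseudocount
  c_ <- rpkm_cond + pseudocount
  out <- data.frame(M = log2(c_ / r), A = sqrt(c_ * r))
  if (!is.null(feature_id)) out <- cbind(feature_id = feature_id, out)
  out
}

#' Absolute log2 cutoff for a fold-change threshold
#'
#' @param fc Fold change > 0 (default 1.5).
#' @return `|log2(fc)|`, with attribute `display` rounded to one decimal for
#'   reporting (1.5 gives 0.585, displayed as 0.6).
#' @export
fold_change_threshold <- function(fc = 1.5) {
  if (!is.numeric(fc) || fc <= 0) stop("fold change must be > 0")
  val <- abs(log2(fc))
  attr(val, "display") <- round(val, 1)
  val
}

#' Classify differentially expressed features
#'
#' A feature is DE when `adj_p < alpha`; direction follows the sign of `M`.
#' With a log2 cutoff, `|M| >= log2_cutoff` is additionally required.
#'
#' @param points `data.frame` with columns `M` and `adj_p` (no missing
#'   `adj_p` allowed).
#' @param alpha Adjusted p-value threshold (default 0.05).
#' @param log2_cutoff Optional absolute log2 fold-change cutoff.
#' @return List with `n_up`, `n_down`, `n_total_de`
#'   (`n_total_de = n_up + n_down`).
#' @export
classify_de <- function(points, alpha = 0.05, log2_cutoff = NULL) {
  if (!all(c("M", "adj_p") %in% names(points)))
    stop("points must have columns 'M' and 'adj_p'")
  if (anyNA(points$adj_p)) stop("missing adj_p values")
  de <- points$adj_p < alpha
  if (!is.null(log2_cutoff)) de <- de & abs(points$M) >= log2_cutoff
  n_up <- sum(de & points$M > 0)
  n_down <- sum(de & points$M < 0)
  list(n_up = n_up, n_down = n_down, n_total_de = n_up + n_down)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P[X >= overlap_x]` for drawing `selected_n`
#' features out of a population of `population_n` of which `annotated_k`
#' carry the term — the standard gene-set over-representation test.
#'
#' @param population_n Population size N.
#' @param annotated_k Features annotated with the term, k.
#' @param selected_n Size of the selected list, n.
#' @param overlap_x Annotated features in the selection, x.
#' @return The p-value `P[X >= x]` under Hypergeometric(N, k, n).
#' @examples
#' hypergeom_enrichment(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_enrichment <- function(population_n, annotated_k, selected_n,
                                 overlap_x) {
  if (annotated_k > population_n || selected_n > population_n ||
      overlap_x > annotated_k || overlap_x > selected_n ||
      any(c(population_n, annotated_k, selected_n, overlap_x) < 0))
    stop("inconsistent hypergeometric arguments")
  stats::phyper(overlap_x - 1, annotated_k, population_n - annotated_k,
                selected_n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; values are capped at 1 and monotone
#' non-decreasing in rank order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
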