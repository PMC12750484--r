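#' Cohen's weighted kappa for two raters
#'
#' Chance-corrected two-rater agreement with partial credit for near-miss
#' ordinal disagreements. With cell proportions `p_kl` of the q x q
#' cross-classification and marginals `p_k+`, `p_+l`:
#' `p_a = sum_kl w_kl p_kl`, `p_e = sum_kl w_kl p_k+ p_+l`,
#' `kappa_w = (p_a - p_e) / (1 - p_e)`.
#'
#' Provided for methodological comparison with Gwet's AC2: because `p_e`
#' is built from rater marginals, kappa can be near zero despite very high
#' observed agreement when one category dominates (the kappa paradox; see
#' [paradox_fixture()]).
#'
#' The standard error is the large-sample (non-null) estimator of Fleiss,
#' Cohen and Everitt (1969); the confidence interval uses the same
#' t(n - 1) convention as [gwet_agreement()].
#'
#' @param pair_table q x q matrix of nonnegative counts: rows = first
#'   rater's category, columns = second rater's category.
#' @param weights Weight family name, [make_weights()] object, or q x q
#'   matrix.
#' @param conflev Confidence level, default 0.95.
#' @return An `"agreement_estimate"` with `method = "cohen_weighted_kappa"`;
#'   `n_subjects` is the table total.
#' @examples
#' cohen_weighted_kappa(paradox_fixture(), weights = "identity")
#' @references Fleiss, J.L., Cohen, J., Everitt, B.S. (1969). Large sample
#'   standard errors of kappa and weighted kappa. Psychological Bulletin,
#'   72, 323-327.
#' @export
cohen_weighted_kappa <- function(pair_table, weights = "ordinal", conflev = 0.95) {
  tab <- as.matrix(pair_table)
  if (nrow(tab) != ncol(tab)) stop("pair table must be square", call. = FALSE)
  if (any(tab < 0)) stop("pair table must have nonnegative counts", call. = FALSE)
  n <- sum(tab)
  if (n < 1) stop("empty pair table", call. = FALSE)
  q <- nrow(tab)
  W <- as_agreement_weights(weights, q)
  w <- W$w
  p <- tab / n
  prow <- rowSums(p)
  pcol <- colSums(p)
  p_a <- sum(w * p)
  p_e <- sum(w * outer(prow, pcol))
  if (p_e >= 1 - 1e-12)
    stop("degenerate chance agreement: p_e = 1", call. = FALSE)
  kap <- (p_a - p_e) / (1 - p_e)

  # Fleiss-Cohen-Everitt large-sample variance
  wbar_row <- as.vector(w %*% pcol)   # row-conditional expected weights
  wbar_col <- as.vector(prow %*% w)
  term <- (w * (1 - p_e) - outer(wbar_row, wbar_col, "+") * (1 - p_a))^2
  v <- (sum(p * term) - (p_a * p_e - 2 * p_e + p_a)^2) / (n * (1 - p_e)^4)
  se <- sqrt(max(v, 0))
  tcrit <- if (n >= 2) stats::qt(1 - (1 - conflev) / 2, n - 1) else NA_real_
  new_agreement_estimate("cohen_weighted_kappa", kap, p_a, p_e, se,
                         kap - tcrit * se, kap + tcrit * se,
                         as.integer(n), W$kind, conflev)
}
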