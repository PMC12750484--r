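#' Reduce a subjects x raters category matrix to category counts
#'
#' The multi-rater agreement formulas work on `r_ik`, the number of raters
#' assigning subject `i` to category `k`. Missing ratings (`NA`) are
#' allowed; subjects rated by fewer than two raters still contribute to the
#' category prevalences but not to observed agreement.
#'
#' @param ratings Matrix (or data frame) of category values, one row per
#'   subject, one column per rater; entries must belong to `categories`.
#' @param categories The full, instrument-defined category vector (e.g. the
#'   feature's [composite_range()]), fixed in advance of the data.
#' @return Integer matrix of counts, `n` subjects x `q` categories, with the
#'   categories as column names.
#' @export
subject_category_counts <- function(ratings, categories) {
  ratings <- as.matrix(ratings)
  categories <- sort(unique(categories))
  if (length(categories) < 2L)
    stop("agreement needs q >= 2 categories", call. = FALSE)
  obs <- ratings[!is.na(ratings)]
  if (length(obs) && !all(obs %in% categories))
    stop("ratings contain values outside the declared category set: ",
         paste(utils::head(setdiff(obs, categories), 5L), collapse = ", "),
         call. = FALSE)
  counts <- matrix(0L, nrow = nrow(ratings), ncol = length(categories),
                   dimnames = list(rownames(ratings), categories))
  for (j in seq_len(ncol(ratings))) {
    k <- match(ratings[, j], categories)
    ok <- which(!is.na(k))
    idx <- cbind(ok, k[ok])
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

#' Gwet's chance-corrected agreement coefficient (AC1/AC2)
#'
#' Computes the weighted multi-rater agreement coefficient of Gwet, designed
#' to stay well-behaved under imbalanced category prevalences where Cohen's
#' kappa collapses (the "kappa paradox"). With identity weights this is AC1;
#' with a non-trivial weight matrix it is the weighted AC2.
#'
#' For `n` subjects, counts `r_ik` of raters per category, `r_i` raters per
#' subject and weights `w_kl`:
#' weighted counts `r*_ik = sum_l w_kl r_il`; per-subject observed agreement
#' `p_a|i = sum_k r_ik (r*_ik - 1) / (r_i (r_i - 1))`, averaged over the
#' `n'` subjects with `r_i >= 2`; prevalences
#' `pi_k = (1/n) sum_i r_ik / r_i`; chance agreement
#' `p_e = T_w / (q (q - 1)) * sum_k pi_k (1 - pi_k)` with
#' `T_w = sum_kl w_kl`; and the coefficient `(p_a - p_e) / (1 - p_e)`.
#'
#' The standard error comes from the linearized per-subject decomposition of
#' the coefficient (the estimator also used by dedicated agreement software);
#' the confidence interval is `coefficient +/- t(1 - alpha/2, n - 1) * se`
#' and is deliberately not truncated to `[-1, 1]`.
#'
#' @param counts Either an `n x q` count matrix from
#'   [subject_category_counts()], or a subjects x raters category matrix (in
#'   which case `categories` must be given).
#' @param weights Weight family name, [make_weights()] object, or custom
#'   q x q matrix.
#' @param categories Full category set; required when `counts` is a raw
#'   ratings matrix, optional (taken from column names) for a count matrix.
#' @param conflev Confidence level, default 0.95.
#' @param N Finite population size for the finite-population correction;
#'   default `Inf` (no correction: subjects are a sample from an unbounded
#'   population of recordings).
#' @return An object of class `"agreement_estimate"`: list with `method`,
#'   `coefficient`, `p_a`, `p_e`, `se`, `ci_low`, `ci_high`, `n_subjects`
#'   (subjects contributing to observed agreement), `weights_kind`, `band`.
#' @examples
#' m <- rbind(c(0, 0), c(0, 1), c(1, 1), c(0, 0))  # two raters, four subjects
#' gwet_agreement(m, weights = "identity", categories = 0:1)
#' @references Gwet, K.L. (2008). Computing inter-rater reliability and its
#'   variance in the presence of high agreement. British Journal of
#'   Mathematical and Statistical Psychology, 61, 29-48.
#' @export
gwet_agreement <- function(counts, weights = "ordinal", categories = NULL,
                           conflev = 0.95, N = Inf) {
  if (!is.null(categories)) {
    counts <- subject_category_counts(counts, categories)
  } else {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
      stop("'categories' is required unless 'counts' has category column names",
           call. = FALSE)
  }
  q <- ncol(counts)
  if (q < 2L) stop("agreement needs q >= 2 categories", call. = FALSE)
  W <- as_agreement_weights(weights, q)
  wmat <- W$w

  ri <- rowSums(counts)
  counts <- counts[ri > 0, , drop = FALSE]
  ri <- ri[ri > 0]
  n <- nrow(counts)
  if (n < 1L) stop("no rated subjects", call. = FALSE)
  multi <- ri >= 2
  n_prime <- sum(multi)
  if (n_prime < 1L)
    stop("observed agreement undefined: every subject is rated by fewer than two raters",
         call. = FALSE)

  rstar <- counts %*% wmat                       # r*_ik = sum_l w_kl r_il (w symmetric)
  sum_q <- rowSums(counts * (rstar - 1))
  den <- ri * (ri - 1)
  pa_i <- ifelse(multi, sum_q / pmax(den, 1), 0)
  p_a <- sum(pa_i[multi]) / n_prime

  pi_k <- colSums(counts / ri) / n
  Tw <- sum(wmat)
  p_e <- Tw / (q * (q - 1)) * sum(pi_k * (1 - pi_k))
  if (p_e >= 1 - 1e-12)
    stop("degenerate chance agreement: p_e = 1", call. = FALSE)
  coef <- (p_a - p_e) / (1 - p_e)

  # Linearized per-subject variance (Gwet 2008): influence of subject i on the
  # coefficient through both p_a and p_e.
  f <- if (is.finite(N)) n / N else 0
  if (n >= 2) {
    pe_r2 <- p_e * multi
    coef_i <- (n / n_prime) * (pa_i - pe_r2) / (1 - p_e)
    pe_i <- (Tw / (q * (q - 1))) * drop(counts %*% (1 - pi_k)) / ri
    coef_i_star <- coef_i - 2 * (1 - coef) * (pe_i - p_e) / (1 - p_e)
    v <- ((1 - f) / (n * (n - 1))) * sum((coef_i_star - coef)^2)
    se <- sqrt(v)
    tcrit <- stats::qt(1 - (1 - conflev) / 2, n - 1)
    ci <- coef + c(-1, 1) * tcrit * se
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }

  new_agreement_estimate(
    method = if (W$kind == "identity") "gwet_ac1" else "gwet_ac2",
    coefficient = coef, p_a = p_a, p_e = p_e, se = se,
    ci_low = ci[1], ci_high = ci[2], n_subjects = n_prime,
    weights_kind = W$kind, conflev = conflev)
}

new_agreement_estimate <- function(method, coefficient, p_a, p_e, se,
                                   ci_low, ci_high, n_subjects, weights_kind,
                                   conflev = 0.95) {
  structure(
    list(method = method, coefficient = coefficient, p_a = p_a, p_e = p_e,
         se = se, ci_low = ci_low, ci_high = ci_high,
         n_subjects = n_subjects, weights_kind = weights_kind,
         conflev = conflev, band = interpret_band(coefficient)),
    class = "agreement_estimate")
}

#' @export
print.agreement_estimate <- function(x, ...) {
  cat(sprintf("<%s> coefficient = %.4f (%d%% CI %.4f, %.4f), band: %s\n",
              x$method, x$coefficient, round(100 * x$conflev),
              x$ci_low, x$ci_high, x$band))
  cat(sprintf("  p_a = %.4f, p_e = %.4f, se = %.4f, n = %d, weights = %s\n",
              x$p_a, x$p_e, x$se, x$n_subjects, x$weights_kind))
  invisible(x)
}

#' @export
as.data.frame.agreement_estimate <- function(x, ...) {
  data.frame(method = x$method, weights_kind = x$weights_kind,
             coefficient = x$coefficient, p_a = x$p_a, p_e = x$p_e,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             n_subjects = x$n_subjects, band = x$band,
             stringsAsFactors = FALSE)
}

#' Percent (weighted) observed agreement
#'
#' The observed-agreement component `p_a` alone, without chance correction;
#' reported alongside the chance-corrected coefficients.
#'
#' @inheritParams gwet_agreement
#' @return An `"agreement_estimate"` with `p_e = 0` and
#'   `coefficient = p_a`; the se/CI are for the mean per-subject agreement.
#' @export
percent_agreement <- function(counts, weights = "identity", categories = NULL,
                              conflev = 0.95) {
  if (!is.null(categories)) counts <- subject_category_counts(counts, categories)
  counts <- as.matrix(counts)
  q <- ncol(counts)
  W <- as_agreement_weights(weights, q)
  ri <- rowSums(counts)
  counts <- counts[ri >= 2, , drop = FALSE]
  ri <- ri[ri >= 2]
  n <- nrow(counts)
  if (n < 1L) stop("observed agreement undefined: no multiply-rated subjects",
                   call. = FALSE)
  rstar <- counts %*% W$w
  pa_i <- rowSums(counts * (rstar - 1)) / (ri * (ri - 1))
  p_a <- mean(pa_i)
  se <- if (n >= 2) stats::sd(pa_i) / sqrt(n) else NA_real_
  tcrit <- if (n >= 2) stats::qt(1 - (1 - conflev) / 2, n - 1) else NA_real_
  new_agreement_estimate("percent_agreement", p_a, p_a, 0, se,
                         p_a - tcrit * se, p_a + tcrit * se, n, W$kind, conflev)
}
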