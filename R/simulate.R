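#' Configuration for a synthetic multi-rater bronchoscopy study
#'
#' Describes a latent-severity generative model for ordinal per-lobe
#' ratings. Per subject `i` and feature `f` a latent severity
#' `theta_if ~ N(mu_group,f, severity_sd)` is drawn; each lobe adds
#' within-subject variation `x_ifl = theta_if + N(0, lobe_sd)`; rater `j`
#' observes `y = x_ifl + bias_j + N(0, noise_sd_j)` and the per-lobe score
#' is the number of the feature's cutpoints lying below `y`. Shifting the
#' cutpoints up relative to the latent mean makes high scores rare,
#' reproducing the imbalanced score marginals typical of rare clinical
#' findings.
#'
#' The defaults emulate the study conditions the package is built around:
#' 80 recordings (50 CF, 30 non-CF), four raters (one trained medical
#' student and three pediatric pulmonologists, modelled as exchangeable:
#' bias 0, noise sd 0.6 latent units), the ten-feature registry, and
#' cutpoints placed so that score 0 dominates most features. CF subjects
#' get a positive latent shift on the secretion-related features
#' (`group_shift`), so CF strata show higher composite scores.
#'
#' @param n_subjects Number of subjects (recordings); default 80.
#' @param group_split Fraction of subjects in the CF group; default 0.625
#'   (50 of 80).
#' @param raters Data frame with columns `rater_id`, `bias`, `noise_sd`;
#'   default four raters with bias 0 and noise sd 0.6.
#' @param features Data frame with columns `feature_id`, `per_lobe_max`,
#'   and a list-column `cutpoints` (strictly increasing, length
#'   `per_lobe_max`); default derived from [default_feature_registry()].
#' @param severity_sd Between-subject latent spread; default 1.
#' @param lobe_sd Within-subject between-lobe spread; default 0.4.
#' @param group_shift Named numeric: latent mean shift added for CF
#'   subjects, per feature (features absent from the vector get 0).
#' @param seed Integer seed; mandatory (no global random state is used).
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 80L,
                              group_split = 0.625,
                              raters = default_sim_raters(),
                              features = default_sim_features(),
                              severity_sd = 1,
                              lobe_sd = 0.4,
                              group_shift = default_group_shift(),
                              seed) {
  if (missing(seed)) stop("'seed' is mandatory in a simulation_config", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 1L, group_split >= 0, group_split <= 1,
            severity_sd >= 0, lobe_sd >= 0)
  stopifnot(all(c("rater_id", "bias", "noise_sd") %in% names(raters)))
  if (any(raters$noise_sd < 0)) stop("rater noise_sd must be >= 0", call. = FALSE)
  stopifnot(all(c("feature_id", "per_lobe_max", "cutpoints") %in% names(features)))
  for (i in seq_len(nrow(features))) {
    cp <- features$cutpoints[[i]]
    if (length(cp) != features$per_lobe_max[i] || is.unsorted(cp, strictly = TRUE))
      stop(sprintf("feature '%s': cutpoints must be strictly increasing with length %d",
                   features$feature_id[i], features$per_lobe_max[i]), call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, group_split = group_split,
                 raters = raters, features = features,
                 severity_sd = severity_sd, lobe_sd = lobe_sd,
                 group_shift = group_shift, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_sim_raters <- function() {
  data.frame(rater_id = c("student", "expert1", "expert2", "expert3"),
             bias = 0, noise_sd = 0.6, stringsAsFactors = FALSE)
}

#' @rdname simulation_config
#' @export
default_sim_features <- function(registry = default_feature_registry()) {
  feats <- lapply(registry, function(f) {
    L <- f$per_lobe_max
    # first cutpoint above the latent mean 0 => score 0 is the modal category
    cp <- 0.6 + 1.1 * (seq_len(L) - 1)
    list(feature_id = f$feature_id, per_lobe_max = L, cutpoints = cp)
  })
  data.frame(feature_id = vapply(feats, `[[`, "", "feature_id"),
             per_lobe_max = vapply(feats, `[[`, 0L, "per_lobe_max"),
             cutpoints = I(lapply(feats, `[[`, "cutpoints")),
             stringsAsFactors = FALSE)
}

#' @rdname simulation_config
#' @export
default_group_shift <- function() {
  c(secretion_color = 0.8, secretion_amount = 0.8, viscosity = 0.6,
    mucus_plugging = 0.6, mucosal_edema = 0.4)
}

#' Simulate a multi-rater per-lobe rating study
#'
#' Draws a long-format ratings table from the latent-severity model of a
#' [simulation_config()]. Fully reproducible: the same config (including
#' seed) yields an identical table, and the caller's RNG state is left
#' untouched.
#'
#' @param config A [simulation_config()].
#' @return Ratings data frame with columns `subject_id`, `group`,
#'   `rater_id`, `feature_id`, `lobe`, `score` (the ratings CSV dialect).
#' @examples
#' r <- simulate_ratings(simulation_config(n_subjects = 6, seed = 42))
#' head(r)
#' @export
simulate_ratings <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, simulate_ratings_impl(config))
}

simulate_ratings_impl <- function(config) {
  n <- config$n_subjects
  lobes <- canonical_lobes()
  nl <- length(lobes)
  nr <- nrow(config$raters)
  n_cf <- round(config$group_split * n)
  subj <- sprintf("S%03d", seq_len(n))
  group <- c(rep("CF", n_cf), rep("nonCF", n - n_cf))

  out <- vector("list", nrow(config$features))
  for (fi in seq_len(nrow(config$features))) {
    fid <- config$features$feature_id[fi]
    cp <- config$features$cutpoints[[fi]]
    shift <- ifelse(group == "CF",
                    unname(config$group_shift[fid] %|NA|% 0), 0)
    theta <- stats::rnorm(n, mean = shift, sd = config$severity_sd)
    x <- theta[rep(seq_len(n), each = nl)] +
      stats::rnorm(n * nl, sd = config$lobe_sd)          # subject-lobe latent
    # raters observe every subject-lobe value
    y <- rep(x, times = nr) +
      rep(config$raters$bias, each = n * nl) +
      stats::rnorm(n * nl * nr,
                   sd = rep(config$raters$noise_sd, each = n * nl))
    score <- findInterval(y, cp)
    out[[fi]] <- data.frame(
      subject_id = rep(subj, each = nl, times = nr),
      group = rep(group, each = nl, times = nr),
      rater_id = rep(config$raters$rater_id, each = n * nl),
      feature_id = fid,
      lobe = rep(lobes, times = n * nr),
      score = as.integer(score),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The two-rater prevalence-paradox fixture
#'
#' A fixed binary cross-classification of 100 subjects by two raters:
#' 90 both-negative, 5 + 4 discordant, 1 both-positive. Observed agreement
#' is 0.91, yet Cohen's kappa is only ~0.135 because the dominant negative
#' category inflates kappa's marginal-based chance correction, while Gwet's
#' AC1 gives ~0.90 -- the prevalence paradox that motivates AC2 for rare
#' clinical findings.
#'
#' @return 2 x 2 integer matrix with dimnames `0`/`1` (rows: rater 1).
#' @examples
#' tab <- paradox_fixture()
#' cohen_weighted_kappa(tab, "identity")$coefficient   # ~0.135
#' @export
paradox_fixture <- function() {
  matrix(c(90L, 5L, 4L, 1L), 2, 2, byrow = TRUE,
         dimnames = list(rater1 = c("0", "1"), rater2 = c("0", "1")))
}

#' Expand a two-rater contingency table to per-subject category counts
#'
#' Convenience for feeding a q x q pair table (e.g. [paradox_fixture()])
#' into the multi-rater engine [gwet_agreement()].
#'
#' @param pair_table q x q count matrix.
#' @return n x q count matrix, one row per subject.
#' @export
pair_table_to_counts <- function(pair_table) {
  tab <- as.matrix(pair_table)
  q <- nrow(tab)
  stopifnot(q == ncol(tab))
  rows <- list()
  for (k in seq_len(q)) for (l in seq_len(q)) {
    m <- tab[k, l]
    if (m > 0) {
      cnt <- integer(q); cnt[k] <- cnt[k] + 1L; cnt[l] <- cnt[l] + 1L
      rows[[length(rows) + 1L]] <- matrix(cnt, m, q, byrow = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(tab) %||% as.character(seq_len(q) - 1L)
  out
}
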