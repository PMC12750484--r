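# Independent oracles, written as literal transcriptions of the published
# rules / direct summation of the defining formulas. They deliberately share
# no code with the package implementation.

# Literal transcription of the published composite rules for a 0-2 per-lobe
# scale, as a top-down case analysis (with "rated v" read as "rated >= v" so
# mixed vectors are covered):
#   3 = three or more lobes rated 2
#   2 = three or more lobes rated (>=)1, or at least one lobe rated 2
#   1 = at least one lobe rated (>=)1
#   0 = all lobes rated 0
oracle_composite_L2 <- function(scores) {
  n1 <- sum(scores >= 1); n2 <- sum(scores >= 2)
  maj <- floor(length(scores) / 2) + 1
  if (n2 >= maj) return(3L)
  if (n1 >= maj || n2 >= 1) return(2L)
  if (n1 >= 1) return(1L)
  0L
}

# Same case analysis extended one level for a 0-3 scale (secretion amount).
oracle_composite_L3 <- function(scores) {
  n1 <- sum(scores >= 1); n2 <- sum(scores >= 2); n3 <- sum(scores >= 3)
  maj <- floor(length(scores) / 2) + 1
  if (n3 >= maj) return(4L)
  if (n2 >= maj || n3 >= 1) return(3L)
  if (n1 >= maj || n2 >= 1) return(2L)
  if (n1 >= 1) return(1L)
  0L
}

# And reduced to the binary per-lobe scale (mucus plugging).
oracle_composite_L1 <- function(scores) {
  n1 <- sum(scores >= 1)
  maj <- floor(length(scores) / 2) + 1
  if (n1 >= maj) return(2L)
  if (n1 >= 1) return(1L)
  0L
}

# Direct-summation Gwet coefficient on an n x q count matrix: explicit loops
# over subjects and categories, no matrix algebra.
oracle_gwet <- function(counts, w) {
  n <- nrow(counts); q <- ncol(counts)
  ri <- rowSums(counts)
  pa_sum <- 0; nprime <- 0
  for (i in seq_len(n)) {
    if (ri[i] >= 2) {
      s <- 0
      for (k in seq_len(q)) {
        rstar <- 0
        for (l in seq_len(q)) rstar <- rstar + w[k, l] * counts[i, l]
        s <- s + counts[i, k] * (rstar - 1)
      }
      pa_sum <- pa_sum + s / (ri[i] * (ri[i] - 1))
      nprime <- nprime + 1
    }
  }
  pa <- pa_sum / nprime
  pik <- numeric(q)
  for (k in seq_len(q)) {
    for (i in seq_len(n)) pik[k] <- pik[k] + counts[i, k] / ri[i]
    pik[k] <- pik[k] / n
  }
  Tw <- sum(w)
  pe <- Tw / (q * (q - 1)) * sum(pik * (1 - pik))
  list(p_a = unname(pa), p_e = unname(pe),
       coefficient = unname((pa - pe) / (1 - pe)))
}

# Leave-one-subject-out jackknife SE of the Gwet coefficient.
jackknife_se_gwet <- function(counts, w) {
  n <- nrow(counts)
  theta <- vapply(seq_len(n), function(i)
    oracle_gwet(counts[-i, , drop = FALSE], w)$coefficient, 0)
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

# Direct-summation weighted kappa on a q x q pair table.
oracle_kappa <- function(tab, w) {
  n <- sum(tab); q <- nrow(tab)
  p <- tab / n
  pa <- 0; pe <- 0
  for (k in seq_len(q)) for (l in seq_len(q)) {
    pa <- pa + w[k, l] * p[k, l]
    pe <- pe + w[k, l] * sum(p[k, ]) * sum(p[, l])
  }
  (pa - pe) / (1 - pe)
}

# Random small agreement instance: n subjects, r raters, q categories, with
# clustered (non-uniform) category use so all weight families get exercised.
random_counts <- function(n, r, q) {
  probs <- as.vector(stats::rmultinom(1, 20, rep(1, q)) + 1)
  ratings <- matrix(sample(seq_len(q) - 1L, n * r, TRUE, prob = probs), n, r)
  # knock out some ratings to exercise the r_i < r path
  if (r > 2 && stats::runif(1) < 0.5)
    ratings[sample(length(ratings), ceiling(n * r / 10))] <- NA
  bronchoscore::subject_category_counts(ratings, 0:(q - 1))
}

# One-feature simulation config used for agreement-engine studies in tests:
# a 0-2 threshold feature at the default study noise settings.
one_feature_config <- function(n_subjects, seed, noise_sd = 0.6,
                               cutpoints = c(0.3, 1.3)) {
  simulation_config(
    n_subjects = n_subjects,
    raters = data.frame(rater_id = paste0("R", 1:4), bias = 0,
                        noise_sd = noise_sd, stringsAsFactors = FALSE),
    features = data.frame(feature_id = "viscosity", per_lobe_max = 2L,
                          cutpoints = I(list(cutpoints)),
                          stringsAsFactors = FALSE),
    severity_sd = 1, lobe_sd = 0.4, seed = seed)
}

# Simulate -> compose -> subjects x raters matrix for the single feature.
simulate_feature_matrix <- function(config) {
  r <- simulate_ratings(config)
  comp <- compose_all(r, default_feature_registry())
  ratings_matrix(comp, config$features$feature_id[1])
}
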