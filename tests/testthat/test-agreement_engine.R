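test_that("weight matrices satisfy their defining formulas and invariants", {
  expect_identical(make_weights("identity", 2)$w, diag(2))
  expect_equal(make_weights("linear", 3)$w[1, 2], 0.5)
  expect_equal(make_weights("ordinal", 3)$w[1, 2], 2 / 3)
  expect_equal(make_weights("ordinal", 3)$w[1, 3], 0)
  expect_equal(make_weights("quadratic", 4)$w[1, 3], 1 - 4 / 9)
  for (kind in c("identity", "linear", "quadratic", "ordinal")) {
    for (q in 2:6) {
      w <- make_weights(kind, q)$w
      expect_equal(diag(w), rep(1, q))
      expect_true(all(w >= 0 & w <= 1))
      expect_equal(w, t(w))
    }
  }
  expect_error(make_weights("identity", 1), "q >= 2")
})

test_that("perfect agreement gives a coefficient of exactly 1 for any weights", {
  set.seed(202)
  for (kind in c("identity", "ordinal", "quadratic")) {
    vals <- sample(0:3, 15, replace = TRUE)
    m <- matrix(vals, 15, 4)       # four identical raters
    est <- gwet_agreement(m, weights = kind, categories = 0:3)
    expect_identical(est$coefficient, 1)
    expect_identical(est$p_a, 1)
  }
})

test_that("hand-computed two-rater fixture reproduces AC1 = 0.529412", {
  m <- rbind(c(0, 0), c(0, 1), c(1, 1), c(0, 0))
  est <- gwet_agreement(m, weights = "identity", categories = 0:1)
  expect_equal(est$p_a, 0.75)
  expect_equal(est$p_e, 0.46875)
  expect_equal(est$coefficient, 0.28125 / 0.53125, tolerance = 1e-12)
  expect_equal(est$coefficient, 0.529412, tolerance = 1e-5)
})

test_that("the prevalence paradox: high percent agreement, low kappa, high AC1", {
  tab <- paradox_fixture()
  counts <- pair_table_to_counts(tab)
  pa <- percent_agreement(counts, "identity")
  expect_equal(pa$coefficient, 0.91)
  kap <- cohen_weighted_kappa(tab, "identity")
  expect_equal(kap$p_e, 0.896)
  expect_equal(kap$coefficient, 0.014 / 0.104, tolerance = 1e-12)
  expect_equal(kap$coefficient, 0.134615, tolerance = 1e-5)
  ac1 <- gwet_agreement(counts, "identity")
  expect_equal(ac1$p_a, 0.91)
  expect_equal(ac1$p_e, 0.10395)
  expect_equal(ac1$coefficient, 32242 / 35842, tolerance = 1e-12)  # 0.8995592...
  # the same data, two verdicts: kappa "slight", AC1 "almost perfect"
  expect_identical(interpret_band(kap$coefficient), "slight_poor")
  expect_identical(interpret_band(ac1$coefficient), "almost_perfect")
})

test_that("gwet_agreement matches the direct-summation oracle on random instances", {
  set.seed(303)
  for (rep in 1:200) {
    n <- sample(2:10, 1); r <- sample(2:4, 1); q <- sample(2:5, 1)
    counts <- random_counts(n, r, q)
    if (all(rowSums(counts) < 2)) next
    kind <- sample(c("identity", "linear", "quadratic", "ordinal"), 1)
    w <- make_weights(kind, q)
    got <- gwet_agreement(counts, weights = w)
    want <- oracle_gwet(counts, w$w)
    expect_equal(got$coefficient, want$coefficient, tolerance = 1e-12)
    expect_equal(got$p_a, want$p_a, tolerance = 1e-12)
    expect_equal(got$p_e, want$p_e, tolerance = 1e-12)
  }
})

test_that("identity weights reduce AC2 to the unweighted AC1 formula", {
  set.seed(404)
  for (rep in 1:25) {
    counts <- random_counts(8, 3, 4)
    if (all(rowSums(counts) < 2)) next
    est <- gwet_agreement(counts, weights = "identity")
    expect_identical(est$method, "gwet_ac1")
    # independent unweighted AC1: pa from exact matches, pe = sum pi(1-pi)/(q-1)
    ri <- rowSums(counts); multi <- ri >= 2
    pa <- mean(rowSums(counts * (counts - 1))[multi] /
                 (ri * (ri - 1))[multi])
    pik <- colSums(counts / ri) / nrow(counts)
    pe <- sum(pik * (1 - pik)) / (ncol(counts) - 1)
    expect_equal(est$p_a, pa, tolerance = 1e-14)
    expect_equal(est$p_e, pe, tolerance = 1e-14)
  }
})

test_that("independent uniform raters give a coefficient near zero", {
  set.seed(505)
  n <- 2000
  m <- matrix(sample(0:3, n * 4, replace = TRUE), n, 4)
  est <- gwet_agreement(m, weights = "ordinal", categories = 0:3)
  expect_lt(abs(est$coefficient), 3 * est$se)
})

test_that("estimates are invariant to subject order and rater relabeling", {
  set.seed(606)
  m <- matrix(sample(0:2, 30 * 3, TRUE), 30, 3)
  est <- gwet_agreement(m, "ordinal", categories = 0:2)
  perm <- gwet_agreement(m[sample(30), ], "ordinal", categories = 0:2)
  swap <- gwet_agreement(m[, c(3, 1, 2)], "ordinal", categories = 0:2)
  expect_equal(perm$coefficient, est$coefficient, tolerance = 1e-14)
  expect_equal(perm$se, est$se, tolerance = 1e-14)
  expect_equal(swap$coefficient, est$coefficient, tolerance = 1e-14)
  # two-rater table transposition leaves the symmetric-weight statistics alone
  tab <- matrix(c(40, 6, 3, 11, 20, 5, 2, 7, 6), 3, 3)
  for (kind in c("identity", "ordinal")) {
    k1 <- cohen_weighted_kappa(tab, kind)
    k2 <- cohen_weighted_kappa(t(tab), kind)
    expect_equal(k1$coefficient, k2$coefficient, tolerance = 1e-14)
    a1 <- gwet_agreement(pair_table_to_counts(tab), kind)
    a2 <- gwet_agreement(pair_table_to_counts(t(tab)), kind)
    expect_equal(a1$coefficient, a2$coefficient, tolerance = 1e-14)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  single <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                   dimnames = list(NULL, c("0", "1")))   # one rater per subject
  expect_error(gwet_agreement(single), "fewer than two raters")
  expect_error(gwet_agreement(matrix(0:1, 2, 2), weights = "identity",
                              categories = 0),
               "q >= 2")
  expect_error(cohen_weighted_kappa(matrix(0, 2, 2), "identity"), "empty")
  expect_error(cohen_weighted_kappa(matrix(c(5, 0, 0, 0), 2, 2), "identity"),
               "degenerate")
  # a single observed category is fine for AC1: pi = (1, 0) gives p_e = 0,
  # coefficient 1 (this is exactly where kappa degenerates and AC does not)
  m <- matrix(0L, 5, 2)
  expect_identical(gwet_agreement(m, "identity", categories = 0:1)$coefficient, 1)
})

test_that("weighted kappa matches its direct-summation oracle and examples", {
  expect_equal(cohen_weighted_kappa(diag(c(5, 3, 2)), "ordinal")$coefficient, 1)
  expect_equal(cohen_weighted_kappa(matrix(1, 2, 2), "identity")$coefficient, 0)
  set.seed(707)
  for (rep in 1:40) {
    q <- sample(2:5, 1)
    tab <- matrix(stats::rpois(q * q, 3), q, q)
    if (sum(tab) == 0) next
    kind <- sample(c("identity", "linear", "quadratic", "ordinal"), 1)
    w <- make_weights(kind, q)
    got <- cohen_weighted_kappa(tab, w)
    if (got$p_e >= 1 - 1e-12) next
    expect_equal(got$coefficient, oracle_kappa(tab, w$w), tolerance = 1e-12)
  }
})

test_that("CI uses t quantiles and is not truncated at 1", {
  # small n with near-perfect agreement: upper bound exceeds 1
  m <- rbind(matrix(2L, 9, 2), c(2L, 1L))
  est <- gwet_agreement(m, "identity", categories = 0:2)
  expect_gt(est$ci_high, 1)
  expect_lt(est$ci_low, est$coefficient)
  expect_equal(est$ci_high - est$coefficient,
               stats::qt(0.975, 9) * est$se, tolerance = 1e-12)
})

test_that("Landis-Koch bands form contiguous half-open intervals", {
  expect_identical(interpret_band(0.94), "almost_perfect")
  expect_identical(interpret_band(0.47), "moderate")
  expect_identical(interpret_band(0.15), "slight_poor")
  expect_identical(interpret_band(c(0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80, 0.81)),
                   c("slight_poor", "fair", "fair", "moderate", "moderate",
                     "substantial", "substantial", "almost_perfect"))
  expect_identical(interpret_band(1.07), "almost_perfect")  # untruncated CI bound
  expect_identical(interpret_band(-0.3), "slight_poor")
  # total on reals, no gaps: every coefficient gets exactly one band
  x <- seq(-1, 1.2, by = 0.01)
  expect_false(anyNA(interpret_band(x)))
})

test_that("pairwise agreement yields one estimate per rater pair", {
  set.seed(808)
  m <- matrix(sample(0:3, 20 * 4, TRUE), 20, 4,
              dimnames = list(NULL, c("student", "e1", "e2", "e3")))
  pw <- pairwise_agreement(m, "ordinal", categories = 0:3)
  expect_identical(nrow(pw), 6L)                      # choose(4, 2)
  expect_identical(anyDuplicated(pw[c("rater_a", "rater_b")]), 0L)
  # each pair equals gwet on the two columns
  for (i in seq_len(nrow(pw))) {
    ref <- gwet_agreement(m[, c(pw$rater_a[i], pw$rater_b[i])],
                          "ordinal", categories = 0:3)
    expect_equal(pw$coefficient[i], ref$coefficient, tolerance = 1e-14)
  }
  # identical pair -> exactly 1
  m2 <- cbind(a = m[, 1], b = m[, 1])
  expect_identical(pairwise_agreement(m2, "ordinal", categories = 0:3)$coefficient, 1)
  # a pair with no co-rated subjects is flagged absent, not zero
  m3 <- cbind(a = c(0, NA, 1, NA), b = c(NA, 1, NA, 0), c = c(0, 1, 1, 0))
  pw3 <- pairwise_agreement(m3, "identity", categories = 0:1)
  ab <- pw3[pw3$rater_a == "a" & pw3$rater_b == "b", ]
  expect_true(ab$absent)
  expect_true(is.na(ab$coefficient))
})
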