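test_that("rarefaction returns exact depth, never inflates counts", {
  set.seed(11)
  m <- matrix(rpois(80, 50), 20, 4,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:4)))
  ft <- feature_table(m)
  depth <- min(colSums(m)) - 10
  rar <- rarefy_table(ft, depth, seed = 1)
  expect_true(all(colSums(rar$counts) == depth))
  expect_true(all(rar$counts <= m))
  # a sample already at depth passes through unchanged
  exact <- feature_table(matrix(c(3L, 7L), 2, 1,
                                dimnames = list(c("a", "b"), "s1")))
  expect_identical(rarefy_table(exact, 10, seed = 1)$counts, exact$counts)
  # samples below depth are dropped with a warning
  expect_warning(out <- rarefy_table(ft, depth + 1e6), "below depth")
  expect_identical(ncol(out$counts), 0L)
  expect_error(rarefy_table(ft, 0), "> 0")
})

test_that("rarefaction matches the hypergeometric expectation", {
  # two features (5, 5), depth 5: expected count 2.5, var 5*.5*.5*(5/9)
  ft <- feature_table(matrix(c(5L, 5L), 2, 1,
                             dimnames = list(c("a", "b"), "s1")))
  n_draws <- 1000
  draws <- vapply(seq_len(n_draws),
                  function(s) rarefy_table(ft, 5, seed = s)$counts[1, 1],
                  numeric(1))
  se <- sqrt(5 * 0.5 * 0.5 * (5 / 9) / n_draws)
  expect_lt(abs(mean(draws) - 2.5), 3 * se)
})

test_that("Bray-Curtis follows the formula and its metric properties", {
  # u = (6, 2), v = (2, 2): (|6-2| + 0) / (8 + 4) = 1/3
  ft <- feature_table(matrix(c(6, 2, 2, 2), 2, 2,
                             dimnames = list(c("f1", "f2"), c("u", "v"))))
  dm <- bray_curtis(ft)
  expect_equal(dm$d["u", "v"], 1 / 3, tolerance = 1e-12)
  same <- feature_table(matrix(c(3, 1, 3, 1), 2, 2,
                               dimnames = list(c("f1", "f2"), c("a", "b"))))
  expect_equal(bray_curtis(same)$d["a", "b"], 0)
  disjoint <- feature_table(matrix(c(5, 0, 0, 7), 2, 2,
                                   dimnames = list(c("f1", "f2"), c("a", "b"))))
  expect_equal(bray_curtis(disjoint)$d["a", "b"], 1)
  zero <- feature_table(matrix(c(1, 0), 1, 2,
                               dimnames = list("f1", c("a", "b"))))
  expect_error(bray_curtis(zero), "all-zero")
  # fuzzed tables: symmetry, zero diagonal, unit range
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rpois(8 * 6, 3), 8, 6,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:6)))
    m[1, ] <- m[1, ] + 1   # guard against all-zero samples
    d <- bray_curtis(feature_table(m))$d
    expect_true(isSymmetric(unname(d)))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("NMDS embeds exact configurations at ~zero stress", {
  square <- config_dm(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  ord <- nmds(square, k = 2, n_restarts = 5, seed = 1)
  expect_lt(ord$stress, 1e-4)
  expect_true(all(abs(colMeans(ord$points)) < 1e-9))
  collinear <- config_dm(cbind(c(0, 1, 2), 0))
  ord3 <- nmds(collinear, k = 2, n_restarts = 5, seed = 1)
  expect_lt(ord3$stress, 1e-6)
})

test_that("NMDS stress trace is non-increasing and rotation-invariant", {
  set.seed(7)
  m <- matrix(rpois(30 * 9, 15), 30, 9,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:9)))
  dm <- bray_curtis(feature_table(m))
  ord <- nmds(dm, k = 2, n_restarts = 10, seed = 3)
  expect_true(all(diff(ord$stress_trace) <= 1e-12))
  # stress depends only on the dissimilarities, which are invariant under
  # rotation/translation of a generating configuration
  set.seed(8)
  P <- matrix(rnorm(16), 8, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  P2 <- P %*% R + 5
  s1 <- nmds(config_dm(P), k = 2, n_restarts = 4, seed = 9)$stress
  s2 <- nmds(config_dm(P2), k = 2, n_restarts = 4, seed = 9)$stress
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("NMDS stress agrees with an independent implementation", {
  set.seed(19)
  m <- matrix(rpois(40 * 10, 20), 40, 10,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:10)))
  dm <- bray_curtis(feature_table(m))
  ours <- nmds(dm, k = 2, n_restarts = 20, seed = 4)
  ref <- vegan::metaMDS(as.dist(dm$d), k = 2, trace = 0)
  expect_lt(abs(ours$stress - ref$stress), 0.01)
})

test_that("envfit r-squared equals the least-squares oracle", {
  set.seed(21)
  pts <- matrix(rnorm(10), 5, 2)
  dm <- config_dm(pts)
  ord <- nmds(dm, k = 2, n_restarts = 3, seed = 1)
  y <- setNames(rnorm(5), ord$sample_ids)
  ef <- envfit_vector(ord, y, n_permutations = 99, seed = 1, variable = "y")
  # brute-force two-covariate regression R^2
  fit <- lm(y[ord$sample_ids] ~ ord$points[, 1] + ord$points[, 2])
  expect_lt(abs(ef$r_squared - summary(fit)$r.squared), 1e-10)
  expect_equal(sqrt(sum(ef$direction^2)), 1, tolerance = 1e-9)
  # a variable equal to axis 1 fits perfectly with the smallest possible p
  # (many samples, so no random permutation reproduces the perfect fit)
  set.seed(22)
  big <- nmds(config_dm(matrix(rnorm(60), 30, 2)), k = 2, n_restarts = 3,
              seed = 7)
  ax1 <- setNames(big$points[, 1], big$sample_ids)
  ef1 <- envfit_vector(big, ax1, n_permutations = 999, seed = 2, variable = "ax1")
  expect_equal(ef1$r_squared, 1, tolerance = 1e-9)
  expect_equal(ef1$p_value, 1 / 1000)
})

test_that("envfit agrees with vegan and handles missing/degenerate input", {
  set.seed(33)
  m <- matrix(rpois(25 * 8, 12), 25, 8,
              dimnames = list(paste0("f", 1:25), paste0("s", 1:8)))
  ord <- nmds(bray_curtis(feature_table(m)), k = 2, n_restarts = 5, seed = 2)
  y <- setNames(rnorm(8), ord$sample_ids)
  ef <- envfit_vector(ord, y, n_permutations = 99, seed = 5, variable = "y")
  ref <- vegan::envfit(ord$points, data.frame(y = y[ord$sample_ids]),
                       permutations = 99)
  expect_equal(ef$r_squared, unname(ref$vectors$r), tolerance = 1e-10)
  # missing samples are excluded from this variable's fit only
  y2 <- y; y2[1:2] <- NA
  ef2 <- envfit_vector(ord, y2, n_permutations = 99, seed = 5, variable = "y2")
  expect_identical(ef2$n_used, 6L)
  expect_error(envfit_vector(ord, setNames(rep(1, 8), ord$sample_ids)),
               "constant")
  expect_error(envfit_vector(ord, setNames(c(1, 2, rep(NA, 6)), ord$sample_ids)),
               ">= 3")
})

test_that("species scores are abundance-weighted sample positions", {
  set.seed(44)
  m <- matrix(rpois(12 * 6, 10) + 1, 12, 6,
              dimnames = list(paste0("f", 1:12), paste0("s", 1:6)))
  ft <- feature_table(m)
  ord <- nmds(bray_curtis(ft), k = 2, n_restarts = 4, seed = 3)
  # feature present in exactly one sample lands on that sample
  m2 <- m; m2["f1", ] <- 0; m2["f1", "s3"] <- 5
  ft2 <- feature_table(m2)
  sc <- species_scores(ft2, ord, "f1")
  expect_equal(unname(sc["f1", ]), unname(ord$points["s3", ]), tolerance = 1e-12)
  # uniformly abundant feature sits at the centroid (origin)
  eq <- matrix(4L, 3, 6, dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  sc0 <- species_scores(feature_table(eq), ord, "g1")
  expect_equal(unname(sc0["g1", ]), c(0, 0), tolerance = 1e-9)
  # two-sample toy case against a hand-computed weighted average
  toy <- feature_table(matrix(c(3, 7, 1, 9), 2, 2,
                              dimnames = list(c("x", "y"), c("s1", "s2"))))
  toy_ord <- ord
  toy_ord$sample_ids <- c("s1", "s2")
  toy_ord$points <- matrix(c(-1, 1, 2, -2), 2, 2,
                           dimnames = list(c("s1", "s2"), c("axis1", "axis2")))
  w <- c(3 / 10, 1 / 10); w <- w / sum(w)    # feature x relative abundances
  expected <- w[1] * toy_ord$points["s1", ] + w[2] * toy_ord$points["s2", ]
  sc2 <- species_scores(toy, toy_ord, "x")
  expect_equal(unname(sc2["x", ]), unname(expected), tolerance = 1e-12)
  # all-zero feature is an error
  m3 <- m; m3["f2", ] <- 0
  expect_error(species_scores(feature_table(m3), ord, "f2"), "all-zero")
})
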