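test_that("ETM weights carry the sign convention and per-EC averaging", {
  r1 <- rxn("R1", "1.7.5.1", c("NO3-", "QH2"), c(1, 1),
            c("NO2-", "Q", "H2O"), c(1, 1, 1))
  etm <- build_etm(list(r1), currency_exclusions = "H2O")
  expect_equal(etm$W["NO3-", "1.7.5.1"], 1)    # consumed -> positive
  expect_equal(etm$W["NO2-", "1.7.5.1"], -1)   # produced -> negative
  expect_false("H2O" %in% etm$metabolite_ids)  # currency: no row

  # one EC catalysing two reactions: weights average over the reaction set
  r2a <- rxn("R2a", "9.9.9.9", "M", 1, "P1", 1)
  r2b <- rxn("R2b", "9.9.9.9", "M", 1, "P2", 1)
  r2c <- rxn("R2c", "9.9.9.9", "N", 2, "M", 1)
  both <- build_etm(list(r2a, r2b), currency_exclusions = character(0))
  expect_equal(both$W["M", "9.9.9.9"], 1)      # consumed (v=1) in both -> +1
  mixed <- build_etm(list(r2a, r2c), currency_exclusions = character(0))
  expect_equal(mixed$W["M", "9.9.9.9"], 0)     # (+1 - 1) / 2
  expect_equal(mixed$W["N", "9.9.9.9"], 1)     # (+2 + 0) / 2
  half <- build_etm(list(r2a, rxn("R2d", "9.9.9.9", "X", 1, "Y", 1)),
                    currency_exclusions = character(0))
  expect_equal(half$W["M", "9.9.9.9"], 0.5)    # consumed in one of two

  summed <- build_etm(list(r2a, r2c), currency_exclusions = character(0),
                      weighting = "sum")
  expect_equal(summed$W["N", "9.9.9.9"], 2)
  expect_error(build_etm(list()), "empty")
})

test_that("reversible reactions score as written or are dropped on request", {
  rv <- rxn("Rv", "2.2.2.2", "A", 1, "B", 1, reversible = TRUE)
  fw <- rxn("Rf", "3.3.3.3", "C", 1, "D", 1)
  as_written <- build_etm(list(rv, fw), currency_exclusions = character(0))
  expect_equal(as_written$W["A", "2.2.2.2"], 1)
  dropped <- build_etm(list(rv, fw), currency_exclusions = character(0),
                       reversible = "drop")
  expect_false("2.2.2.2" %in% dropped$ec_ids)
})

test_that("quantile normalization maps columns onto the common distribution", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("e", 1:3), c("s1", "s2")))
  norm <- normalize_ec_abundance(feature_table(m))
  expect_equal(unname(norm$A[, 1]), log2(c(2.5, 3.5, 4.5) + 1), tolerance = 1e-12)
  expect_equal(unname(norm$A[, 2]), log2(c(2.5, 3.5, 4.5) + 1), tolerance = 1e-12)
  # identical columns are unchanged before the log transform
  m2 <- matrix(c(4, 1, 9, 4, 1, 9), 3, 2, dimnames = dimnames(m))
  norm2 <- normalize_ec_abundance(feature_table(m2))
  expect_equal(unname(norm2$A[, 1]), log2(c(4, 1, 9) + 1), tolerance = 1e-12)
  # post-condition: sorted columns identical (tie-free values; with ties the
  # tied entries receive the mean of their rank positions' reference values,
  # which perturbs the per-column multisets)
  set.seed(12)
  m3 <- matrix(runif(50 * 5, 0, 100), 50, 5,
               dimnames = list(paste0("e", 1:50), paste0("s", 1:5)))
  norm3 <- normalize_ec_abundance(feature_table(m3, units = "normalized"))
  sorted <- apply(norm3$A, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
  one <- feature_table(matrix(1L, 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_error(normalize_ec_abundance(one), ">= 2 samples")
})

test_that("PRMT scores are linear deviations with zero-sum rows", {
  r1 <- rxn("R1", "1.1.1.1", "M", 1, "P", 1)
  etm <- build_etm(list(r1), currency_exclusions = character(0))
  # identical samples: zero deviations, zero scores
  A_same <- structure(list(ec_ids = "1.1.1.1", sample_ids = c("s1", "s2"),
                           A = matrix(3, 1, 2, dimnames = list("1.1.1.1", c("s1", "s2")))),
                      class = "normalized_abundance")
  expect_true(all(prmt_scores(A_same, etm)$S == 0))
  # deviations (+1, -1) propagate linearly through W[m, e] = 1
  A_dev <- A_same
  A_dev$A <- matrix(c(4, 2), 1, 2, dimnames = list("1.1.1.1", c("s1", "s2")))
  sc <- prmt_scores(A_dev, etm)
  expect_equal(unname(sc$S["M", ]), c(1, -1))
  expect_equal(unname(sc$S["P", ]), c(-1, 1))
  expect_identical(sc$reference, "mean of samples")
  # zero-sum rows on a larger random system; linearity in the abundances
  set.seed(23)
  rxns <- nitrogen_cycle_reactions()
  etm2 <- build_etm(rxns)
  ecs <- etm2$ec_ids
  A <- matrix(rnorm(length(ecs) * 6, 8, 2), length(ecs), 6,
              dimnames = list(ecs, paste0("s", 1:6)))
  na <- structure(list(ec_ids = ecs, sample_ids = colnames(A), A = A),
                  class = "normalized_abundance")
  sc2 <- prmt_scores(na, etm2)
  expect_true(all(abs(rowSums(sc2$S)) < 1e-9))
  na3 <- na
  na3$A <- A + (A - rowMeans(A)) * 2          # deviations scaled by 3
  sc3 <- prmt_scores(na3, etm2)
  expect_equal(sc3$S, sc2$S * 3, tolerance = 1e-9)
})

test_that("PRMT scoring warns about and drops ECs missing from the ETM", {
  r1 <- rxn("R1", "1.1.1.1", "M", 1, "P", 1)
  etm <- build_etm(list(r1), currency_exclusions = character(0))
  A <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("1.1.1.1", "5.5.5.5"), c("s1", "s2")))
  na <- structure(list(ec_ids = rownames(A), sample_ids = colnames(A), A = A),
                  class = "normalized_abundance")
  expect_warning(sc <- prmt_scores(na, etm), "5.5.5.5")
  expect_identical(sc$metabolite_ids, c("M", "P"))
  na2 <- na
  na2$ec_ids <- rownames(na2$A) <- c("7.7.7.7", "5.5.5.5")
  expect_error(prmt_scores(na2, etm), "no EC shared")
})

test_that("rank-sum permutation p-values match the exact enumeration bound", {
  # complete separation, 7 vs 7: exact two-sided rank-sum tail = 2/C(14,7)
  S <- matrix(c(1:7 + 100, 1:7), 1, 14,
              dimnames = list("m", paste0("s", 1:14)))
  sc <- structure(list(metabolite_ids = "m", sample_ids = colnames(S), S = S,
                       reference = "mean of samples"), class = "prmt_scores")
  cmp <- compare_prmt_groups(sc, paste0("s", 1:7), paste0("s", 8:14),
                             n_permutations = 1000, seed = 1)
  exact_tail <- 2 / choose(14, 7)
  expect_gte(cmp$p_value, 1 / 1001)
  expect_lte(cmp$p_value, exact_tail + 3 * sqrt(exact_tail / 1000) + 2 / 1001)
  # identical values across both groups: p = 1
  S0 <- matrix(5, 1, 14, dimnames = dimnames(S))
  sc0 <- sc; sc0$S <- S0
  cmp0 <- compare_prmt_groups(sc0, paste0("s", 1:7), paste0("s", 8:14),
                              n_permutations = 200, seed = 1)
  expect_equal(cmp0$p_value, 1)
  expect_error(compare_prmt_groups(sc, "s1", "s2"), ">= 2 samples")
})

test_that("paired signed-rank mode detects a consistent shift", {
  set.seed(5)
  base <- rnorm(8)
  S <- rbind(shift = c(base + 2, base), null = rnorm(16))
  colnames(S) <- paste0("s", 1:16)
  sc <- structure(list(metabolite_ids = rownames(S), sample_ids = colnames(S),
                       S = S, reference = "mean of samples"),
                  class = "prmt_scores")
  cmp <- compare_prmt_groups(sc, paste0("s", 1:8), paste0("s", 9:16),
                             n_permutations = 500, seed = 2, paired = TRUE)
  expect_lt(cmp$p_value[cmp$metabolite == "shift"], 0.05)
  expect_gt(cmp$p_value[cmp$metabolite == "null"], 0.05)
  expect_error(compare_prmt_groups(sc, paste0("s", 1:3), paste0("s", 9:16),
                                   paired = TRUE), "equal group sizes")
})

test_that("direction labels follow the sign convention and group order", {
  S <- rbind(up = c(2, 2, -2, -2), down = c(-1, -1, 1, 1), flat = c(1, 1, 1, 1))
  colnames(S) <- paste0("s", 1:4)
  sc <- structure(list(metabolite_ids = rownames(S), sample_ids = colnames(S),
                       S = S, reference = "mean of samples"),
                  class = "prmt_scores")
  ab <- annotate_metabolite_directions(
    compare_prmt_groups(sc, c("s1", "s2"), c("s3", "s4"),
                        n_permutations = 50, seed = 1))
  ba <- annotate_metabolite_directions(
    compare_prmt_groups(sc, c("s3", "s4"), c("s1", "s2"),
                        n_permutations = 50, seed = 1))
  expect_identical(ab$direction[ab$metabolite == "up"], "consumption_up")
  expect_identical(ab$direction[ab$metabolite == "down"], "accumulation_up")
  expect_identical(ab$direction[ab$metabolite == "flat"], "ambiguous")
  # swapping the groups flips every non-ambiguous label
  expect_identical(ba$direction[ba$metabolite == "up"], "accumulation_up")
  expect_identical(ba$direction[ba$metabolite == "down"], "consumption_up")
  expect_identical(ba$direction[ba$metabolite == "flat"], "ambiguous")
})
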