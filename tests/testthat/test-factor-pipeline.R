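test_that("parallel analysis keeps noise at <= 1 factor and structure at >= 4", {
  set.seed(6)
  meas <- battery_measures()$measure
  noise_hits <- structure_hits <- 0L
  for (r in 1:5) {
    noise <- as.data.frame(matrix(stats::rnorm(400 * 32), 400, 32))
    colnames(noise) <- meas
    noise_hits <- noise_hits + (parallel_analysis(noise, n_reps = 30,
                                                  seed = r) <= 1L)
    gen <- generate_measure_table(cohort_spec(n_subjects = 400,
                                              seed = 600 + r))
    tab <- normalize_measures(gen$baseline)$table
    structure_hits <- structure_hits +
      (parallel_analysis(tab, n_reps = 30, seed = r) >= 4L)
  }
  expect_gte(noise_hits, 4L)
  expect_gte(structure_hits, 4L)
  expect_identical(parallel_analysis(normalized_800()$table, n_reps = 25,
                                     seed = 3),
                   parallel_analysis(normalized_800()$table, n_reps = 25,
                                     seed = 3))
  expect_error(parallel_analysis(normalized_800()$table, n_reps = 5), "20")
})

test_that("minres recovers a noiseless single factor almost exactly", {
  set.seed(11)
  lam <- stats::runif(32, 0.4, 0.8)
  n <- 2000
  f <- stats::rnorm(n)
  sigma <- 0.05
  X <- outer(f, lam) + matrix(stats::rnorm(n * 32, sd = sigma), n, 32)
  tab <- as.data.frame(X); colnames(tab) <- battery_measures()$measure
  fa <- fit_ecfa(tab, 1)
  ## on the correlation metric the planted loadings are lam/sqrt(lam^2+s^2)
  lam_std <- lam / sqrt(lam^2 + sigma^2)
  cc <- abs(dacuity:::congruence(fa$loadings[, 1], lam_std))
  expect_gt(cc, 0.999)
  expect_lt(max(fa$uniquenesses), 0.05)
  tabz <- as.data.frame(scale(X))
  colnames(tabz) <- colnames(tab)
  sc <- score_subjects(fa, tabz)
  expect_gt(abs(stats::cor(sc[, 1], f)), 0.999)
})

test_that("two orthogonal planted factors are recovered after matching", {
  set.seed(12)
  n <- 1500
  L <- matrix(0, 32, 2)
  L[1:16, 1] <- stats::runif(16, 0.5, 0.7)
  L[17:32, 2] <- stats::runif(16, 0.5, 0.7)
  F2 <- matrix(stats::rnorm(n * 2), n, 2)
  X <- F2 %*% t(L) + matrix(stats::rnorm(n * 32, sd = 0.6), n, 32)
  tab <- as.data.frame(X); colnames(tab) <- battery_measures()$measure
  fa <- fit_ecfa(tab, 2)
  m <- match_factors(fa$str_loadings, L)
  expect_true(all(m$congruence >= 0.95))
})

test_that("fitting beyond the parallel-analysis bound warns but returns", {
  tab <- normalized_800()$table[1:200, ]
  expect_warning(fa <- fit_ecfa(tab, 6, max_factors = 5), "exceeds")
  expect_s3_class(fa, "dacuity_fa")
  expect_error(fit_ecfa(tab, 0), "at least 1")
})

test_that("scores are invariant to measure column order and linear in the data", {
  norm <- normalized_800()
  fa <- fixture("fa4_800", function() fit_ecfa(normalized_800()$table, 4))
  tab <- norm$table
  perm <- sample(dacuity:::measure_columns(tab))
  tab_perm <- tab[, c(setdiff(colnames(tab), perm), perm)]
  expect_equal(score_subjects(fa, tab_perm), score_subjects(fa, tab))
  ## with loadings fixed, scoring is a linear map on the measures
  tab2 <- tab
  cols <- dacuity:::measure_columns(tab)
  tab2[, cols] <- 2 * tab2[, cols]
  expect_equal(score_subjects(fa, tab2), 2 * score_subjects(fa, tab))
})

test_that("six-task subset scoring tracks the full battery score", {
  fa <- fixture("fa4_800", function() fit_ecfa(normalized_800()$table, 4))
  tab <- normalized_800()$table
  full <- score_subjects(fa, tab)[, 1]
  sub <- score_subjects(fa, tab, task_subset = c("gng", "aat", "twostep",
                                                 "info", "trust", "disc"))[, 1]
  expect_gte(stats::cor(full, sub), 0.9)
  ## follow-up identical to baseline reproduces baseline scores exactly
  expect_equal(score_subjects(fa, tab), predict(fa, tab))
})

test_that("confirmatory selection picks the generating dimensionality", {
  gen <- cohort_800()
  norm <- normalized_800()
  halves <- split_discovery_test(norm$table, seed = 17)
  models <- lapply(1:5, function(k) fit_ecfa(halves$discovery, k))
  sel <- confirm_and_select(models, halves$test)
  expect_equal(sel$chosen_k, 4L)
  idx <- sel$indices
  expect_equal(which.min(idx$BIC[1:4]), 4L)  # k = 4 is the BIC optimum
  ## confirmatory fit of the true generating pattern is excellent
  Xt <- as.matrix(halves$test[, dacuity:::measure_columns(halves$test)])
  fit <- cfa_fit(stats::cor(Xt), nrow(Xt), gen$truth$planted_loadings != 0)
  expect_true(fit$converged)
  expect_gte(fit$CFI, 0.95)
  expect_lt(fit$RMSEA_lower, fit$RMSEA_upper)
})

test_that("a factor with no freed loadings is flagged under-identified", {
  models <- list(fixture("fa4_800", function()
    fit_ecfa(normalized_800()$table, 4)))
  weak <- models[[1]]
  weak$loadings[, 3] <- 0.1        # all below the 0.25 threshold
  weak$str_loadings[, 3] <- 0.1
  sel <- confirm_and_select(list(weak), normalized_800()$table)
  expect_false(sel$indices$identified[1])
  expect_true(is.na(sel$indices$BIC[1]))
  expect_error(cfa_fit(diag(32), 100, abs(weak$loadings) >= 0.25),
               "under-identified")
})

test_that("cross-scoring stability: identical halves give r = 1, permuted give ~0", {
  norm <- normalized_800()
  half <- norm$table[1:400, ]
  st <- stability_cross_scoring(half, half)
  expect_equal(st$r_cross, 1, tolerance = 1e-9)
  ## measure columns randomly permuted in B destroys the construct
  set.seed(3)
  other <- norm$table[401:800, ]
  cols <- dacuity:::measure_columns(other)
  other[, cols] <- other[, sample(cols)]
  st2 <- stability_cross_scoring(half, other)
  expect_lt(abs(st2$r_cross), 0.5)
  expect_true(st2$flagged)
})
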