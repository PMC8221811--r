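test_that("cohort spec validates its fields", {
  expect_error(cohort_spec(n_subjects = 1), "at least 2")
  expect_error(cohort_spec(retention = 0), "retention")
  expect_error(cohort_spec(missing_rate = 0.5), "missing_rate")
  expect_error(cohort_spec(common_loadings = rep(0.2, 10)), "length-32")
  bad <- default_specific_structure()
  bad$disc$members <- c(28:32, 21)  # overlaps info factor
  expect_error(cohort_spec(specific_structure = bad), "disjoint")
})

test_that("same seed gives identical tables; different seeds differ", {
  a <- generate_measure_table(cohort_spec(n_subjects = 60, seed = 7))
  b <- generate_measure_table(cohort_spec(n_subjects = 60, seed = 7))
  c <- generate_measure_table(cohort_spec(n_subjects = 60, seed = 8))
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$followup, b$followup)
  expect_false(identical(a$baseline, c$baseline))
})

test_that("noiseless factor model has rank at most 4", {
  spec <- cohort_spec(n_subjects = 200, uniqueness = rep(0, 32),
                      missing_rate = 0, seed = 3)
  gen <- generate_measure_table(spec)
  X <- as.matrix(gen$baseline[, battery_measures()$measure])
  X[, skewed_measure_idx()] <- log(X[, skewed_measure_idx()])  # undo storage skew
  expect_lte(qr(scale(X), tol = 1e-7)$rank, 4)
})

test_that("cohort structure: waves, retention, ages, missingness", {
  spec <- cohort_spec(n_subjects = 400, seed = 5)
  gen <- generate_measure_table(spec)
  expect_equal(nrow(gen$baseline), 400)
  ret <- nrow(gen$followup) / 400
  expect_gt(ret, 0.6); expect_lt(ret, 0.8)
  expect_true(all(gen$followup$age >
                    gen$baseline$age[match(gen$followup$subject_id,
                                           gen$baseline$subject_id)]))
  X <- as.matrix(gen$baseline[, battery_measures()$measure])
  expect_gt(mean(is.na(X)), 0.01); expect_lt(mean(is.na(X)), 0.04)
  ## ages fill 5 bins
  expect_equal(length(unique(cut(gen$baseline$age, seq(14, 24, 2),
                                 include.lowest = TRUE))), 5)
})

test_that("latent d and IQ correlate as built, and retest stability holds", {
  gen <- cohort_800()
  lat <- gen$truth$latents
  w1 <- lat[lat$wave == 1, ]; w2 <- lat[lat$wave == 2, ]
  expect_equal(stats::sd(w1$latent_d), 1, tolerance = 0.1)
  both <- merge(w1, w2, by = "subject_id")
  r12 <- stats::cor(both$latent_d.x, both$latent_d.y)
  expect_equal(r12, 0.68, tolerance = 0.08)
  expect_gt(stats::cor(w1$latent_d, w1$latent_iq), 0.2)
})

test_that("connectivity matrices are symmetric, zero-diagonal, template-exact when noiseless", {
  gen <- small_conn()$gen
  cs0 <- connectivity_spec(n_nodes = 20, n_modules = 4, subject_noise_sd = 0,
                           effect_d = 0, effect_iq = 0,
                           site_offsets = c(0, 0, 0), fd_slope = 0,
                           volume_slope = 0, seed = 2)
  ds0 <- generate_connectivity(cs0, gen$truth, wave = 1)
  m1 <- subject_matrix(ds0, 1); m2 <- subject_matrix(ds0, 2)
  expect_true(isSymmetric(m1))
  expect_equal(diag(m1), rep(0, 20))
  expect_equal(m1, m2)  # every subject equals the block template
  idx <- edge_index(20)
  within <- ds0$planted_partition[idx$i] == ds0$planted_partition[idx$j]
  expect_equal(unique(ds0$edges[1, within]), cs0$within_block_mean)
  expect_equal(unique(ds0$edges[1, !within]), cs0$between_block_mean)
})

test_that("null edges stay inside the sample-correlation null envelope", {
  gen <- small_conn()$gen
  cs <- connectivity_spec(n_nodes = 30, n_modules = 6, effect_d = 0,
                          effect_iq = 0, seed = 77)
  ds <- generate_connectivity(cs, gen$truth, wave = 1)
  lat <- gen$truth$latents[gen$truth$latents$wave == 1, ]
  d <- lat$latent_d[match(ds$subjects, lat$subject_id)]
  rmax <- max(abs(cor(ds$edges, d)))
  ## Bonferroni-style envelope for the max of 435 null correlations at n=250
  n <- length(d); p_edges <- ncol(ds$edges)
  env <- stats::qnorm(1 - 0.01 / (2 * p_edges)) / sqrt(n - 3)
  expect_lt(rmax, tanh(env) * 1.15)
})

test_that("strong planted edges dominate the correlation ranking", {
  gen <- small_conn()$gen
  set.seed(4)
  sig <- sample.int(435, 50)
  cs <- connectivity_spec(n_nodes = 30, n_modules = 6, signal_edges_d = sig,
                          effect_d = 0.5, seed = 9)
  ds <- generate_connectivity(cs, gen$truth, wave = 1)
  lat <- gen$truth$latents[gen$truth$latents$wave == 1, ]
  d <- lat$latent_d[match(ds$subjects, lat$subject_id)]
  top100 <- order(-abs(cor(ds$edges, d)))[1:100]
  expect_gte(sum(sig %in% top100), 40)  # >= 80% recall
})

test_that("trust exchange generator respects game constraints and policies", {
  expect_error(generate_trust_exchanges(list(type = "coaxing"), n_rounds = 1),
               "at least 2")
  expect_error(generate_trust_exchanges(list(type = "coaxing", endowment = -1)),
               "positive")
  exs <- generate_trust_exchanges(list(type = "random"), n_exchanges = 10,
                                  seed = 3)
  for (ex in exs) {
    expect_true(all(ex$investor >= 0 & ex$investor <= ex$endowment))
    expect_true(all(ex$trustee >= 0 & ex$trustee <= 3 * ex$investor + 1e-9))
  }
  expect_identical(generate_trust_exchanges(list(type = "coaxing"), seed = 5),
                   generate_trust_exchanges(list(type = "coaxing"), seed = 5))
  ## policy orientations
  co <- sapply(generate_trust_exchanges(list(type = "coaxing"),
                                        n_exchanges = 30, seed = 11),
               function(e) exchange_scores(e)$orientation_deg)
  expect_true(mean(abs(co) <= 15) >= 0.9)
  mr <- sapply(generate_trust_exchanges(list(type = "mutual_reduction"),
                                        n_exchanges = 30, seed = 12),
               function(e) exchange_scores(e)$orientation_deg)
  expect_true(mean(abs(mr + 135) <= 15) >= 0.9)
})

test_that("connectivity round-trips through the manifest writer", {
  gen <- small_conn()$gen
  cs <- connectivity_spec(n_nodes = 12, n_modules = 3, seed = 2)
  ds <- generate_connectivity(cs, gen$truth, wave = 1,
                              subjects = gen$truth$latents$subject_id[1:5])
  dir <- withr::local_tempdir()
  write_connectivity(ds, dir)
  back <- read_connectivity(dir)
  expect_equal(back$subjects, ds$subjects)
  expect_equal(back$edges, ds$edges, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "ground_truth.oracle.json")))
})
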