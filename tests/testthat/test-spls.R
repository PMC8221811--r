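test_that("dense limit matches the Krylov-subspace PLS oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:50) {
    X <- scale(matrix(stats::rnorm(30 * 10), 30, 10))
    y <- stats::rnorm(30); y <- y - mean(y)
    K <- sample(1:3, 1)
    worst <- max(worst, max(abs(fit_spls(X, y, 0, K) - krylov_pls(X, y, K))))
  }
  expect_lt(worst, 1e-8)
  ## eta = 0, K = 1 is proportional to X'y
  X <- scale(matrix(stats::rnorm(40 * 8), 40, 8))
  y <- stats::rnorm(40); y <- y - mean(y)
  b <- fit_spls(X, y, 0, 1)
  z <- as.numeric(crossprod(X, y))
  expect_gt(abs(stats::cor(as.numeric(b), z)), 1 - 1e-10)
})

test_that("sparse problems recover the exact active set", {
  set.seed(7)
  for (i in 1:5) {
    X <- scale(matrix(stats::rnorm(100 * 500), 100, 500))
    truth <- sample.int(500, 3)
    y <- X[, truth] %*% c(1, 0.8, -0.6); y <- as.numeric(y - mean(y))
    b <- fit_spls(X, y, 0.8, 3)
    expect_setequal(attr(b, "active"), truth)
  }
  ## eta near 1 keeps only the argmax
  X <- scale(matrix(stats::rnorm(60 * 50), 60, 50))
  y <- X[, 10] + 0.01 * stats::rnorm(60); y <- y - mean(y)
  expect_equal(attr(fit_spls(X, y, 0.99, 1), "active"), 10L)
  expect_error(fit_spls(X, rep(1, 60), 0.5, 1), "zero-variance")
  expect_error(fit_spls(X, y, 0.5, 100), "rank")
})

test_that("deconfounding fits on training rows only", {
  set.seed(15)
  n <- 120
  cov <- random_covariates(n)
  D <- dacuity:::deconfound_design(cov)
  beta <- stats::rnorm(ncol(D), sd = 0.5)
  tr <- 1:80
  ## y exactly linear in the covariates: training residuals are ~0
  y_lin <- as.numeric(D %*% beta)
  dec <- deconfound(y_lin, cov, tr)
  expect_lt(max(abs(dec$residuals[tr])), 1e-10)
  ## covariates orthogonal to y: y unchanged up to centering
  y_ind <- stats::rnorm(n)
  y_orth <- stats::lm.fit(D[tr, ], y_ind[1:80])$residuals
  dec2 <- deconfound(c(y_orth, y_ind[81:n]), cov, tr)
  expect_equal(dec2$residuals[tr], unname(y_orth), tolerance = 1e-10)
  ## perturbing test covariates leaves training residuals unchanged
  cov2 <- cov; cov2$volume[81:n] <- cov2$volume[81:n] + 10
  dec3 <- deconfound(y_lin, cov2, tr)
  expect_equal(dec3$residuals[tr], dec$residuals[tr])
  ## collinearity is reported by column name
  cov3 <- cov; cov3$dof <- 2 * cov3$fd
  expect_error(deconfound(y_lin, cov3, tr), "dof")
})

test_that("the prefilter passes about alpha of null features", {
  set.seed(21)
  hits <- numeric(10)
  for (i in 1:10) {
    X <- matrix(stats::rnorm(100 * 500), 100, 500)
    y <- stats::rnorm(100)
    hits[i] <- mean(dacuity:::prefilter_pvalues(X, y) < 0.05)
  }
  ## binomial 95% envelope around 5% over 5000 total draws
  expect_gt(mean(hits), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 5000))
  expect_lt(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 5000))
})

test_that("bagging averages resampled fits and ranks true features first", {
  set.seed(31)
  n <- 150; p <- 80
  X <- scale(matrix(stats::rnorm(n * p), n, p))
  truth <- 1:10
  y <- as.numeric(X[, truth] %*% rep(0.3, 10) + stats::rnorm(n))
  y <- y - mean(y)
  bf <- bagged_fit(X, y, eta = 0.5, K = 1, n_boot = 50)
  expect_gt(mean(bf$sel_freq[truth]), mean(bf$sel_freq[-truth]))
  ## N_B = 1 with a fixed seed equals the single fit on that resample
  set.seed(99)
  bf1 <- bagged_fit(X, y, eta = 0.5, K = 1, n_boot = 1, keep = seq_len(p))
  set.seed(99)
  idx <- sample.int(n, n, replace = TRUE)
  b_single <- fit_spls(X[idx, ], y[idx] - mean(y[idx]), 0.5, 1)
  expect_equal(bf$intercept, mean(y))
  expect_equal(bf1$beta, as.numeric(b_single))
  ## empty prefilter degrades to the training mean with a warning
  y_null <- stats::rnorm(n)
  expect_warning(bf0 <- bagged_fit(X, y_null, 0.5, 1, n_boot = 5,
                                   keep = integer(0)),
                 "training mean")
  expect_true(bf0$empty)
  expect_equal(bf0$beta, rep(0, p))
})

test_that("nested CV predicts each subject once per repeat", {
  sc <- small_conn()
  cfg <- fast_config()
  res <- nested_cv_predict(sc$ds, sc$d, cfg)
  expect_equal(dim(res$predictions), c(length(sc$d), cfg$repeats))
  expect_false(anyNA(res$predictions))
  expect_false(anyNA(res$observed))
  expect_equal(res$r_mean, mean(res$r_per_repeat))
  ## every subject appears in exactly one fold per repeat
  for (j in seq_len(cfg$repeats))
    expect_equal(sort(unique(res$folds[, j])), 1:cfg$outer_folds)
  expect_output(print(res), "Nested-CV SPLS")
  expect_equal(nrow(predict(res)), length(sc$d))
})

test_that("no information leaks from test folds into training fits", {
  sc <- small_conn()
  cfg <- fast_config(repeats = 1)
  res <- nested_cv_predict(sc$ds, sc$d, cfg)
  fm <- res$fold_models[[1]][[2]]
  ## refit fold 2 by hand with test-fold targets permuted: identical weights
  te <- fm$test
  tr <- setdiff(seq_along(sc$d), te)
  y2 <- sc$d
  y2[te] <- sample(y2[te])
  dec <- deconfound(y2, sc$ds$covariates, tr)
  expect_equal(dec$coef, fm$dec_coef)
})

test_that("planted signal yields high CV correlation; null data do not", {
  sc <- small_conn()
  cfg <- fast_config()
  res <- nested_cv_predict(sc$ds, sc$d, cfg)
  expect_gt(res$r_mean, 0.2)
  set.seed(77)
  y_null <- stats::rnorm(length(sc$d))
  res0 <- nested_cv_predict(sc$ds, y_null, cfg)
  expect_lt(abs(res0$r_mean), 0.2)
})

test_that("permutation p-values separate signal from noise", {
  sc <- small_conn()
  cfg <- fast_config()
  res <- nested_cv_predict(sc$ds, sc$d, cfg)
  pv <- permutation_pvalue(res, sc$ds, cfg)
  expect_lte(pv$p, 0.01)
  ## observed statistic below the null mean gives p > 0.5
  res_flip <- res
  res_flip$r_mean <- -0.2
  pv2 <- permutation_pvalue(res_flip, sc$ds, cfg, observed_stat = -0.2)
  expect_gt(pv2$p, 0.5)
  expect_error(permutation_pvalue(res, sc$ds, fast_config(n_perm = 10)),
               "at least 20")
})

test_that("virtual lesion features count as within plus boundary connections", {
  sc <- small_conn()
  idx <- edge_index(30)
  for (m in c(1, 4)) {
    nodes <- which(sc$mem == m)
    feat <- which(sc$mem[idx$i] == m | sc$mem[idx$j] == m)
    mn <- length(nodes); N <- 30
    expect_length(feat, mn * (mn - 1) / 2 + mn * (N - mn))
  }
  ## partition must cover all nodes
  expect_error(virtual_lesion_scan(sc$ds, sc$d, rep(1, 10), fast_config()),
               "covers")
})

test_that("partial correlation equals the residual-correlation identity", {
  set.seed(51)
  x <- stats::rnorm(200); z <- stats::rnorm(200)
  y <- 0.5 * x + 0.3 * z + stats::rnorm(200)
  pr <- partial_cor(x, y, z)
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  expect_equal(pr, stats::cor(rx, ry), tolerance = 1e-12)
  ## independent control leaves the correlation almost unchanged
  z_ind <- stats::rnorm(200)
  expect_equal(partial_cor(x, y, z_ind), stats::cor(x, y), tolerance = 0.1)
})

test_that("transfer keeps fold separation and reproduces identical data exactly", {
  sc <- small_conn()
  cfg <- fast_config()
  res <- nested_cv_predict(sc$ds, sc$d, cfg)
  tf <- transfer_to_followup(res, sc$ds, sc$d, n_perm = 30)
  expect_equal(tf$predictions,
               res$predictions[match(tf$subjects, res$subjects), ],
               ignore_attr = TRUE)
  expect_equal(tf$r_mean, res$r_mean, tolerance = 1e-9)
  ## subjects new at follow-up are excluded and logged
  ds2 <- sc$ds
  ds2$subjects[1] <- "NEWSUBJ"
  ds2$covariates$subject_id[1] <- "NEWSUBJ"
  expect_message(tf2 <- transfer_to_followup(res, ds2, sc$d, n_perm = 30),
                 "NEWSUBJ")
  expect_false("NEWSUBJ" %in% tf2$subjects)
  expect_error(transfer_to_followup(res, structure(list(
    subjects = "nobody", edges = sc$ds$edges[1, , drop = FALSE],
    n_nodes = 30, covariates = sc$ds$covariates[1, ]),
    class = "connectivity_dataset"), 1), "overlap")
})
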