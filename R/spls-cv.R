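## Nested cross-validated SPLS prediction with permutation inference,
## virtual-lesion module scans, phenotype specificity, and cross-wave
## transfer.

## random assignment into folds of near-equal size. Deliberately not
## stratified by the target: the permutation null reuses the observed fold
## structure, and target-dependent fold assignment would make the observed
## statistic non-exchangeable with its permutation replicates.
cv_folds <- function(n, n_folds) {
  sample(rep_len(sample.int(n_folds), n))
}

resolve_features <- function(dataset, features) {
  if (inherits(dataset, "connectivity_dataset")) {
    X <- dataset$edges
    cov <- dataset$covariates
    subjects <- dataset$subjects
  } else if (is.matrix(dataset)) {
    X <- dataset
    cov <- attr(dataset, "covariates")
    subjects <- rownames(dataset) %||% as.character(seq_len(nrow(dataset)))
    if (is.null(cov)) stop_config("matrix input needs a 'covariates' attribute")
  } else stop_config("dataset must be a connectivity_dataset or a matrix")
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  list(X = X, cov = cov, subjects = subjects,
       features = features %||% seq_len(ncol(X)))
}

#' Nested cross-validated SPLS prediction of a phenotype
#'
#' For every outer fold: the target is residualized for confounds using the
#' training rows only; features are standardized by training statistics; the
#' univariate prefilter is applied once on the training partition; sparsity
#' and component count are selected by inner k-fold cross-validation (minimum
#' MSE, ties to the sparser model); a bagged SPLS model is fitted at the
#' winning hyperparameters and applied to the test fold. The whole procedure
#' repeats `config$repeats` times with fresh fold assignments, so every
#' subject is predicted once per repeat. Performance is the mean over repeats
#' of the per-repeat correlation between residualized observed and predicted
#' scores.
#'
#' @param dataset a `connectivity_dataset` that already passed FD exclusion,
#'   or a plain feature matrix with a `covariates` attribute.
#' @param target complete numeric phenotype aligned to the dataset rows.
#' @param config an [spls_config()].
#' @param features optional column subset (canonical edge indices).
#' @return Object of class `spls_cv`; see [print.spls_cv()].
#' @export
nested_cv_predict <- function(dataset, target, config = spls_config(),
                              features = NULL) {
  stopifnot(inherits(config, "spls_config"))
  rf <- resolve_features(dataset, features)
  X <- rf$X; cov <- rf$cov
  n <- nrow(X)
  if (length(target) != n) stop_config("target length mismatch")
  if (anyNA(target)) stop_config("target must be complete")
  if (inherits(dataset, "connectivity_dataset") &&
      any(cov$fd > config$fd_threshold))
    stop_config("dataset contains subjects above the FD threshold; run exclude_high_motion() first")

  grid <- expand.grid(eta = config$eta_grid, K = config$K_grid)
  search <- nrow(grid) > 1L
  preds <- obs <- folds_m <- matrix(NA_real_, n, config$repeats)
  fold_models <- vector("list", config$repeats)
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  for (rep_i in seq_len(config$repeats)) {
    folds <- cv_folds(n, config$outer_folds)
    if (min(table(folds)) < 3L)
      stop_config("outer fold with fewer than 3 subjects (n = %d, %d folds)",
                  n, config$outer_folds)
    fold_models[[rep_i]] <- vector("list", config$outer_folds)
    for (f in seq_len(config$outer_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      dec <- deconfound(target, cov, tr)
      yr <- dec$residuals
      ctr <- colMeans(X[tr, , drop = FALSE])
      scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      scl[scl == 0] <- 1
      Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      keep <- which(prefilter_pvalues(Xs[tr, , drop = FALSE], yr[tr]) <
                      config$prefilter_alpha)
      if (search && length(keep)) {
        win <- inner_cv_select(Xs[tr, keep, drop = FALSE], yr[tr], grid,
                               config$inner_folds)
      } else win <- grid[nrow(grid), ]   # single combo or empty filter
      bf <- bagged_fit(Xs[tr, , drop = FALSE], yr[tr],
                       eta = win$eta, K = win$K, n_boot = config$n_boot,
                       alpha = config$prefilter_alpha, keep = keep)
      pr <- as.numeric(Xs[te, , drop = FALSE] %*% bf$beta + bf$intercept)
      preds[te, rep_i] <- pr
      obs[te, rep_i] <- yr[te]
      folds_m[te, rep_i] <- f
      fold_models[[rep_i]][[f]] <- list(
        fold = f, test = te, eta = win$eta, K = win$K,
        beta = bf$beta, intercept = bf$intercept, keep = bf$keep,
        sel_freq = bf$sel_freq, x_center = ctr, x_scale = scl,
        dec_coef = dec$coef, y_resid = yr)
    }
  }
  r_rep <- vapply(seq_len(config$repeats), function(j)
    stats::cor(obs[, j], preds[, j]), 0)
  structure(list(
    predictions = preds, observed = obs, folds = folds_m,
    r_per_repeat = r_rep, r_mean = mean(r_rep),
    fold_models = fold_models, config = config,
    subjects = rf$subjects, features = rf$features,
    target = target, n = n, p = ncol(X)
  ), class = "spls_cv")
}

## inner k-fold grid search; winner by minimum MSE, ties toward larger eta
## then smaller K (the sparser model)
inner_cv_select <- function(X, y, grid, n_folds) {
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  folds <- cv_folds(n, n_folds)
  mse <- numeric(nrow(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    if (!any(te) || sum(tr) < 3L) next
    ytr <- y[tr]
    for (g in seq_len(nrow(grid))) {
      K <- min(grid$K[g], sum(tr) - 1L, ncol(X))
      b <- fit_spls(X[tr, , drop = FALSE], ytr - mean(ytr), grid$eta[g], K)
      pr <- X[te, , drop = FALSE] %*% b + mean(ytr)
      mse[g] <- mse[g] + sum((y[te] - pr)^2)
    }
  }
  ord <- order(mse, -grid$eta, grid$K)
  grid[ord[1], ]
}

#' @export
print.spls_cv <- function(x, ...) {
  cat(sprintf("Nested-CV SPLS prediction: n = %d, p = %d features\n", x$n, x$p))
  cat(sprintf("%d outer folds x %d repeat(s); bagging %d; grid %d combo(s)\n",
              x$config$outer_folds, x$config$repeats, x$config$n_boot,
              length(x$config$eta_grid) * length(x$config$K_grid)))
  cat(sprintf("r per repeat: %s\nmean r = %.3f\n",
              paste(sprintf("%.3f", x$r_per_repeat), collapse = ", "),
              x$r_mean))
  if (!is.null(x$p_value)) cat(sprintf("permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
summary.spls_cv <- function(object, ...) {
  sf <- Reduce(`+`, lapply(object$fold_models, function(rep_f)
    Reduce(`+`, lapply(rep_f, `[[`, "sel_freq"))))
  sf <- sf / (length(object$fold_models) * length(object$fold_models[[1]]))
  out <- list(r_mean = object$r_mean, r_per_repeat = object$r_per_repeat,
              p_value = object$p_value, n = object$n, p = object$p,
              top_features = utils::head(order(-sf), 10),
              mean_sel_freq = sf)
  class(out) <- "summary.spls_cv"
  out
}

#' @export
print.summary.spls_cv <- function(x, ...) {
  cat(sprintf("SPLS nested CV (n = %d, p = %d): mean r = %.3f\n",
              x$n, x$p, x$r_mean))
  if (!is.null(x$p_value)) cat(sprintf("permutation p = %.4g\n", x$p_value))
  cat("features with highest mean selection frequency:",
      paste(x$top_features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
fitted.spls_cv <- function(object, ...) rowMeans(object$predictions)

#' @export
residuals.spls_cv <- function(object, ...)
  rowMeans(object$observed) - rowMeans(object$predictions)

#' Cross-validated predicted and observed scores
#' @param object an `spls_cv`.
#' @param ... unused.
#' @return data.frame of per-subject mean predicted and observed
#'   (residualized) scores.
#' @export
predict.spls_cv <- function(object, ...) {
  data.frame(subject_id = object$subjects,
             predicted = rowMeans(object$predictions),
             observed = rowMeans(object$observed))
}

## ------------------------------------------------------------------------
## permutation machinery

## refit the pipeline for one permutation, reusing fold structure, selected
## hyperparameters and stored residualized targets; returns the statistic
## computed by stat_fun(obs_matrix, pred_matrix)
.null_stat_once <- function(result, dataset, config, perm, stat_fun) {
  rf <- resolve_features(dataset, result$features)
  X <- rf$X
  n <- result$n
  preds <- obs <- matrix(NA_real_, n, config$repeats)
  for (rep_i in seq_len(config$repeats)) {
    for (fm in result$fold_models[[rep_i]]) {
      yr <- fm$y_resid[perm]
      te <- fm$test
      tr <- setdiff(seq_len(n), te)
      Xs <- sweep(sweep(X, 2, fm$x_center), 2, fm$x_scale, "/")
      keep <- which(prefilter_pvalues(Xs[tr, , drop = FALSE], yr[tr]) <
                      config$prefilter_alpha)
      bf <- bagged_fit(Xs[tr, , drop = FALSE], yr[tr], eta = fm$eta,
                       K = fm$K, n_boot = config$n_boot,
                       alpha = config$prefilter_alpha, keep = keep)
      preds[te, rep_i] <- Xs[te, , drop = FALSE] %*% bf$beta + bf$intercept
      obs[te, rep_i] <- yr[te]
    }
  }
  stat_fun(obs, preds)
}

## mean over repeats of the per-repeat correlation
.stat_mean_r <- function(obs, preds) {
  mean(vapply(seq_len(ncol(obs)), function(j) {
    if (stats::sd(obs[, j]) == 0 || stats::sd(preds[, j]) == 0) 0
    else stats::cor(obs[, j], preds[, j])
  }, 0))
}

#' Permutation p-value for a cross-validated correlation
#'
#' Permutes the residualized target within the whole sample `config$n_perm`
#' times, refits the pipeline per permutation (fold structure and selected
#' hyperparameters preserved), Fisher-transforms the null correlations,
#' estimates the SD of the zero-centered Gaussian null, and returns the
#' one-tailed p-value of the observed Fisher-z.
#'
#' @param result an `spls_cv` from [nested_cv_predict()].
#' @param dataset the dataset the result was fitted on.
#' @param config the configuration used (defaults to the result's).
#' @param stat_fun statistic on (observed, predicted) matrices; defaults to
#'   the mean per-repeat correlation.
#' @param observed_stat observed value of the statistic; defaults to
#'   `result$r_mean`.
#' @return List with `p`, `null_sd_z`, `null_r`, and the observed statistic;
#'   also stored in the returned `result` by [add_permutation_pvalue()].
#' @export
permutation_pvalue <- function(result, dataset, config = result$config,
                               stat_fun = .stat_mean_r,
                               observed_stat = result$r_mean) {
  if (config$n_perm < 20L)
    stop_config("n_perm must be at least 20 for a stable variance estimate")
  old <- local_seed(config$seed + 777L)
  on.exit(restore_seed(old))
  null_r <- vapply(seq_len(config$n_perm), function(b) {
    perm <- sample.int(result$n)
    .null_stat_once(result, dataset, config, perm, stat_fun)
  }, 0)
  sd_z <- sqrt(mean(fisher_z(null_r)^2))   # zero-mean Gaussian SD
  p <- stats::pnorm(fisher_z(observed_stat) / sd_z, lower.tail = FALSE)
  list(p = max(p, .Machine$double.xmin), null_sd_z = sd_z, null_r = null_r,
       observed = observed_stat)
}

#' Attach a permutation p-value to a prediction result
#' @param result an `spls_cv`.
#' @param dataset the dataset it was fitted on.
#' @param config configuration (defaults to the result's).
#' @return The result with `p_value` and `null` fields set.
#' @export
add_permutation_pvalue <- function(result, dataset, config = result$config) {
  pv <- permutation_pvalue(result, dataset, config)
  result$p_value <- pv$p
  result$null <- pv[c("null_sd_z", "null_r")]
  result
}

## ------------------------------------------------------------------------

#' Virtual-lesion module scan
#'
#' Refits the whole prediction pipeline once per module, restricted to the
#' connections touching that module (edges among its nodes plus edges
#' between its nodes and the rest of the brain), plus the all-connections
#' model, and applies Benjamini-Hochberg FDR correction across all tests.
#' Modules with fewer than 2 nodes are skipped with a warning.
#'
#' @param dataset a `connectivity_dataset` post FD exclusion.
#' @param target complete phenotype vector.
#' @param partition a `consensus_partition` or integer membership vector
#'   covering all nodes.
#' @param config an [spls_config()].
#' @return List with `table` (module, n_nodes, n_features, r_mean, p,
#'   p_fdr) and `results` (the per-module `spls_cv` objects).
#' @export
virtual_lesion_scan <- function(dataset, target, partition,
                                config = spls_config()) {
  mem <- if (inherits(partition, "consensus_partition"))
    partition$membership else as.integer(partition)
  if (length(mem) != dataset$n_nodes)
    stop_config("partition covers %d nodes; dataset has %d", length(mem),
                dataset$n_nodes)
  idx <- edge_index(dataset$n_nodes)
  modules <- sort(unique(mem))
  keep_mod <- vapply(modules, function(m) sum(mem == m) >= 2L, TRUE)
  if (any(!keep_mod))
    warning(sprintf("skipping module(s) with < 2 nodes: %s",
                    paste(modules[!keep_mod], collapse = ", ")))
  modules <- modules[keep_mod]

  runs <- c(list(all = NULL),
            stats::setNames(lapply(modules, function(m)
              which(mem[idx$i] == m | mem[idx$j] == m)),
              paste0("M", modules)))
  results <- lapply(runs, function(feat) {
    res <- nested_cv_predict(dataset, target, config, features = feat)
    add_permutation_pvalue(res, dataset, config)
  })
  tab <- data.frame(
    module = names(runs),
    n_nodes = c(dataset$n_nodes, vapply(modules, function(m) sum(mem == m), 0L)),
    n_features = vapply(results, function(r) as.numeric(r$p), 0),
    r_mean = vapply(results, function(r) r$r_mean, 0),
    p = vapply(results, function(r) r$p_value, 0),
    stringsAsFactors = FALSE)
  tab$p_fdr <- stats::p.adjust(tab$p, method = "BH")
  list(table = tab, results = results)
}

#' Phenotype specificity by partial correlation
#'
#' Partial correlation between observed and predicted scores controlling for
#' another phenotype (e.g. d vs predicted d controlling IQ), computed on top
#' of the deconfounded scale: the control score is first residualized on the
#' same covariate design, so observed, predicted and control all live on the
#' confound-free scale. Significance comes from the same permutation-null
#' machinery (the partial statistic is evaluated on every permutation
#' refit).
#'
#' @param result an `spls_cv` for the primary phenotype.
#' @param other_score the competing phenotype, aligned to the result's
#'   subjects.
#' @param dataset the dataset the result was fitted on.
#' @param config configuration (defaults to the result's).
#' @return List with `partial_r` (mean over repeats) and `p`.
#' @export
specificity_partial <- function(result, other_score, dataset,
                                config = result$config) {
  if (stats::sd(other_score) == 0)
    stop_config("control score is constant")
  rf <- resolve_features(dataset, result$features)
  D <- deconfound_design(rf$cov)
  other_score <- stats::lm.fit(D, other_score)$residuals
  stat <- function(obs, preds) {
    mean(vapply(seq_len(ncol(obs)), function(j)
      partial_cor(obs[, j], preds[, j], other_score), 0))
  }
  observed <- stat(result$observed, result$predictions)
  pv <- permutation_pvalue(result, dataset, config, stat_fun = stat,
                           observed_stat = observed)
  list(partial_r = observed, p = pv$p, null_sd_z = pv$null_sd_z)
}

#' Partial correlation of x and y given controls z
#'
#' Equals the correlation of the OLS residuals of both variables on the
#' controls.
#' @param x,y numeric vectors.
#' @param z numeric vector or matrix of controls.
#' @export
partial_cor <- function(x, y, z) {
  Z <- cbind(1, as.matrix(z))
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0)
  stats::cor(rx, ry)
}

#' Transfer baseline fold-models to follow-up data
#'
#' Each follow-up subject is predicted by the baseline model of the fold in
#' which they were a test subject, so the prediction never involves their own
#' baseline data. Follow-up targets are residualized with the baseline
#' fold-fitted confound coefficients applied to follow-up covariates.
#' Subjects absent at baseline are excluded and logged. Significance comes
#' from permuting the follow-up residualized target (models fixed).
#'
#' @param result baseline `spls_cv` (fold models retained).
#' @param followup_dataset follow-up `connectivity_dataset`.
#' @param followup_target follow-up phenotype aligned to
#'   `followup_dataset$subjects`.
#' @param n_perm permutations for the p-value.
#' @return List with `r_per_repeat`, `r_mean`, `p`, `predictions` (matrix),
#'   `observed`, `subjects`, `excluded`.
#' @export
transfer_to_followup <- function(result, followup_dataset, followup_target,
                                 n_perm = result$config$n_perm) {
  fu_ids <- followup_dataset$subjects
  common <- intersect(fu_ids, result$subjects)
  if (!length(common)) stop_config("no overlapping subjects with baseline")
  excluded <- setdiff(fu_ids, result$subjects)
  if (length(excluded))
    message(sprintf("excluding %d follow-up subject(s) absent at baseline: %s",
                    length(excluded),
                    paste(utils::head(excluded, 5), collapse = ", ")))
  fi <- match(common, fu_ids)             # rows in follow-up data
  bi <- match(common, result$subjects)    # rows in baseline result
  X_fu <- followup_dataset$edges[fi, result$features, drop = FALSE]
  cov_fu <- followup_dataset$covariates[fi, , drop = FALSE]
  y_fu <- followup_target[fi]
  D_fu <- deconfound_design(cov_fu)
  n_rep <- length(result$fold_models)
  preds <- obs <- matrix(NA_real_, length(common), n_rep)
  for (rep_i in seq_len(n_rep)) {
    for (fm in result$fold_models[[rep_i]]) {
      rows <- which(bi %in% fm$test)
      if (!length(rows)) next
      if (!identical(colnames(D_fu), names(fm$dec_coef)))
        stop_config("follow-up covariate design does not match baseline")
      yr <- y_fu[rows] - as.numeric(D_fu[rows, , drop = FALSE] %*% fm$dec_coef)
      Xs <- sweep(sweep(X_fu[rows, , drop = FALSE], 2, fm$x_center),
                  2, fm$x_scale, "/")
      preds[rows, rep_i] <- Xs %*% fm$beta + fm$intercept
      obs[rows, rep_i] <- yr
    }
  }
  ok <- stats::complete.cases(preds, obs)
  r_rep <- vapply(seq_len(n_rep), function(j)
    stats::cor(obs[ok, j], preds[ok, j]), 0)
  r_mean <- mean(r_rep)
  ## permutation of the residualized follow-up target; models are fixed
  old <- local_seed(result$config$seed + 4242L)
  null_r <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(sum(ok))
    mean(vapply(seq_len(n_rep), function(j)
      stats::cor(obs[ok, j][perm], preds[ok, j]), 0))
  }, 0)
  restore_seed(old)
  sd_z <- sqrt(mean(fisher_z(null_r)^2))
  p <- stats::pnorm(fisher_z(r_mean) / sd_z, lower.tail = FALSE)
  list(r_per_repeat = r_rep, r_mean = r_mean, p = p,
       predictions = preds, observed = obs, subjects = common,
       excluded = excluded)
}
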