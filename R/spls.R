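## Sparse partial least squares: core fit, target deconfounding, bagging.

#' Configuration for the SPLS prediction pipeline
#'
#' Defaults follow the full-scale design: 20 outer folds, 10 inner folds,
#' 5 repeats, 200 bootstrap resamples, 100 permutations, univariate
#' prefilter at p < 0.05, FD exclusion at 0.3 mm. Hyperparameter grids:
#' sparsity eta in {0.1, ..., 0.9} and components K in {1, 2, 3}; the inner
#' winner is minimum mean squared prediction error, ties to the sparser
#' model (larger eta, then smaller K).
#'
#' @param eta_grid sparsity thresholds in [0, 1).
#' @param K_grid component counts.
#' @param outer_folds,inner_folds,repeats cross-validation structure.
#' @param n_boot bootstrap resamples per bagged model.
#' @param n_perm permutations for the null distribution.
#' @param prefilter_alpha univariate correlation filter level.
#' @param fd_threshold mean-FD exclusion threshold (mm).
#' @param seed integer seed governing folds, bagging and permutations.
#' @return Object of class `spls_config`.
#' @export
spls_config <- function(eta_grid = seq(0.1, 0.9, by = 0.2),
                        K_grid = 1:3,
                        outer_folds = 20L, inner_folds = 10L, repeats = 5L,
                        n_boot = 200L, n_perm = 100L,
                        prefilter_alpha = 0.05, fd_threshold = 0.3,
                        seed = 1L) {
  if (outer_folds < 2L || inner_folds < 2L) stop_config("folds must be >= 2")
  if (!length(eta_grid) || !length(K_grid)) stop_config("empty grid")
  if (any(eta_grid < 0 | eta_grid >= 1))
    stop_config("eta values must lie in [0, 1)")
  if (prefilter_alpha <= 0 || prefilter_alpha >= 1)
    stop_config("prefilter_alpha must lie in (0, 1)")
  structure(list(eta_grid = eta_grid, K_grid = as.integer(K_grid),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats), n_boot = as.integer(n_boot),
                 n_perm = as.integer(n_perm),
                 prefilter_alpha = prefilter_alpha,
                 fd_threshold = fd_threshold, seed = as.integer(seed)),
            class = "spls_config")
}

## dense univariate-response PLS (NIPALS); returns the coefficient vector
## for ncomp components on centered y and column-standardized X
pls1_coef <- function(X, y, ncomp) {
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); cvec <- numeric(ncomp)
  Xk <- X; yk <- y
  used <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xk, yk)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xk %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- crossprod(Xk, t) / tt
    cc <- sum(yk * t) / tt
    W[, k] <- w; P[, k] <- pl; cvec[k] <- cc
    Xk <- Xk - tcrossprod(t, pl)
    yk <- yk - cc * t
    used <- k
  }
  if (used == 0L) return(numeric(p))
  W <- W[, seq_len(used), drop = FALSE]; P <- P[, seq_len(used), drop = FALSE]
  as.numeric(W %*% solve(crossprod(P, W), cvec[seq_len(used)]))
}

#' Fit a sparse PLS coefficient vector
#'
#' Iteratively builds an active feature set: at each of the K steps the
#' cross-covariance direction z = X'y (y the current residual) is
#' soft-thresholded at `eta * max|z|`, surviving features join the active
#' set, and the coefficients are refitted by dense PLS on the union active
#' set with the current number of components. At eta = 0 this reduces to
#' dense PLS; as eta -> 1 only the argmax feature survives each step.
#'
#' @param X column-standardized feature matrix.
#' @param y centered target.
#' @param eta sparsity threshold in [0, 1).
#' @param K number of latent components (<= min(n - 1, p)).
#' @return Dense coefficient vector (zeros off the active set) with
#'   attribute `"active"` (active set indices).
#' @export
fit_spls <- function(X, y, eta, K) {
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) == 0) stop_config("zero-variance target")
  if (K > min(n - 1L, p))
    stop_config("K = %d exceeds the maximal rank %d", K, min(n - 1L, p))
  if (eta < 0 || eta >= 1) stop_config("eta must lie in [0, 1)")
  active <- integer(0)
  y_res <- y
  beta <- numeric(p)
  for (k in seq_len(K)) {
    z <- as.numeric(crossprod(X, y_res))
    thr <- eta * max(abs(z))
    sel <- which(abs(z) >= thr - 1e-12 & abs(z) > 0)
    active <- union(active, sel)
    if (!length(active)) break
    bA <- pls1_coef(X[, active, drop = FALSE], y - mean(y),
                    min(k, length(active)))
    beta <- numeric(p)
    beta[active] <- bA
    y_res <- y - X[, active, drop = FALSE] %*% bA
  }
  structure(beta, active = sort(active))
}

## design matrix for target deconfounding: age, sex and their interaction,
## brain volume, scanning site (indicator contrasts, reference dropped),
## mean FD and denoising DOF -- whichever columns are present
deconfound_design <- function(covariates) {
  cv <- covariates
  cv$sex <- factor(cv$sex)
  cv$site <- factor(cv$site)
  terms <- c(if (all(c("age", "sex") %in% names(cv))) "age * sex"
             else intersect(c("age", "sex"), names(cv)),
             intersect(c("volume", "site", "fd", "dof"), names(cv)))
  stats::model.matrix(stats::as.formula(paste("~", paste(terms, collapse = " + "))),
                      data = cv)
}

#' Regress confounds out of a target using training rows only
#'
#' Fits an OLS model of the target on the covariate design over the training
#' rows and applies the fitted coefficients to all rows, so test-set
#' covariates never influence the fit.
#'
#' @param y numeric target.
#' @param covariates data.frame with any of `age`, `sex`, `site`, `fd`,
#'   `dof`, `volume`.
#' @param train_index integer or logical index of training rows.
#' @return List with `residuals` (all rows), `coef`, and the `design` matrix.
#' @export
deconfound <- function(y, covariates, train_index) {
  D <- deconfound_design(covariates)
  tr <- seq_len(nrow(D)) %in% (if (is.logical(train_index))
    which(train_index) else train_index)
  if (!any(tr)) stop_config("empty training index")
  qd <- qr(D[tr, , drop = FALSE])
  if (qd$rank < ncol(D)) {
    bad <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop_config("rank-deficient covariate design; collinear column(s): %s",
                paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qd, y[tr])
  list(residuals = as.numeric(y - D %*% beta), coef = beta, design = D)
}

## two-sided p-values of per-feature Pearson correlations with y
prefilter_pvalues <- function(X, y) {
  n <- nrow(X)
  r <- col_cor(X, y)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Bagged sparse PLS fit on one training partition
#'
#' Applies the univariate prefilter once on the full training partition
#' (features with correlation p < `alpha` survive), then fits `n_boot`
#' SPLS models on bootstrap resamples and averages their coefficient
#' vectors. Feature-selection frequencies across resamples are recorded.
#'
#' @param X_train column-standardized training features.
#' @param y_train residualized training target.
#' @param eta,K SPLS hyperparameters.
#' @param n_boot bootstrap resamples.
#' @param alpha prefilter level.
#' @param keep optional precomputed prefilter index (skips the filter).
#' @return List with `beta` (length ncol(X_train)), `intercept`, `keep`,
#'   `sel_freq` (full length), `empty` flag.
#' @export
bagged_fit <- function(X_train, y_train, eta, K, n_boot = 200L,
                       alpha = 0.05, keep = NULL) {
  p <- ncol(X_train); n <- nrow(X_train)
  if (is.null(keep)) keep <- which(prefilter_pvalues(X_train, y_train) < alpha)
  beta <- numeric(p); sel <- numeric(p)
  intercept <- mean(y_train)
  if (!length(keep)) {
    warning("prefilter removed all features; model predicts the training mean")
    return(list(beta = beta, intercept = intercept, keep = integer(0),
                sel_freq = sel, empty = TRUE))
  }
  Xk <- X_train[, keep, drop = FALSE]
  acc <- numeric(length(keep)); freq <- numeric(length(keep))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y_train[idx]
    if (stats::sd(yb) == 0) { idx <- sample.int(n, n, replace = TRUE); yb <- y_train[idx] }
    bb <- fit_spls(Xk[idx, , drop = FALSE], yb - mean(yb), eta,
                   min(K, n - 1L, length(keep)))
    acc <- acc + bb
    freq <- freq + (bb != 0)
  }
  beta[keep] <- acc / n_boot
  sel[keep] <- freq / n_boot
  list(beta = beta, intercept = intercept, keep = keep, sel_freq = sel,
       empty = FALSE)
}
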