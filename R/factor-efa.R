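## Exploratory factor analysis: parallel analysis, minimum-residual (minres)
## extraction, quartimin (oblimin-family) oblique rotation via gradient
## projection, and regression factor scores.

#' Parallel analysis for factor retention
#'
#' Counts eigenvalues of the observed correlation matrix exceeding the
#' `quantile` of eigenvalues of `n_reps` random standard-normal datasets of
#' the same dimensions.
#'
#' @param table measure table (complete, transformed).
#' @param n_reps number of random datasets (>= 20).
#' @param seed integer seed.
#' @param quantile null-eigenvalue quantile (default 0.95).
#' @return Integer: maximum number of factors to retain.
#' @export
parallel_analysis <- function(table, n_reps = 100L, seed = 1L,
                              quantile = 0.95) {
  if (n_reps < 20L)
    stop_config("n_reps must be at least 20 for a stable percentile")
  X <- as.matrix(table[, measure_columns(table)])
  if (anyNA(X)) stop_config("parallel analysis needs a complete table")
  n <- nrow(X); p <- ncol(X)
  ev_obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  old <- local_seed(seed)
  ev_null <- matrix(0, n_reps, p)
  for (r in seq_len(n_reps)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    ev_null[r, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                          only.values = TRUE)$values
  }
  restore_seed(old)
  thresh <- apply(ev_null, 2, stats::quantile, probs = quantile)
  ## leading run of observed eigenvalues above the null quantile
  above <- ev_obs > thresh
  if (!above[1]) return(0L)
  which.min(c(above, FALSE)) - 1L
}

## minres extraction: optimize uniquenesses psi so that the rank-k
## eigen-approximation of R - diag(psi) minimizes squared off-diagonal
## residuals. Returns unrotated loadings.
minres_extract <- function(R, k, max_iter = 500L) {
  p <- ncol(R)
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.01), 0.95)
  load_at <- function(psi) {
    Rs <- R; diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    d <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(d), k)
  }
  obj <- function(psi) {
    L <- load_at(psi)
    res <- R - tcrossprod(L)
    sum(res[lower.tri(res)]^2)
  }
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = 0.005, upper = 1,
                      control = list(maxit = max_iter))
  if (opt$convergence != 0)
    stop_config("minres extraction did not converge (optim code %d, %s)",
                opt$convergence, opt$message %||% "no message")
  L <- load_at(opt$par)
  list(loadings = L, uniquenesses = opt$par, objective = opt$value)
}

## Quartimin rotation by the oblique gradient-projection algorithm.
## Returns the rotated pattern matrix and factor correlation matrix Phi.
rotate_quartimin <- function(A, max_iter = 500L, tol = 1e-6) {
  k <- ncol(A)
  if (k == 1L) return(list(loadings = A, Phi = matrix(1, 1, 1)))
  N <- matrix(1, k, k) - diag(k)
  crit <- function(L) {
    L2 <- L^2
    list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
  }
  Tmat <- diag(k)
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  cv <- crit(L)
  al <- 1
  for (it in seq_len(max_iter)) {
    G <- -t(t(L) %*% cv$Gq %*% Ti)
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:20) {
      Xm <- Tmat - al * Gp
      Tt <- Xm %*% diag(1 / sqrt(colSums(Xm^2)), k)
      Tti <- solve(Tt)
      Lt <- A %*% t(Tti)
      ct <- crit(Lt)
      if (ct$f < cv$f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt; Ti <- Tti; L <- Lt; cv <- ct
  }
  list(loadings = L, Phi = crossprod(Tmat))
}

#' Fit an exploratory minres factor model
#'
#' Minimum-residual extraction on the measure correlation matrix followed by
#' quartimin (oblique) rotation. Factors are ordered by explained variance
#' and signed so that the majority of salient (|loading| >= 0.25) entries
#' are positive. Regression (correlation-preserving) scoring weights are
#' computed from the rotated solution.
#'
#' @param table complete, standardized measure table.
#' @param k number of factors (>= 1).
#' @param max_factors optional parallel-analysis bound; exceeding it records
#'   a warning but the fit is still returned.
#' @return Object of class `dacuity_fa` with loadings (pattern), factor
#'   correlations `Phi`, uniquenesses, scoring weights and metadata.
#' @export
fit_ecfa <- function(table, k, max_factors = NULL) {
  if (k < 1L) stop_config("k must be at least 1")
  cols <- measure_columns(table)
  X <- as.matrix(table[, cols])
  if (anyNA(X)) stop_config("fit_ecfa needs a complete table")
  if (!is.null(max_factors) && k > max_factors)
    warning(sprintf("k = %d exceeds the parallel-analysis bound %d",
                    k, max_factors))
  R <- stats::cor(X)
  ext <- minres_extract(R, k)
  rot <- rotate_quartimin(ext$loadings)
  L <- rot$loadings; Phi <- rot$Phi

  ## Factor 1 is the battery-wide factor: the one with salient loadings
  ## (|lambda| >= 0.25) spread over the most tasks (explained variance breaks
  ## ties); remaining factors ordered by explained variance. Task-specific
  ## factors concentrate their salient loadings in one task, so variance
  ## order alone cannot be relied on to put the cross-task factor first.
  S <- L %*% Phi
  task <- battery_measures()$task[match(cols, battery_measures()$measure)]
  spread <- apply(L, 2, function(l) length(unique(task[abs(l) >= 0.25])))
  ss <- colSums(S^2)
  lead <- order(spread, ss, decreasing = TRUE)[1]
  ord <- c(lead, setdiff(order(ss, decreasing = TRUE), lead))
  L <- L[, ord, drop = FALSE]; Phi <- Phi[ord, ord, drop = FALSE]
  for (j in seq_len(k)) {
    sal <- abs(L[, j]) >= 0.25
    flip <- if (any(sal)) sum(L[sal, j] > 0) < sum(sal) / 2 else sum(L[, j]) < 0
    if (flip) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]; Phi[, j] <- -Phi[, j]
    }
  }
  S <- L %*% Phi             # structure matrix: measure-factor correlations
  W <- solve(R, S)           # regression scoring weights

  structure(list(
    k = k, loadings = structure(L, dimnames = list(cols, paste0("F", 1:k))),
    str_loadings = structure(S, dimnames = list(cols, paste0("F", 1:k))),
    Phi = Phi, uniquenesses = stats::setNames(ext$uniquenesses, cols),
    rotation = if (k > 1) "quartimin" else "none",
    weights = structure(W, dimnames = list(cols, paste0("F", 1:k))),
    R = R, n = nrow(X), measures = cols, objective = ext$objective
  ), class = "dacuity_fa")
}

#' @export
print.dacuity_fa <- function(x, ...) {
  cat(sprintf("Exploratory factor model: %d factor(s), %d measures, n = %d\n",
              x$k, length(x$measures), x$n))
  cat(sprintf("Rotation: %s; minres objective %.4g\n", x$rotation,
              x$objective))
  sal <- colSums(abs(x$loadings) >= 0.25)
  cat("Salient loadings (|lambda| >= 0.25) per factor:",
      paste(sal, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.dacuity_fa <- function(object, ...) object$loadings

#' @export
summary.dacuity_fa <- function(object, ...) {
  S <- object$loadings %*% object$Phi
  out <- list(k = object$k, n = object$n,
              ss_loadings = colSums(S^2),
              uniqueness_high = sum(object$uniquenesses > 0.8),
              loadings = object$loadings, Phi = object$Phi)
  class(out) <- "summary.dacuity_fa"
  out
}

#' @export
print.summary.dacuity_fa <- function(x, ...) {
  cat(sprintf("Factor model with k = %d (n = %d)\n", x$k, x$n))
  cat("SS structure loadings:", paste(round(x$ss_loadings, 2), collapse = ", "), "\n")
  cat(sprintf("%d measures with uniqueness > 0.8\n", x$uniqueness_high))
  invisible(x)
}

#' Score subjects on a fitted factor model
#'
#' Applies the model's regression weights to a standardized measure table.
#' Factor 1 of the battery-wide model is decision acuity. When `task_subset`
#' is given, weights for measures outside those tasks are zeroed and the raw
#' weighted sum is returned without renormalization, so subset scores stay on
#' a conservative, comparable scale.
#'
#' @param model a `dacuity_fa`.
#' @param table standardized measure table on the model's baseline scale.
#' @param task_subset optional character vector of task labels (see
#'   [battery_measures()]).
#' @return Matrix of scores, subjects x factors.
#' @export
score_subjects <- function(model, table, task_subset = NULL) {
  stopifnot(inherits(model, "dacuity_fa"))
  miss <- setdiff(model$measures, colnames(table))
  if (length(miss))
    stop_config("table lacks measure(s): %s", paste(miss, collapse = ", "))
  Z <- as.matrix(table[, model$measures])
  if (anyNA(Z)) stop_config("scoring needs a complete table")
  W <- model$weights
  if (!is.null(task_subset)) {
    keep <- battery_measures()$task[match(model$measures,
                                          battery_measures()$measure)] %in% task_subset
    W <- W * keep
  }
  Z %*% W
}

#' @export
predict.dacuity_fa <- function(object, newdata, task_subset = NULL, ...) {
  score_subjects(object, newdata, task_subset = task_subset)
}

#' Split-half construct stability by cross-scoring
#'
#' Fits an exploratory model in each half, matches group B's factors to
#' group A's by congruence (resolving sign/permutation indeterminacy), and
#' correlates, within group A, the factor-1 scores from A's own loadings
#' with factor-1 scores from B's loadings applied to A.
#'
#' The default `k = 1` scores the first ECFA component directly: the
#' construct under study is the cross-task common dimension, and a
#' single-factor extraction isolates it without the rotational
#' indeterminacy that makes multi-factor weight vectors noisier across
#' resamples.
#'
#' @param table_A,table_B standardized measure tables over the same 32
#'   measures.
#' @param k number of factors fitted in each half.
#' @param flag_threshold |r| below which the construct is flagged unstable.
#' @return List with `r_cross`, `flagged`, and the two fitted models.
#' @export
stability_cross_scoring <- function(table_A, table_B, k = 1L,
                                    flag_threshold = 0.5) {
  fa_A <- fit_ecfa(table_A, k)
  fa_B <- fit_ecfa(table_B, k)
  if (!setequal(fa_A$measures, fa_B$measures))
    stop_config("the two tables must share the same measures")
  m <- match_factors(fa_B$str_loadings, fa_A$str_loadings)
  ## recompute B's weights under the matched orientation
  W_B <- fa_B$weights[, m$perm, drop = FALSE] %*% diag(m$signs, k)
  Z_A <- as.matrix(table_A[, fa_A$measures])
  own <- (Z_A %*% fa_A$weights)[, 1]
  cross <- (Z_A %*% W_B)[, 1]
  if (stats::sd(own) == 0 || stats::sd(cross) == 0)
    stop_config("degenerate (constant) factor scores")
  r <- stats::cor(own, cross)
  list(r_cross = r, flagged = abs(r) < flag_threshold,
       model_A = fa_A, model_B = fa_B)
}
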