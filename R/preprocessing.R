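## Measure-table preprocessing: gaussianizing transforms, low-rank
## imputation, discovery/test split, follow-up standardization, composites.

measure_columns <- function(table) {
  intersect(battery_measures()$measure, colnames(table))
}

## Transform family: identity; shifted log y = log(x - shift), where the
## shift is 0 for strictly positive measures and min - eps (eps = 1e-6 *
## range) otherwise; signed power sign(x) |x|^p, p in {1/3, 1/2, 2}.
## Selection: minimum post-transform |sample skewness|; a measure already
## near-normal (|skewness| < 0.2) keeps the identity. All family members
## are monotone increasing on the observed range.
.transforms <- function(x) {
  rng <- range(x, na.rm = TRUE)
  eps <- 1e-6 * max(diff(rng), 1e-12)
  shift <- if (rng[1] > 0) 0 else rng[1] - eps
  list(
    identity = list(family = "identity", shift = 0, exponent = 1,
                    fn = function(v) v),
    log = list(family = "shifted-log", shift = shift, exponent = 1,
               fn = function(v) log(v - shift)),
    pow13 = list(family = "signed-power", shift = 0, exponent = 1 / 3,
                 fn = function(v) sign(v) * abs(v)^(1 / 3)),
    pow12 = list(family = "signed-power", shift = 0, exponent = 1 / 2,
                 fn = function(v) sign(v) * abs(v)^(1 / 2)),
    pow2 = list(family = "signed-power", shift = 0, exponent = 2,
                fn = function(v) sign(v) * abs(v)^2)
  )
}

apply_transform <- function(x, tr) {
  switch(tr$family,
         "identity" = x,
         "shifted-log" = log(x - tr$shift),
         "signed-power" = sign(x) * abs(x)^tr$exponent,
         stop_config("unknown transform family '%s'", tr$family))
}

#' Gaussianize, impute and standardize a measure table
#'
#' For each of the 32 battery measures, selects the transform (identity,
#' shifted log, or signed power) minimizing post-transform |skewness|,
#' imputes missing entries by iterative low-rank SVD completion (rank chosen
#' by cross-validation on masked cells; observed entries are never altered),
#' and z-scores each measure. The fitted transform, shift/exponent and
#' baseline mean/SD are stored for exact re-application to follow-up data.
#'
#' @param table measure table (data.frame containing the battery columns).
#' @param max_rank largest completion rank tried.
#' @return List with `table` (transformed, complete, z-scored measures;
#'   other columns untouched) and `spec` (a `transform_spec`).
#' @export
normalize_measures <- function(table, max_rank = 6L) {
  cols <- measure_columns(table)
  if (length(cols) == 0L) stop_config("no battery measures found in table")
  X <- as.matrix(table[, cols])
  n_ok <- colSums(!is.na(X))
  if (any(n_ok == 0L))
    stop_config("measure(s) entirely missing: %s",
                paste(cols[n_ok == 0L], collapse = ", "))
  if (any(n_ok < 3L))
    stop_config("fewer than 3 observed values in: %s",
                paste(cols[n_ok < 3L], collapse = ", "))

  specs <- vector("list", length(cols)); names(specs) <- cols
  Xt <- X
  for (k in seq_along(cols)) {
    x <- X[, k]
    cand <- .transforms(x)
    sk <- vapply(cand, function(tr) abs(sample_skewness(tr$fn(x))), 0)
    sk[!is.finite(sk)] <- Inf
    best <- if (sk[["identity"]] < 0.2) cand$identity else cand[[which.min(sk)]]
    specs[[k]] <- best[c("family", "shift", "exponent")]
    Xt[, k] <- best$fn(x)
  }

  Xi <- impute_lowrank(Xt, max_rank = max_rank)
  mu <- colMeans(Xi); sd <- apply(Xi, 2, stats::sd)
  if (any(sd == 0)) stop_config("zero-variance measure after transform")
  for (k in seq_along(cols)) {
    specs[[k]]$mean <- mu[k]; specs[[k]]$sd <- sd[k]
  }
  Z <- sweep(sweep(Xi, 2, mu), 2, sd, "/")
  out <- table
  out[, cols] <- Z
  list(table = out,
       spec = structure(list(measures = specs), class = "transform_spec"))
}

#' Iterative low-rank SVD completion
#'
#' EM-style completion: missing cells start at column means, then are
#' repeatedly replaced by a rank-r reconstruction of the column-centered
#' matrix until convergence. The rank is chosen by cross-validation: an
#' extra 5% of observed cells are masked, and the rank (from 1 to
#' `max_rank`) with lowest reconstruction RMSE wins, ties to the smaller
#' rank. Observed entries are returned unchanged.
#'
#' @param X numeric matrix with `NA`s.
#' @param max_rank largest rank tried.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @param cv_seed seed for the mask draw (local RNG use).
#' @return Completed matrix.
#' @export
impute_lowrank <- function(X, max_rank = 6L, tol = 1e-6, max_iter = 200L,
                           cv_seed = 71L) {
  obs <- !is.na(X)
  if (all(obs)) return(X)
  max_rank <- min(max_rank, dim(X) - 1L)

  complete_at <- function(M, miss, r) {
    mu <- colMeans(M, na.rm = TRUE)
    Y <- M
    Y[miss] <- matrix(mu, nrow(M), ncol(M), byrow = TRUE)[miss]
    prev <- Inf
    for (it in seq_len(max_iter)) {
      cm <- colMeans(Y)
      Yc <- sweep(Y, 2, cm)
      sv <- svd(Yc, nu = r, nv = r)
      R <- sv$u %*% (diag(sv$d[seq_len(r)], r) %*% t(sv$v))
      fill <- sweep(R, 2, cm, "+")[miss]
      delta <- sum((Y[miss] - fill)^2)
      Y[miss] <- fill
      if (is.finite(prev) && abs(prev - delta) <= tol * (prev + 1e-12)) break
      prev <- delta
    }
    Y
  }

  ## rank selection on an extra masked subset of observed cells
  ranks <- seq_len(max_rank)
  if (length(ranks) > 1L) {
    oi <- which(obs)
    old <- local_seed(cv_seed)
    mask <- sample(oi, max(1L, round(0.05 * length(oi))))
    restore_seed(old)
    Xm <- X; Xm[mask] <- NA
    miss_m <- is.na(Xm)
    rmse <- vapply(ranks, function(r) {
      Yr <- complete_at(Xm, miss_m, r)
      sqrt(mean((Yr[mask] - X[mask])^2))
    }, 0)
    r_star <- ranks[which.min(rmse)]  # which.min ties to the smaller rank
  } else r_star <- 1L

  Y <- complete_at(X, !obs, r_star)
  Y[obs] <- X[obs]
  attr(Y, "rank") <- r_star
  Y
}

## save/restore the global RNG state around internal draws
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Random discovery/test split of a measure table
#'
#' @param table measure table (one row per subject).
#' @param seed integer seed.
#' @return List with `discovery` and `test` tables: disjoint, sizes differing
#'   by at most 1, union equal to the input.
#' @export
split_discovery_test <- function(table, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) stop_config("need at least 2 subjects to split")
  old <- local_seed(seed)
  idx <- sample.int(n, ceiling(n / 2))
  restore_seed(old)
  list(discovery = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

#' Standardize follow-up measures on the baseline scale
#'
#' Applies the baseline-fitted transforms to each follow-up measure, then
#' z-scores with the baseline (transformed-scale) mean and SD — never the
#' follow-up sample's own statistics — so wave-2 scores live on the wave-1
#' scale and absolute change is interpretable.
#'
#' @param followup follow-up measure table.
#' @param spec `transform_spec` from [normalize_measures()] on baseline.
#' @return Follow-up table with measures transformed and standardized.
#' @export
zscore_followup <- function(followup, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  cols <- measure_columns(followup)
  unknown <- setdiff(cols, names(spec$measures))
  if (length(unknown))
    stop_config("measure(s) not in baseline transform spec: %s",
                paste(unknown, collapse = ", "))
  out <- followup
  for (m in cols) {
    tr <- spec$measures[[m]]
    out[[m]] <- (apply_transform(followup[[m]], tr) - tr$mean) / tr$sd
  }
  out
}

#' Aggregate task performance and composite IQ
#'
#' Performance: winnings in each of the Go-NoGo, information-gathering,
#' investor-trustee and two-step tasks are t-scored (mean 50, SD 10) within
#' the sample and averaged. IQ composite: mean of the two z-scored subscores.
#'
#' @param winnings_by_task data.frame with columns `win_gonogo`, `win_info`,
#'   `win_trust`, `win_twostep`.
#' @param iq_subscores data.frame with columns `iq_vocab_raw`,
#'   `iq_matrix_raw`.
#' @return List with vectors `performance` and `iq_composite`.
#' @export
derive_composites <- function(winnings_by_task, iq_subscores) {
  need <- c("win_gonogo", "win_info", "win_trust", "win_twostep")
  miss <- setdiff(need, colnames(winnings_by_task))
  if (length(miss))
    stop_config("missing winnings column(s): %s", paste(miss, collapse = ", "))
  need_iq <- c("iq_vocab_raw", "iq_matrix_raw")
  miss_iq <- setdiff(need_iq, colnames(iq_subscores))
  if (length(miss_iq))
    stop_config("missing IQ subscore column(s): %s",
                paste(miss_iq, collapse = ", "))
  tsc <- vapply(need, function(cn) {
    w <- winnings_by_task[[cn]]
    s <- stats::sd(w)
    if (!is.finite(s) || s == 0)
      stop_config("winnings constant across subjects in %s: t-score undefined", cn)
    50 + 10 * (w - mean(w)) / s
  }, numeric(nrow(winnings_by_task)))
  zs <- vapply(need_iq, function(cn) as.numeric(scale(iq_subscores[[cn]])),
               numeric(nrow(iq_subscores)))
  list(performance = rowMeans(tsc), iq_composite = rowMeans(zs))
}

#' Serialize a transform spec to JSON
#' @param spec `transform_spec`.
#' @param path output path.
#' @export
write_transform_spec <- function(spec, path) {
  jsonlite::write_json(spec$measures, path, auto_unbox = TRUE, digits = NA)
}

#' Read a transform spec from JSON
#' @param path JSON path written by [write_transform_spec()].
#' @export
read_transform_spec <- function(path) {
  structure(list(measures = jsonlite::read_json(path, simplifyVector = TRUE)),
            class = "transform_spec")
}
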