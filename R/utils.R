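## Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample skewness
#'
#' Third standardized moment, computed on non-missing values.
#'
#' @param x numeric vector.
#' @return Scalar skewness; `NA` if fewer than 3 values or zero variance.
#' @keywords internal
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(NA_real_)
  mean((x - m)^3) / s^3
}

#' Fisher z-transform of a correlation
#' @param r correlation in (-1, 1).
#' @keywords internal
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

## Lower-triangle vectorization: row-major over i < j in a fixed node order,
## i.e. edges (1,2), (1,3), ..., (1,n), (2,3), ... This ordering is the
## package-wide convention so feature indices are stable across modules.

#' Edge index table for an n-node symmetric matrix
#'
#' @param n_nodes node count.
#' @return data.frame with columns `i`, `j` (i < j), one row per edge, in the
#'   package's canonical row-major order.
#' @export
edge_index <- function(n_nodes) {
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Vectorize the upper triangle of a symmetric matrix
#' @param m symmetric matrix.
#' @return Numeric vector in canonical edge order (see [edge_index()]).
#' @export
vec_edges <- function(m) {
  m[upper.tri(m)][order(row(m)[upper.tri(m)], col(m)[upper.tri(m)])]
}

#' Rebuild a symmetric zero-diagonal matrix from its edge vector
#' @param v edge vector in canonical order.
#' @param n_nodes node count.
#' @export
unvec_edges <- function(v, n_nodes) {
  stopifnot(length(v) == n_nodes * (n_nodes - 1L) / 2L)
  m <- matrix(0, n_nodes, n_nodes)
  idx <- edge_index(n_nodes)
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  m
}

#' Tucker congruence coefficient between two loading vectors
#' @param a,b numeric vectors of equal length.
#' @keywords internal
congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Match columns of a loading matrix to a reference by absolute congruence
#'
#' Resolves the permutation and sign indeterminacy of factor solutions before
#' any comparison: greedily pairs each reference column with the unmatched
#' fitted column of highest |congruence|, then flips signs so matched
#' congruences are positive.
#'
#' @param fitted,reference loading matrices with equal row counts.
#' @return List with `loadings` (reordered, sign-aligned columns of `fitted`),
#'   `perm`, `signs`, and `congruence` per reference column.
#' @export
match_factors <- function(fitted, reference) {
  fitted <- as.matrix(fitted); reference <- as.matrix(reference)
  kf <- ncol(fitted); kr <- ncol(reference)
  cc <- matrix(0, kr, kf)
  for (a in seq_len(kr)) for (b in seq_len(kf))
    cc[a, b] <- congruence(reference[, a], fitted[, b])
  perm <- integer(kr); signs <- numeric(kr)
  avail <- rep(TRUE, kf)
  for (a in order(-apply(abs(cc), 1, max))) {
    b <- which.max(abs(cc[a, ]) * avail)
    perm[a] <- b; signs[a] <- sign(cc[a, b]); avail[b] <- FALSE
  }
  out <- fitted[, perm, drop = FALSE] %*% diag(signs, kr)
  list(loadings = out, perm = perm, signs = signs,
       congruence = abs(cc[cbind(seq_len(kr), perm)]))
}

## column-wise z-scoring with stored statistics
zscore_fit <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  list(mean = mu, sd = sd)
}
zscore_apply <- function(x, st) sweep(sweep(x, 2, st$mean), 2, st$sd, "/")

## fast per-column Pearson correlation of matrix columns with a vector
col_cor <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  num <- crossprod(Xc, yc)
  den <- sqrt(colSums(Xc^2) * sum(yc^2))
  as.numeric(ifelse(den > 0, num / den, 0))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
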