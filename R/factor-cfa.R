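## Confirmatory factor analysis and model selection.
##
## For each exploratory solution fitted on the discovery half, a confirmatory
## model freeing only the salient loadings (|exploratory loading| >= 0.25) is
## fitted by maximum likelihood to the held-out test half, with standardized
## latent variances, free factor correlations and free uniquenesses.

## Phi parametrized through a row-normalized unit-diagonal Cholesky factor,
## keeping it a valid correlation matrix for any unconstrained parameters.
phi_from_par <- function(cpar, k) {
  if (k == 1L) return(matrix(1, 1, 1))
  Lc <- diag(k)
  Lc[lower.tri(Lc)] <- cpar
  Lc <- Lc / sqrt(rowSums(Lc^2))
  tcrossprod(Lc)
}

#' Maximum-likelihood confirmatory factor fit
#'
#' @param S sample correlation matrix of the test sample.
#' @param n test sample size.
#' @param pattern logical p x k matrix of freed loadings.
#' @param start_loadings optional numeric start values (e.g. exploratory
#'   loadings); defaults to 0.3 on freed entries.
#' @param max_iter optimizer iteration cap.
#' @return List with estimates, minimized discrepancy, `chisq`, `df`,
#'   `converged`, and fit indices `BIC`, `CFI`, `RMSEA` with a 90% interval.
#' @export
cfa_fit <- function(S, n, pattern, start_loadings = NULL, max_iter = 1000L) {
  p <- nrow(pattern); k <- ncol(pattern)
  free_per_factor <- colSums(pattern)
  if (any(free_per_factor == 0L))
    stop_config("under-identified model: factor(s) %s have no freed loadings",
                paste(which(free_per_factor == 0L), collapse = ", "))
  nl <- sum(pattern); nc <- k * (k - 1L) / 2L
  q <- nl + p + nc
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]

  unpack <- function(th) {
    Lam <- matrix(0, p, k)
    Lam[pattern] <- th[seq_len(nl)]
    psi <- exp(th[nl + seq_len(p)])
    Phi <- phi_from_par(th[nl + p + seq_len(nc)], k)
    list(Lam = Lam, psi = psi, Phi = Phi)
  }
  sigma_of <- function(par) tcrossprod(par$Lam %*% par$Phi, par$Lam) + diag(par$psi)

  fn <- function(th) {
    par <- unpack(th)
    Sig <- sigma_of(par)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv_S <- chol2inv(ch) %*% S
    logdet + sum(diag(Sinv_S)) - logdetS - p
  }
  gr <- function(th) {
    par <- unpack(th)
    Sig <- sigma_of(par)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(th)))
    Sinv <- chol2inv(ch)
    G <- Sinv %*% (Sig - S) %*% Sinv           # dF/dSigma
    gL <- 2 * (G %*% par$Lam %*% par$Phi)[pattern]
    gpsi <- diag(G) * par$psi
    gphi <- numeric(nc)
    if (nc > 0) {
      A <- crossprod(par$Lam, G %*% par$Lam)   # dF/dPhi contraction
      cp <- th[nl + p + seq_len(nc)]
      h <- 1e-6
      for (j in seq_len(nc)) {
        cp2 <- cp; cp2[j] <- cp2[j] + h
        dPhi <- (phi_from_par(cp2, k) - par$Phi) / h
        gphi[j] <- sum(A * dPhi)
      }
    }
    c(gL, gpsi, gphi)
  }

  th0 <- c(if (is.null(start_loadings)) rep(0.3, nl) else start_loadings[pattern],
           rep(log(0.5), p), rep(0, nc))
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  par <- unpack(opt$par)
  grad_norm <- max(abs(gr(opt$par)))
  ## admissibility: factors collapsing onto each other (|phi| near 1) or
  ## quasi-Heywood pattern loadings mark a degenerate, overfactored solution
  phi_off <- if (k > 1L) max(abs(par$Phi[upper.tri(par$Phi)])) else 0
  admissible <- phi_off < 0.9 && max(abs(par$Lam)) <= 0.95
  converged <- opt$convergence == 0 && opt$value < 1e9 &&
    grad_norm < 1e-2 && admissible

  chisq <- (n - 1) * opt$value
  df <- p * (p + 1) / 2 - q
  chisq_b <- (n - 1) * (-logdetS)
  df_b <- p * (p - 1) / 2
  cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, .Machine$double.eps)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  rmsea_ci <- rmsea_interval(chisq, df, n)
  list(loadings = par$Lam, uniquenesses = par$psi, Phi = par$Phi,
       F_min = opt$value, chisq = chisq, df = df, q = q,
       converged = converged, grad_norm = grad_norm,
       BIC = chisq + q * log(n), CFI = min(max(cfi, 0), 1),
       RMSEA = rmsea, RMSEA_lower = rmsea_ci[1], RMSEA_upper = rmsea_ci[2])
}

## 90% RMSEA interval from the noncentral chi-square distribution
rmsea_interval <- function(chisq, df, n) {
  bound <- function(prob) {
    f <- function(ncp) stats::pchisq(chisq, df, ncp = ncp) - prob
    if (f(0) < 0) return(0)
    hi <- max(chisq * 2, df * 2, 10)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    stats::uniroot(f, c(0, hi))$root
  }
  lam_l <- bound(0.95); lam_u <- bound(0.05)
  sort(sqrt(c(lam_l, lam_u) / (df * (n - 1))))
}

#' Confirmatory testing and factor-count selection
#'
#' For each exploratory model (fitted on the discovery half only), frees the
#' loadings salient in the exploratory solution (|structure loading| >=
#' `threshold`, i.e. measure-factor correlation, the loading scale on which
#' salience is interpretable for an oblique solution) and fits the
#' resulting confirmatory model to the disjoint test half. A factor needs
#' at least 3
#' freed loadings (the standard indicator rule) or the model is
#' under-identified and excluded — in practice this is what removes the
#' junk factors of overspecified models. The chosen factor count is the
#' largest identified, converged k whose BIC improves on the previous
#' identified, converged model.
#'
#' @param models list of `dacuity_fa` objects (increasing k).
#' @param test_table standardized test-half measure table.
#' @param threshold salience threshold for freeing loadings (default 0.25).
#' @param min_indicators freed loadings required per factor (default 3).
#' @return List with `chosen_k` and `indices`, a data.frame of per-k fit
#'   indices (BIC, CFI, RMSEA interval, convergence, identification).
#' @export
confirm_and_select <- function(models, test_table, threshold = 0.25,
                               min_indicators = 3L) {
  cols <- models[[1]]$measures
  X <- as.matrix(test_table[, cols])
  if (anyNA(X)) stop_config("test table must be complete")
  S <- stats::cor(X); n <- nrow(X)

  rows <- lapply(models, function(mod) {
    sal <- mod$str_loadings %||% mod$loadings
    pat <- abs(sal) >= threshold
    base <- data.frame(k = mod$k,
                       identified = all(colSums(pat) >= min_indicators),
                       converged = NA, chisq = NA_real_, df = NA_real_,
                       BIC = NA_real_, CFI = NA_real_, RMSEA = NA_real_,
                       RMSEA_lower = NA_real_, RMSEA_upper = NA_real_)
    if (!base$identified) return(base)
    fit <- tryCatch(cfa_fit(S, n, pat, start_loadings = mod$loadings),
                    error = function(e) NULL)
    if (is.null(fit)) { base$converged <- FALSE; return(base) }
    base$converged <- fit$converged
    base[c("chisq", "df", "BIC", "CFI", "RMSEA", "RMSEA_lower",
           "RMSEA_upper")] <-
      fit[c("chisq", "df", "BIC", "CFI", "RMSEA", "RMSEA_lower",
            "RMSEA_upper")]
    base
  })
  indices <- do.call(rbind, rows)

  ## largest usable k whose BIC beats the previous usable model; the scan
  ## covers the whole range because single-k fluctuations are common
  usable <- indices[indices$identified & indices$converged %in% TRUE, ]
  chosen <- NA_integer_
  for (i in seq_len(nrow(usable))) {
    if (i == 1L || usable$BIC[i] < usable$BIC[i - 1L]) chosen <- usable$k[i]
  }
  list(chosen_k = chosen, indices = indices)
}
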