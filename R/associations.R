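## Linear mixed-effects association stage: decision acuity on age, IQ and
## psychometric covariates, with participant random intercepts and the age
## effect decomposed into between-subject and within-subject components.

#' Fit the longitudinal association model
#'
#' REML linear mixed-effects fit with a participant random intercept.
#' Age is decomposed into the subject's mean age across waves (between,
#' cross-sectional) and the occasion's deviation from that mean (within,
#' longitudinal); a Wald test of equality of the two coefficients is
#' reported. Random age slopes are omitted by default. If the fit is
#' singular, a warning is emitted and an OLS comparison is attached.
#'
#' @param table longitudinal table with columns `subject_id`, `wave`,
#'   the response, `age`, and any covariates.
#' @param response response column name (default `"d"`).
#' @param covariates character vector of additional fixed-effect columns.
#' @param decompose_age decompose age into between/within components
#'   (default TRUE); if FALSE a single `age` term is used.
#' @return Object of class `dacuity_lme`: coefficient table (raw and
#'   standardized), `BIC`, `logLik`, `age_equality` (Wald chi-square, p),
#'   `singular`, and the underlying `lme4` fit.
#' @export
fit_lme <- function(table, response = "d", covariates = character(),
                    decompose_age = TRUE) {
  need <- c("subject_id", "age", response, covariates)
  miss <- setdiff(need, colnames(table))
  if (length(miss))
    stop_config("table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!any(duplicated(table$subject_id)))
    stop_config("no subject has more than one wave; a mixed model is not identified")
  d <- table
  if (decompose_age) {
    mu_age <- stats::ave(d$age, d$subject_id)
    d$age_between <- mu_age - mean(mu_age)
    d$age_within <- d$age - mu_age
    age_terms <- c("age_between", "age_within")
  } else age_terms <- "age"
  rhs <- paste(c(age_terms, covariates), collapse = " + ")
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | subject_id)", response, rhs))
  fit <- lme4::lmer(fml, data = d, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-4)

  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  sd_y <- stats::sd(d[[response]])
  sd_x <- vapply(names(b), function(nm)
    if (nm == "(Intercept)") NA_real_ else stats::sd(d[[nm]]), 0)
  coefs <- data.frame(term = names(b), estimate = unname(b), se = unname(se),
                      z = unname(b / se),
                      std_beta = unname(b * sd_x / sd_y),
                      stringsAsFactors = FALSE)

  age_eq <- NULL
  if (decompose_age) {
    ct <- as.numeric(names(b) == "age_between") -
      as.numeric(names(b) == "age_within")
    w <- sum(ct * b)^2 / as.numeric(t(ct) %*% V %*% ct)
    age_eq <- list(chisq = w, df = 1L,
                   p = stats::pchisq(w, 1, lower.tail = FALSE))
  }

  ols <- NULL
  if (singular) {
    warning("singular random-effect fit; attaching OLS comparison")
    ols <- stats::lm(stats::as.formula(sprintf("%s ~ %s", response, rhs)),
                     data = d)
  }
  structure(list(coefficients = coefs, BIC = stats::BIC(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 age_equality = age_eq, singular = singular,
                 fit = fit, ols = ols), class = "dacuity_lme")
}

#' @export
print.dacuity_lme <- function(x, ...) {
  cat("Linear mixed-effects association model (participant random intercept)\n")
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("BIC = %.1f; logLik = %.1f%s\n", x$BIC, x$logLik,
              if (x$singular) " [singular fit]" else ""))
  if (!is.null(x$age_equality))
    cat(sprintf("within = between age slope: chi2(1) = %.2f, p = %.3g\n",
                x$age_equality$chisq, x$age_equality$p))
  invisible(x)
}

#' @export
coef.dacuity_lme <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
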