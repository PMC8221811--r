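## Synthetic cohort generators: behavioral battery, connectivity, trust game.
## These define the study conditions for every downstream validation; ground
## truth is emitted separately and is oracle-only.

## Latent model per wave:
##   d_w = beta_age * z(age_w) + b_v * v + b_m * m + s * g + sigma_e * e_w
## where v, m are stable age-orthogonal IQ trait latents (correlated rho_vm),
## g a stable acuity trait and e_w occasion noise, so beta_age is exactly the
## standardized slope of latent d on age. The observable raw IQ subscores
## additionally load on age (a_iq), as raw ability scores do. s and sigma_e
## are solved so Var(d) = 1 and the between-wave latent correlation equals
## retest_r.
solve_latent_variances <- function(spec, cor_age_waves = 0.97) {
  b <- spec$iq_betas; beta <- spec$beta_age
  a_iq <- 0.35          # loading of raw IQ subscores on standardized age
  rho_vm <- 0.45        # correlation of the two IQ trait latents
  q <- b[1]^2 + b[2]^2 + 2 * b[1] * b[2] * rho_vm
  base_same <- beta^2 + q
  base_wave <- beta^2 * cor_age_waves + q
  s2 <- spec$retest_r - base_wave
  e2 <- 1 - base_same - s2
  if (s2 < 0 || e2 <= 0)
    stop_config("cohort_spec latent structure infeasible: retest_r=%.2f with beta_age=%.2f and iq_betas (%.2f, %.2f)",
                spec$retest_r, beta, b[1], b[2])
  list(a_iq = a_iq, rho_vm = rho_vm, s = sqrt(s2), sigma_e = sqrt(e2))
}

#' Generate a synthetic decision-battery table with ground truth
#'
#' Draws a baseline cohort (5 equal age bins across `spec$age_range`) and a
#' follow-up wave (~18 months later, +/- 6 months jitter) for a `retention`
#' fraction of subjects. Measures follow a common factor plus three
#' task-specific factors with high uniqueness; a fixed subset of measures is
#' stored exponentiated so the transform-selection step is exercised; missing
#' entries are MCAR at `missing_rate`. Per-task winnings (four tasks) and raw
#' IQ subscores are emitted for composite scoring.
#'
#' @param spec a [cohort_spec()].
#' @return List with `baseline` and `followup` measure tables (data.frames:
#'   id columns, covariates, 32 measures, 4 winnings columns) and `truth`
#'   (per subject x wave latent scores plus planted loadings) of class
#'   `cohort_truth`.
#' @export
generate_measure_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  vv <- solve_latent_variances(spec)
  meas <- battery_measures()

  ## accelerated longitudinal ages: uniform within 5 equal bins
  bins <- seq(spec$age_range[1], spec$age_range[2], length.out = 6L)
  bin_id <- sample(rep_len(1:5, n))
  age1 <- stats::runif(n, bins[bin_id], bins[bin_id + 1L])
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "F", "M")
  sd_age <- sqrt(diff(spec$age_range)^2 / 12)
  mid_age <- mean(spec$age_range)

  ## stable traits
  v <- stats::rnorm(n)
  m <- vv$rho_vm * v + sqrt(1 - vv$rho_vm^2) * stats::rnorm(n)
  g <- stats::rnorm(n)
  f_spec <- matrix(stats::rnorm(n * 3L), n, 3L)  # task-specific traits

  latent_wave <- function(age, idx) {
    z_age <- (age - mid_age) / sd_age
    V <- vv$a_iq * z_age + sqrt(1 - vv$a_iq^2) * v[idx]
    M <- vv$a_iq * z_age + sqrt(1 - vv$a_iq^2) * m[idx]
    d <- spec$beta_age * z_age + spec$iq_betas[1] * v[idx] +
      spec$iq_betas[2] * m[idx] + vv$s * g[idx] +
      vv$sigma_e * stats::rnorm(length(age))
    list(d = d, V = V, M = M)
  }

  measures_wave <- function(lat, idx) {
    X <- outer(lat$d, spec$common_loadings)
    ks <- seq_along(spec$specific_structure)
    for (k in ks) {
      f <- spec$specific_structure[[k]]
      X[, f$members] <- X[, f$members] + outer(f_spec[idx, k], f$loadings)
    }
    X <- X + sweep(matrix(stats::rnorm(length(idx) * 32L), ncol = 32L),
                   2, spec$uniqueness, "*")
    X[, skewed_measure_idx()] <- exp(X[, skewed_measure_idx()])
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(length(X)) < spec$missing_rate, nrow(X))
      X[miss] <- NA_real_
    }
    colnames(X) <- meas$measure
    X
  }

  winnings_wave <- function(d)
    vapply(c("gonogo", "info", "trust", "twostep"), function(t)
      0.6 * d + 0.8 * stats::rnorm(length(d)), numeric(length(d)))

  assemble <- function(ids, wave, age, lat, idx) {
    X <- measures_wave(lat, idx)
    W <- winnings_wave(lat$d)
    colnames(W) <- paste0("win_", colnames(W))
    data.frame(subject_id = ids, wave = wave, age = age,
               sex = sex[idx],
               iq_vocab_raw = round(55 + 10 * (lat$V + 0.3 * stats::rnorm(length(idx)))),
               iq_matrix_raw = round(25 + 5 * (lat$M + 0.3 * stats::rnorm(length(idx)))),
               X, W, check.names = FALSE, stringsAsFactors = FALSE)
  }

  ids <- sprintf("S%04d", seq_len(n))
  lat1 <- latent_wave(age1, seq_len(n))
  baseline <- assemble(ids, 1L, age1, lat1, seq_len(n))

  keep <- which(stats::runif(n) < spec$retention)
  age2 <- age1[keep] + 1.5 + stats::runif(length(keep), -0.5, 0.5)
  lat2 <- latent_wave(age2, keep)
  followup <- assemble(ids[keep], 2L, age2, lat2, keep)

  truth <- structure(list(
    latents = data.frame(
      subject_id = c(ids, ids[keep]), wave = c(rep(1L, n), rep(2L, length(keep))),
      age = c(age1, age2), sex = c(sex, sex[keep]),
      latent_d = c(lat1$d, lat2$d),
      latent_iq = c((lat1$V + lat1$M), (lat2$V + lat2$M)) / sqrt(2 * (1 + vv$a_iq^2 + (1 - vv$a_iq^2) * vv$rho_vm)),
      stringsAsFactors = FALSE),
    planted_loadings = cbind(common = spec$common_loadings,
                             vapply(spec$specific_structure, function(f) {
                               z <- numeric(32); z[f$members] <- f$loadings; z
                             }, numeric(32))),
    spec = spec), class = "cohort_truth")

  list(baseline = baseline, followup = followup, truth = truth)
}

#' Generate synthetic connectivity matrices aligned to a cohort
#'
#' Each subject's symmetric zero-diagonal matrix is the modular block template
#' plus i.i.d. symmetric noise, per-edge linear effects of the standardized
#' latent phenotypes on the planted edge sets, and additive site, motion (FD)
#' and brain-volume confounds on all edges. A covariate table (age, sex, site,
#' FD, denoising DOF, volume) is emitted alongside.
#'
#' @param spec a [connectivity_spec()].
#' @param truth `cohort_truth` from [generate_measure_table()].
#' @param wave which wave's latents to use (1 = baseline, 2 = follow-up).
#' @param subjects optional subject IDs to scan (default: all in the wave).
#' @param covariates optional covariate table from a previous wave; if given,
#'   site and brain volume are carried over (stable per subject) and FD/DOF
#'   redrawn.
#' @return Object of class `connectivity_dataset`: `edges` (subjects x edges
#'   matrix in canonical order), `n_nodes`, `covariates`, `wave`,
#'   `planted_partition`, and the planted signal edge sets.
#' @export
generate_connectivity <- function(spec, truth, wave = 1L, subjects = NULL,
                                  covariates = NULL) {
  stopifnot(inherits(spec, "connectivity_spec"),
            inherits(truth, "cohort_truth"))
  lat <- truth$latents[truth$latents$wave == wave, ]
  if (nrow(lat) == 0L)
    stop_config("no subjects at wave %s in ground truth", wave)
  if (!is.null(subjects)) {
    miss <- setdiff(subjects, lat$subject_id)
    if (length(miss))
      stop_config("subjects absent from wave %s: %s", wave,
                  paste(utils::head(miss, 5), collapse = ", "))
    lat <- lat[match(subjects, lat$subject_id), ]
  }
  set.seed(spec$seed + as.integer(wave))
  n <- nrow(lat); nn <- spec$n_nodes
  n_edge <- nn * (nn - 1L) / 2L

  partition <- planted_partition(spec)
  idx <- edge_index(nn)
  within <- partition[idx$i] == partition[idx$j]
  template <- ifelse(within, spec$within_block_mean, spec$between_block_mean)

  sig_d <- spec$signal_edges_d %||% sample.int(n_edge, spec$n_signal_edges)
  sig_iq <- spec$signal_edges_iq %||% sample.int(n_edge, spec$n_signal_edges)

  if (is.null(covariates)) {
    site <- sample(c("siteA", "siteB", "siteC"), n, replace = TRUE)
    volume <- stats::rnorm(n)
  } else {
    cv <- covariates[match(lat$subject_id, covariates$subject_id), ]
    if (anyNA(cv$site)) stop_config("covariates missing for some subjects")
    site <- cv$site; volume <- cv$volume
  }
  fd <- pmin(stats::rlnorm(n, log(0.12), 0.45), 0.8)
  dof <- round(stats::rnorm(n, 150, 15))

  zd <- as.numeric(scale(lat$latent_d))
  ziq <- as.numeric(scale(lat$latent_iq))
  site_id <- match(site, c("siteA", "siteB", "siteC"))

  E <- matrix(stats::rnorm(n * n_edge, sd = spec$subject_noise_sd), n, n_edge)
  E <- sweep(E, 2, template, "+")
  E[, sig_d] <- E[, sig_d] + spec$effect_d * zd
  E[, sig_iq] <- E[, sig_iq] + spec$effect_iq * ziq
  conf <- spec$site_offsets[site_id] + spec$fd_slope * (fd - mean(fd)) +
    spec$volume_slope * volume
  E <- E + conf

  structure(list(
    subjects = lat$subject_id,
    edges = E, n_nodes = nn, wave = as.integer(wave),
    covariates = data.frame(subject_id = lat$subject_id,
                            age = lat$age, sex = lat$sex, site = site,
                            fd = fd, dof = dof, volume = volume,
                            stringsAsFactors = FALSE),
    planted_partition = partition,
    signal_edges_d = sort(unique(sig_d)),
    signal_edges_iq = sort(unique(sig_iq))
  ), class = "connectivity_dataset")
}

#' Planted node-to-module assignment of a connectivity spec
#' @param spec a [connectivity_spec()].
#' @return Integer vector of module labels, contiguous from 1.
#' @export
planted_partition <- function(spec) {
  sort(rep_len(seq_len(spec$n_modules), spec$n_nodes))
}

#' Rebuild one subject's dense connectivity matrix
#' @param dataset a `connectivity_dataset`.
#' @param subject subject ID or row index.
#' @export
subject_matrix <- function(dataset, subject) {
  i <- if (is.character(subject)) match(subject, dataset$subjects) else subject
  if (is.na(i)) stop_config("unknown subject")
  unvec_edges(dataset$edges[i, ], dataset$n_nodes)
}

#' Generate synthetic investor-trustee exchanges
#'
#' Simulates multi-round exchanges under simple stylized policies:
#' `"coaxing"` (investor escalates while the trustee's returned fraction
#' holds steady, resultant orientation near 0 degrees), `"mutual_reduction"`
#' (both parties reduce together, orientation near -135 degrees), or
#' `"random"` (uniform contributions).
#'
#' @param policy_params list with `type` (one of the above), optional `noise`
#'   (SD of per-round perturbations, units of endowment fraction), optional
#'   `endowment` (default 20) and `multiplier` (default 3).
#' @param n_rounds rounds per exchange (>= 2).
#' @param n_exchanges number of independent exchanges.
#' @param seed integer seed.
#' @return List of `trust_exchange` objects (see [trust_exchange()]).
#' @export
generate_trust_exchanges <- function(policy_params, n_rounds = 10L,
                                     n_exchanges = 1L, seed = 1L) {
  if (n_rounds < 2L) stop_config("n_rounds must be at least 2")
  type <- policy_params$type %||% "random"
  noise <- policy_params$noise %||% 0.02
  endow <- policy_params$endowment %||% 20
  mult <- policy_params$multiplier %||% 3
  if (endow <= 0 || mult <= 0)
    stop_config("endowment and multiplier must be positive")
  set.seed(seed)
  one <- function() {
    if (type == "coaxing") {
      inv_frac <- pmin(0.4 + 0.06 * (seq_len(n_rounds) - 1L) +
                         stats::rnorm(n_rounds, 0, noise), 1)
      ret_frac <- pmin(pmax(0.5 + stats::rnorm(n_rounds, 0, noise), 0), 1)
    } else if (type == "mutual_reduction") {
      step <- 0.07 * (seq_len(n_rounds) - 1L)
      inv_frac <- pmax(0.8 - step + stats::rnorm(n_rounds, 0, noise), 0.05)
      ret_frac <- pmax(0.7 - step + stats::rnorm(n_rounds, 0, noise), 0)
    } else if (type == "random") {
      inv_frac <- stats::runif(n_rounds, 0.05, 1)
      ret_frac <- stats::runif(n_rounds)
    } else stop_config("unknown policy type '%s'", type)
    inv <- pmin(pmax(inv_frac * endow, 0), endow)
    ret <- pmin(pmax(ret_frac, 0), 1) * mult * inv
    trust_exchange(investor = inv, trustee = ret, endowment = endow,
                   multiplier = mult)
  }
  replicate(n_exchanges, one(), simplify = FALSE)
}
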