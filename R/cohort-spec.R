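## Specifications for the synthetic cohort generators.

#' Canonical names and task labels of the 32-measure decision battery
#'
#' The battery spans seven tasks: Go-NoGo (gng, 8 measures), economic risk
#' preferences (econ, 4), approach-avoidance conflict (aat, 3), two-step
#' planning (twostep, 5), information gathering (info, 4), investor-trustee
#' exchange (trust, 3), and interpersonal discounting (disc, 5).
#'
#' @return data.frame with columns `measure` and `task` (32 rows).
#' @export
battery_measures <- function() {
  data.frame(
    measure = c(
      "gng_pav_bias", "gng_rt_threat", "gng_rt_opport", "gng_outcome_sens",
      "gng_go_bias", "gng_noise", "gng_lr_appet", "gng_lr_avers",
      "econ_gamble_pref", "econ_risk_pref", "econ_skew_pref", "econ_ev_sens",
      "aat_threat_sens", "aat_loss_sens", "aat_performance",
      "ts_model_based", "ts_learning_rate", "ts_perseveration",
      "ts_reward_sens", "ts_eligibility",
      "info_sampling_noise", "info_subj_cost", "info_costed_noise",
      "info_costed_cost",
      "trust_initial", "trust_cooperativeness", "trust_responsiveness",
      "disc_discount_rate", "disc_other_relevance", "disc_taste_uncert",
      "disc_other_noise", "disc_noise"),
    task = rep(c("gng", "econ", "aat", "twostep", "info", "trust", "disc"),
               c(8L, 4L, 3L, 5L, 4L, 3L, 5L)),
    stringsAsFactors = FALSE
  )
}

#' Default signed sparse pattern of common-factor loadings
#'
#' Negative on decision-noise/discounting measures, positive on outcome
#' sensitivity, learning rates and trust; most measures load weakly (high
#' uniqueness).
#' @return Numeric vector of length 32 in [battery_measures()] order.
#' @export
default_common_loadings <- function() {
  c(-0.35, -0.28, -0.28, 0.52, 0.10, -0.50, 0.40, 0.32,   # gng
     0.10, -0.15, 0.05, 0.45,                             # econ
     0.05, 0.05, 0.24,                                    # aat
     0.32, 0.28, -0.10, 0.45, 0.10,                       # twostep
    -0.55, -0.12, -0.18, -0.12,                           # info
     0.32, 0.15, 0.10,                                    # trust
    -0.45, 0.05, -0.22, -0.32, -0.40)                     # disc
}

#' Default task-specific factor structure
#'
#' Three task-specific factors: discounting, information gathering and
#' economic risk. Member indices follow [battery_measures()] ordering.
#' @return List of three factors with `members` and `loadings`.
#' @export
default_specific_structure <- function() {
  list(
    disc = list(members = 28:32, loadings = rep(0.50, 5)),
    info = list(members = 21:24, loadings = rep(0.50, 4)),
    econ = list(members = 9:12,  loadings = rep(0.50, 4))
  )
}

#' Indices of measures stored on an exponentiated (right-skewed) scale
#'
#' These measures exercise the transform-selection step. Fixed subset.
#' @return Integer vector of measure indices.
#' @export
skewed_measure_idx <- function() c(2L, 6L, 9L, 21L, 28L, 31L)

#' Specification of a synthetic behavioral cohort
#'
#' Defines the generative model for a longitudinal cohort performing the
#' 32-measure decision battery: one cross-task common factor (decision
#' acuity), three task-specific factors, high per-measure uniqueness, an
#' accelerated longitudinal age structure (5 equal age bins spanning
#' `age_range`, ~18-month follow-up for a `retention` fraction), and latent
#' associations with age and two IQ subscores.
#'
#' @param n_subjects number of baseline subjects.
#' @param age_range numeric length 2; ages drawn uniformly within 5 equal bins.
#' @param sex_ratio proportion of female subjects.
#' @param common_loadings signed length-32 vector of common-factor loadings.
#' @param specific_structure list of 3 task-specific factors, each with
#'   `members` (measure indices) and `loadings`.
#' @param uniqueness per-measure residual SD; default completes each measure's
#'   variance to 1 given its loadings.
#' @param beta_age standardized slope of latent decision acuity on age.
#' @param iq_betas standardized slopes of latent decision acuity on the
#'   vocabulary and matrix IQ latents, in that order.
#' @param retention follow-up probability in (0, 1].
#' @param retest_r target latent-level stability of decision acuity between
#'   waves.
#' @param missing_rate MCAR missingness fraction in [0, 0.2].
#' @param seed integer seed; one RNG stream per generator call.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 800L,
                        age_range = c(14, 24),
                        sex_ratio = 0.5,
                        common_loadings = default_common_loadings(),
                        specific_structure = default_specific_structure(),
                        uniqueness = NULL,
                        beta_age = 0.24,
                        iq_betas = c(vocab = 0.30, matrix = 0.17),
                        retention = 0.70,
                        retest_r = 0.68,
                        missing_rate = 0.02,
                        seed = 1L) {
  if (n_subjects < 2L) stop_config("n_subjects must be at least 2")
  if (length(common_loadings) != 32L || any(!is.finite(common_loadings)))
    stop_config("common_loadings must be a finite length-32 vector")
  if (retention <= 0 || retention > 1)
    stop_config("retention must lie in (0, 1]")
  if (missing_rate < 0 || missing_rate > 0.2)
    stop_config("missing_rate must lie in [0, 0.2]")
  if (length(age_range) != 2L || diff(age_range) <= 0)
    stop_config("age_range must be increasing length 2")
  members <- unlist(lapply(specific_structure, `[[`, "members"))
  if (any(members < 1L | members > 32L) || anyDuplicated(members))
    stop_config("specific_structure members must be disjoint indices in 1..32")

  lam_s <- numeric(32)
  for (f in specific_structure) lam_s[f$members] <- f$loadings
  if (is.null(uniqueness)) {
    comm <- common_loadings^2 + lam_s^2
    if (any(comm >= 1))
      stop_config("loadings imply communality >= 1; supply uniqueness")
    uniqueness <- sqrt(1 - comm)
  }
  if (length(uniqueness) != 32L || any(uniqueness < 0))
    stop_config("uniqueness must be a nonnegative length-32 vector")

  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    sex_ratio = sex_ratio, common_loadings = common_loadings,
    specific_structure = specific_structure, specific_loadings = lam_s,
    uniqueness = uniqueness, beta_age = beta_age, iq_betas = iq_betas,
    retention = retention, retest_r = retest_r,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Specification of synthetic connectivity data
#'
#' Defines per-subject symmetric connectivity matrices as a modular block
#' template plus subject noise, a sparse linear edge signal for each of two
#' phenotypes, and additive site/motion/volume confounds on all edges.
#'
#' @param n_nodes node count.
#' @param n_modules planted module count (nodes split as evenly as possible).
#' @param within_block_mean,between_block_mean template edge weights inside
#'   and between planted modules (partial-correlation scale).
#' @param subject_noise_sd SD of i.i.d. symmetric subject noise per edge.
#' @param signal_edges_d,signal_edges_iq canonical edge indices (see
#'   [edge_index()]) carrying the phenotype signals; `NULL` draws
#'   `n_signal_edges` at random. Overlap allowed.
#' @param n_signal_edges number of signal edges drawn when a set is `NULL`.
#' @param effect_d,effect_iq per-edge slope on the standardized phenotype.
#' @param site_offsets additive offsets for the 3 scanning sites.
#' @param fd_slope,volume_slope additive slope of every edge on centered mean
#'   framewise displacement (mm) and standardized brain volume.
#' @param seed integer seed.
#' @return Object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(n_nodes = 168L,
                              n_modules = 14L,
                              within_block_mean = 0.25,
                              between_block_mean = 0.02,
                              subject_noise_sd = 0.10,
                              signal_edges_d = NULL,
                              signal_edges_iq = NULL,
                              n_signal_edges = 12L,
                              effect_d = 0.019,
                              effect_iq = 0.019,
                              site_offsets = c(0, 0.01, -0.01),
                              fd_slope = 0.05,
                              volume_slope = 0.02,
                              seed = 1L) {
  n_nodes <- as.integer(n_nodes); n_modules <- as.integer(n_modules)
  if (n_modules > n_nodes) stop_config("n_modules must not exceed n_nodes")
  n_edge <- n_nodes * (n_nodes - 1L) / 2L
  for (s in list(signal_edges_d, signal_edges_iq))
    if (!is.null(s) && (any(s < 1L) || any(s > n_edge)))
      stop_config("signal edge indices must lie in 1..%d", n_edge)
  if (length(site_offsets) != 3L)
    stop_config("site_offsets must have length 3")
  structure(list(
    n_nodes = n_nodes, n_modules = n_modules,
    within_block_mean = within_block_mean,
    between_block_mean = between_block_mean,
    subject_noise_sd = subject_noise_sd,
    signal_edges_d = signal_edges_d, signal_edges_iq = signal_edges_iq,
    n_signal_edges = as.integer(n_signal_edges),
    effect_d = effect_d, effect_iq = effect_iq,
    site_offsets = site_offsets, fd_slope = fd_slope,
    volume_slope = volume_slope, seed = as.integer(seed)
  ), class = "connectivity_spec")
}
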