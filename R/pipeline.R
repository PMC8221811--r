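## End-to-end orchestration: synthetic generation -> preprocessing -> trust
## metrics -> factor pipeline -> network modules -> SPLS prediction ->
## longitudinal associations, with a versioned report directory.

#' Write a measure table as TSV
#' @param table data.frame.
#' @param path output path.
#' @export
write_measure_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a measure table written by [write_measure_table()]
#' @param path TSV path.
#' @export
read_measure_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a connectivity dataset as per-subject dense matrix files
#'
#' One whitespace-delimited dense matrix file per subject plus a manifest
#' TSV (subject, file, covariates). Ground truth (planted partition and
#' signal edges) goes to a clearly marked oracle-only sidecar.
#'
#' @param dataset a `connectivity_dataset`.
#' @param dir output directory (created).
#' @param truth_sidecar write the oracle-only sidecar (default TRUE).
#' @export
write_connectivity <- function(dataset, dir, truth_sidecar = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_wave%d.mat.txt", dataset$subjects, dataset$wave)
  for (i in seq_along(dataset$subjects)) {
    m <- subject_matrix(dataset, i)
    utils::write.table(format(m, digits = 8), file.path(dir, files[i]),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- cbind(dataset$covariates, file = files,
                    n_nodes = dataset$n_nodes, wave = dataset$wave)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (truth_sidecar)
    jsonlite::write_json(
      list(note = "oracle-only ground truth; not an input to any analysis",
           planted_partition = dataset$planted_partition,
           signal_edges_d = dataset$signal_edges_d,
           signal_edges_iq = dataset$signal_edges_iq),
      file.path(dir, "ground_truth.oracle.json"), auto_unbox = TRUE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a connectivity dataset from a manifest directory
#' @param dir directory written by [write_connectivity()].
#' @export
read_connectivity <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  nn <- manifest$n_nodes[1]
  edges <- t(vapply(manifest$file, function(f) {
    m <- as.matrix(utils::read.table(file.path(dir, f)))
    vec_edges(m)
  }, numeric(nn * (nn - 1L) / 2L)))
  rownames(edges) <- manifest$subject_id
  structure(list(subjects = manifest$subject_id, edges = edges,
                 n_nodes = nn, wave = manifest$wave[1],
                 covariates = manifest[, setdiff(colnames(manifest),
                                                 c("file", "n_nodes", "wave"))],
                 planted_partition = NULL, signal_edges_d = NULL,
                 signal_edges_iq = NULL),
            class = "connectivity_dataset")
}

validate_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop_config("config must be a list or a JSON path")
  if (is.null(config$out_dir)) stop_config("config field missing: out_dir")
  stages <- config$stages %||% list()
  defaults <- list(factors = TRUE, trust = TRUE, modules = TRUE,
                   predict = TRUE, associate = TRUE)
  stages <- utils::modifyList(defaults, as.list(stages))
  if (isTRUE(stages$predict) && is.null(config$connectivity))
    stop_config("config field missing: connectivity (required when stages$predict is enabled)")
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes generation, preprocessing, trust metrics, the factor pipeline,
#' module detection, SPLS prediction and the LME association stage according
#' to the configuration, writing tables, a JSON run record and a log to the
#' output directory. Any stage failure preserves the outputs produced so far
#' and leaves a failure marker file.
#'
#' @param config list (or path to a JSON file) with fields `out_dir`,
#'   `seed`, `cohort` (arguments to [cohort_spec()]), `connectivity`
#'   (arguments to [connectivity_spec()]), optional `spls` (arguments to
#'   [spls_config()]), `gamma` (resolution, or a grid to tune over),
#'   `n_factors` (maximum factor count tried) and `stages` (logical
#'   toggles: factors, trust, modules, predict, associate).
#' @return Invisible list of stage outputs.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  record <- list(seed = config$seed, started = format(Sys.time()),
                 stages = config$stages)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  results <- list()
  stage <- function(name, expr) {
    say("stage %s: start", name)
    val <- tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(out, paste0("FAILED_", name)))
      say("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    say("stage %s: done", name)
    val
  }

  ## generation + preprocessing
  results$cohort <- stage("generate", {
    spec <- do.call(cohort_spec, utils::modifyList(
      as.list(config$cohort %||% list()), list(seed = config$seed)))
    gen <- generate_measure_table(spec)
    write_measure_table(gen$baseline, file.path(out, "baseline.tsv"))
    write_measure_table(gen$followup, file.path(out, "followup.tsv"))
    jsonlite::write_json(gen$truth$latents,
                         file.path(out, "latents.oracle.json"))
    gen
  })
  results$prep <- stage("preprocess", {
    norm <- normalize_measures(results$cohort$baseline)
    fu <- zscore_followup(results$cohort$followup, norm$spec)
    write_transform_spec(norm$spec, file.path(out, "transforms.json"))
    list(baseline = norm$table, followup = fu, spec = norm$spec)
  })

  if (isTRUE(config$stages$trust)) results$trust <- stage("trust", {
    ex <- c(generate_trust_exchanges(list(type = "coaxing"), n_exchanges = 20L,
                                     seed = config$seed),
            generate_trust_exchanges(list(type = "mutual_reduction"),
                                     n_exchanges = 20L, seed = config$seed + 1L))
    tab <- trust_score_table(ex)
    write_measure_table(tab, file.path(out, "trust_scores.tsv"))
    tab
  })

  if (isTRUE(config$stages$factors)) results$factors <- stage("factors", {
    halves <- split_discovery_test(results$prep$baseline, seed = config$seed)
    kmax <- config$n_factors %||% 5L
    pa <- parallel_analysis(halves$discovery, n_reps = 50L,
                            seed = config$seed)
    models <- lapply(seq_len(kmax), function(k)
      fit_ecfa(halves$discovery, k))
    sel <- confirm_and_select(models, halves$test)
    chosen <- if (is.na(sel$chosen_k)) kmax else sel$chosen_k
    full <- fit_ecfa(results$prep$baseline, chosen)
    scores <- score_subjects(full, results$prep$baseline)
    stab <- stability_cross_scoring(halves$discovery, halves$test, k = chosen)
    d_tab <- data.frame(subject_id = results$cohort$baseline$subject_id,
                        wave = 1L, d = scores[, 1])
    fu <- results$prep$followup
    fu_ok <- stats::complete.cases(fu[, full$measures])
    fu_scores <- score_subjects(full, fu[fu_ok, , drop = FALSE])
    d_tab <- rbind(d_tab,
                   data.frame(subject_id = fu$subject_id[fu_ok],
                              wave = 2L, d = fu_scores[, 1]))
    write_measure_table(d_tab, file.path(out, "decision_acuity.tsv"))
    utils::write.table(cbind(measure = full$measures, full$loadings),
                       file.path(out, "loadings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(parallel_k = pa, selection = sel, chosen_k = chosen, model = full,
         scores = d_tab, stability = stab$r_cross)
  })

  if (isTRUE(config$stages$modules) || isTRUE(config$stages$predict)) {
    results$connectivity <- stage("connectivity", {
      cspec <- do.call(connectivity_spec, utils::modifyList(
        as.list(config$connectivity %||% list()), list(seed = config$seed + 7L)))
      ds <- generate_connectivity(cspec, results$cohort$truth, wave = 1L)
      exclude_high_motion(ds, (config$spls %||% list())$fd_threshold %||% 0.3)
    })
  }

  if (isTRUE(config$stages$modules)) results$modules <- stage("modules", {
    W <- group_mean_fc(results$connectivity)
    gamma <- config$gamma %||% 1
    part <- if (length(gamma) > 1L) {
      tg <- tune_gamma(W, gamma, n_runs = config$consensus_runs %||% 25L,
                       seed = config$seed)
      say("tuned gamma = %g (%d modules)", tg$gamma_star,
          max(tg$partition$membership))
      tg$partition
    } else consensus_partition(W, gamma,
                               n_runs = config$consensus_runs %||% 25L,
                               seed = config$seed)
    utils::write.table(data.frame(node = seq_along(part$membership),
                                  module = part$membership),
                       file.path(out, "partition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    part
  })

  if (isTRUE(config$stages$predict)) results$predict <- stage("predict", {
    ds <- results$connectivity
    lat <- results$cohort$truth$latents
    d_obs <- if (!is.null(results$factors)) {
      sc <- results$factors$scores
      sc$d[match(ds$subjects, sc$subject_id[sc$wave == 1L])]
    } else lat$latent_d[match(ds$subjects, lat$subject_id[lat$wave == 1L])]
    cfg <- do.call(spls_config, utils::modifyList(
      as.list(config$spls %||% list()), list(seed = config$seed + 11L)))
    res <- nested_cv_predict(ds, d_obs, cfg)
    res <- add_permutation_pvalue(res, ds, cfg)
    write_measure_table(predict(res), file.path(out, "predictions.tsv"))
    res
  })

  if (isTRUE(config$stages$associate)) results$associate <- stage("associate", {
    lat <- results$cohort$truth$latents
    tab <- if (!is.null(results$factors)) {
      merge(results$factors$scores,
            rbind(results$cohort$baseline[, c("subject_id", "wave", "age")],
                  results$cohort$followup[, c("subject_id", "wave", "age")]),
            by = c("subject_id", "wave"))
    } else data.frame(subject_id = lat$subject_id, wave = lat$wave,
                      d = lat$latent_d, age = lat$age)
    fit <- fit_lme(tab, response = "d")
    utils::write.table(fit$coefficients, file.path(out, "lme_coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit
  })

  record$finished <- format(Sys.time())
  record$outputs <- list.files(out)
  jsonlite::write_json(record, file.path(out, "run_record.json"),
                       auto_unbox = TRUE)
  say("pipeline complete")
  invisible(results)
}
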