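#' Full-pipeline run configuration
#'
#' Validates every knob of the end-to-end analysis before any stage runs.
#' Input is either a shipped generator preset or a pair of delimited-text
#' files with a schema (see [load_cohort()]).
#'
#' @param preset name of a generator preset (see [preset_scenario()]), or
#'   `NULL` when loading from files.
#' @param baseline_path,visits_path,schema file-input mode, see
#'   [load_cohort()].
#' @param seed master seed; every stage derives a child seed from it.
#' @param k_range candidate class counts for the latent class model.
#' @param n_draws pseudo-class draws for the stability selection.
#' @param min_prev disease-eligibility prevalence threshold.
#' @param oe_min,excl_min overexpression thresholds.
#' @param stability_threshold selection-frequency retention threshold.
#' @param n_folds cross-validation folds for all penalized fits.
#' @param output_dir directory the stage artifacts are written to.
#' @return Object of class `run_config`.
#' @export
run_config <- function(preset = "study_scale",
                       baseline_path = NULL, visits_path = NULL, schema = NULL,
                       seed = 1L, k_range = 2:6, n_draws = 1000,
                       min_prev = 0.02, oe_min = 2.0, excl_min = 0.25,
                       stability_threshold = 0.70, n_folds = 10,
                       output_dir = tempfile("multimorbid_run_")) {
  if (is.null(preset) && (is.null(baseline_path) || is.null(visits_path) ||
                          is.null(schema)))
    stop("either a preset or baseline/visits paths with a schema are required")
  stopifnot(min_prev >= 0, min_prev <= 1,
            oe_min >= 0, excl_min >= 0, excl_min <= 1,
            n_draws >= 1, n_folds >= 2, length(k_range) >= 1)
  if (stability_threshold <= 0 || stability_threshold > 1)
    stop("stability_threshold must lie in (0, 1]")
  structure(list(preset = preset, baseline_path = baseline_path,
                 visits_path = visits_path, schema = schema,
                 seed = as.integer(seed), k_range = k_range,
                 n_draws = n_draws, min_prev = min_prev,
                 oe_min = oe_min, excl_min = excl_min,
                 stability_threshold = stability_threshold,
                 n_folds = n_folds, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full multimorbidity-biomarker analysis
#'
#' Orchestrates the seven pipeline stages from one configuration:
#' simulate-or-load, preprocess (below-detection imputation, z-scoring,
#' correlation structure), latent-class fitting with class-count selection
#' on the multimorbid subset, O/E-ratio/exclusivity pattern labelling,
#' biomarker selection (Gaussian LASSO on the baseline disease count and
#' stability selection over pseudo-class draws), longitudinal slope
#' modelling with slope LASSO, and PCA subprofiles per multimorbidity
#' measure. Each stage writes its artifact as delimited text or JSON under
#' `config$output_dir`, and a JSON manifest records the config hash, master
#' and child seeds, per-stage timings and completed stages. A rerun with the
#' same config reproduces the same artifacts.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every stage result plus the manifest.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "multimorbid",
                   version = as.character(utils::packageVersion("multimorbid")),
                   seed = config$seed,
                   config_hash = config_hash(unclass(config)),
                   stages = list())
  results <- list()
  t_all <- proc.time()[["elapsed"]]

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "completed",
      seed = child_seed(config$seed, length(manifest$stages) + 1L),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    value
  }

  # 1. simulate or load -----------------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$preset)) {
      gen <- generate_cohort(preset_scenario(config$preset,
                                             seed = child_seed(config$seed, 1L)))
      results$truth <- gen$truth
      gen$cohort
    } else {
      load_cohort(config$baseline_path, config$visits_path, config$schema)
    }
  })
  write_cohort(cohort, file.path(out_dir, "cohort"))
  manifest$n_dropped <- cohort$n_dropped

  # 2. preprocess ------------------------------------------------------------
  prep <- run_stage("preprocess", {
    std <- zscore_biomarkers(cohort)
    corr <- spearman_matrix(std)
    list(cohort = std, corr = corr)
  })
  utils::write.csv(as.data.frame(prep$corr$values),
                   file.path(out_dir, "biomarker_spearman.csv"))
  results$cohort <- prep$cohort

  # 3. latent class analysis on the multimorbid subset -----------------------
  lca_res <- run_stage("lca", {
    mm <- disease_count(prep$cohort) >= 2
    Y <- diseases(prep$cohort)[mm, , drop = FALSE]
    keep <- eligible_diseases(Y, config$min_prev)
    Y <- Y[, keep, drop = FALSE]
    sel <- select_k(Y, config$k_range, seed = child_seed(config$seed, 3L))
    model <- sel$models[[paste0("K", sel$chosen_K)]]
    list(multimorbid = mm, Y = Y, selection = sel, model = model,
         posterior = posterior_membership(model, Y))
  })
  utils::write.csv(lca_res$selection$report,
                   file.path(out_dir, "lca_selection.csv"), row.names = FALSE)
  jsonlite::write_json(list(K = lca_res$model$K, pi = lca_res$model$pi,
                            rho = lca_res$model$rho,
                            loglik = lca_res$model$loglik,
                            converged = lca_res$model$converged),
                       file.path(out_dir, "lca_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$lca <- lca_res

  # 4. pattern labelling ------------------------------------------------------
  labels_res <- run_stage("label", {
    lab <- suppressMessages(modal_assignment(lca_res$posterior, lca_res$model$pi))
    tab <- overexpressed(oe_exclusivity(lca_res$Y, lab),
                         config$oe_min, config$excl_min)
    list(modal = lab, table = tab, names = label_patterns(tab))
  })
  utils::write.csv(labels_res$table, file.path(out_dir, "pattern_labels.csv"),
                   row.names = FALSE)
  results$patterns <- labels_res

  # 5. biomarker selection ----------------------------------------------------
  select_res <- run_stage("select", {
    X <- biomarkers(results$cohort)
    covars <- as.matrix(results$cohort$baseline[c("age", "sex", "education")])
    count_fit <- cv_lasso(cbind(covars, X), disease_count(results$cohort),
                          family = "gaussian",
                          penalty_factor = c(rep(0, 3L), rep(1, ncol(X))),
                          n_folds = config$n_folds,
                          seed = child_seed(config$seed, 5L))
    draws <- draw_memberships(lca_res$posterior, config$n_draws,
                              seed = child_seed(config$seed, 50L))
    stab <- stability_select(draws, X, covars, lca_res$multimorbid,
                             threshold = config$stability_threshold,
                             n_folds = config$n_folds,
                             seed = child_seed(config$seed, 51L))
    list(count_fit = count_fit, draws = draws, stability = stab)
  })
  utils::write.csv(select_res$stability,
                   file.path(out_dir, "stability_selection.csv"),
                   row.names = FALSE)
  results$selection <- select_res

  # 6. longitudinal -----------------------------------------------------------
  long_res <- run_stage("longitudinal", {
    slopes <- fit_disease_trajectories(results$cohort)
    X <- biomarkers(results$cohort)
    covars <- as.matrix(results$cohort$baseline[c("age", "sex", "education")])
    sl_fit <- slope_lasso(slopes, X, covars, n_folds = config$n_folds,
                          seed = child_seed(config$seed, 6L))
    list(slopes = slopes, fit = sl_fit)
  })
  utils::write.csv(long_res$slopes$estimates,
                   file.path(out_dir, "slopes.csv"), row.names = FALSE)
  utils::write.csv(long_res$fit$table,
                   file.path(out_dir, "slope_selection.csv"), row.names = FALSE)
  results$longitudinal <- long_res

  # 7. PCA subprofiles ---------------------------------------------------------
  pca_res <- run_stage("pca", {
    X <- biomarkers(results$cohort)
    profiles <- list()
    count_bm <- names(which(select_res$count_fit$coefficients[colnames(X)] != 0))
    if (length(count_bm) >= 2L)
      profiles$disease_count <- pca_profile(X[, count_bm, drop = FALSE])
    slope_bm <- long_res$fit$table$biomarker[long_res$fit$table$retained]
    if (length(slope_bm) >= 2L)
      profiles$accumulation_rate <- pca_profile(X[, slope_bm, drop = FALSE])
    for (cl in unique(select_res$stability$class)) {
      sub <- select_res$stability[select_res$stability$class == cl, ]
      bm <- sub$biomarker[sub$retained]
      if (length(bm) >= 2L)
        profiles[[cl]] <- pca_profile(X[, bm, drop = FALSE])
    }
    profiles
  })
  if (length(pca_res)) {
    long_tab <- do.call(rbind, lapply(names(pca_res), function(m)
      cos2_table(pca_res[[m]], m)))
    utils::write.csv(long_tab, file.path(out_dir, "pca_cos2.csv"),
                     row.names = FALSE)
  }
  results$pca <- pca_res

  manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest$n_stages_completed <- sum(vapply(manifest$stages,
                                            function(s) s$status == "completed",
                                            logical(1L)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
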