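test_that("the generator is deterministic given its seed", {
  cfg <- small_config(n = 120, seed = 31)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$baseline, g2$cohort$baseline)
  expect_identical(g1$cohort$visits, g2$cohort$visits)
  expect_identical(g1$truth, g2$truth)
})

test_that("single-class disease prevalences match the planted probabilities", {
  # binomial sampling oracle: each prevalence within 3 binomial s.e. at n = 5000
  probs <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  cfg <- generator_config(n_participants = 5000,
                          class_proportions = 1,
                          item_probs = matrix(probs, 1),
                          biomarker_class_effects = matrix(0, 1, 3),
                          biomarker_corr = diag(3),
                          slope_effects = numeric(3), seed = 5)
  g <- generate_cohort(cfg)
  prev <- colMeans(diseases(g$cohort))
  se <- sqrt(probs * (1 - probs) / 5000)
  expect_true(all(abs(prev - probs) <= 3 * se))
})

test_that("marginal prevalence follows the law of total probability", {
  cfg <- small_config(n = 4000, K = 2, D = 8, seed = 17)
  g <- generate_cohort(cfg)
  expected <- as.vector(cfg$class_proportions %*% cfg$item_probs)
  prev <- colMeans(diseases(g$cohort))
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_true(all(abs(prev - expected) <= 3 * se))
})

test_that("noiseless configurations yield flat trajectories and zero slopes", {
  cfg <- small_config(n = 150, seed = 3,
                      slope_random_sd = 0, intercept_random_sd = 0,
                      residual_sd = 0)
  g <- generate_cohort(cfg)
  counts <- g$cohort$visits$disease_count
  base <- rep(unname(disease_count(g$cohort)), each = length(cfg$visit_times))
  expect_identical(counts, base)
  sl <- fit_disease_trajectories(g$cohort)
  expect_lt(max(abs(sl$estimates$slope)), 1e-6)
})

test_that("visit counts are non-decreasing and anchored at the baseline row sum", {
  g <- generate_cohort(preset_scenario("well_separated", seed = 8))
  v <- g$cohort$visits
  nondec <- vapply(split(v$disease_count, v$participant_id),
                   function(x) all(diff(x) >= 0), logical(1))
  expect_true(all(nondec))
  v0 <- v[v$time_years == 0, ]
  idx <- match(v0$participant_id, g$cohort$baseline$participant_id)
  expect_equal(v0$disease_count, unname(disease_count(g$cohort)[idx]))
})

test_that("left-censoring hits the configured fraction per biomarker", {
  g <- generate_cohort(preset_scenario("well_separated", seed = 8))
  frac <- colMeans(g$cohort$lod_mask)
  expect_true(all(abs(frac - 0.02) <= 1 / n_participants(g$cohort)))
  # censored values sit exactly at the per-biomarker detection limit
  X <- biomarkers(g$cohort)
  lods <- vapply(seq_len(ncol(X)), function(j) min(X[, j]), numeric(1))
  expect_true(all(X[g$cohort$lod_mask] ==
                    lods[col(X)[g$cohort$lod_mask]]))
})

test_that("presets encode their documented scenarios", {
  ws <- preset_scenario("well_separated")
  # minimum inter-class gap on each class's discriminating diseases
  for (k in seq_len(nrow(ws$item_probs))) {
    disc <- which(ws$item_probs[k, ] >= 0.5)
    expect_true(all(ws$item_probs[k, disc] -
                      apply(ws$item_probs[-k, disc, drop = FALSE], 2, max) >= 0.4))
  }
  nu <- preset_scenario("null_effects")
  expect_true(all(nu$biomarker_class_effects == 0))
  expect_true(all(nu$slope_effects == 0))
  pl <- preset_scenario("study_scale")
  expect_length(pl$class_proportions, 5)
  expect_equal(pl$visit_times, c(0, 3, 6, 9, 12, 15))
  expect_error(preset_scenario("nope"), "well_separated")
})

test_that("invalid generator configurations are rejected", {
  expect_error(small_config(n = 100, seed = 1, visit_times = numeric(0)))
  bad_corr <- matrix(c(1, 2, 2, 1), 2)  # not positive-definite
  expect_error(generator_config(n_participants = 10, class_proportions = 1,
                                item_probs = matrix(0.5, 1, 3),
                                biomarker_class_effects = matrix(0, 1, 2),
                                biomarker_corr = bad_corr,
                                slope_effects = numeric(2)),
               "positive-definite")
  expect_error(generator_config(n_participants = 10, class_proportions = c(0.5, 0.4),
                                item_probs = matrix(0.5, 2, 3),
                                biomarker_class_effects = matrix(0, 2, 2),
                                biomarker_corr = diag(2),
                                slope_effects = numeric(2)),
               "sum to 1")
})
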