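test_that("pseudo-class draws follow the posterior and the seed", {
  # degenerate rows always land in their class
  post <- diag(3)[c(1, 2, 3, 2, 1), ]
  d <- draw_memberships(post, 50, seed = 1)
  expect_true(all(d == matrix(c(1, 2, 3, 2, 1), 50, 5, byrow = TRUE)))
  # a 50/50 row lands in class 1 about half the time (3 binomial s.e.)
  d2 <- draw_memberships(matrix(c(0.5, 0.5), 1), 1000, seed = 2)
  expect_gte(mean(d2 == 1), 0.45)
  expect_lte(mean(d2 == 1), 0.55)
  # determinism
  expect_identical(draw_memberships(post, 20, seed = 9),
                   draw_memberships(post, 20, seed = 9))
  expect_error(draw_memberships(post, 0), "n_draws")
  expect_error(draw_memberships(matrix(c(0.7, 0.6), 1), 5), "simplex")
})

test_that("the penalty path zeroes penalized terms at lambda_max and matches
           least squares as lambda vanishes", {
  set.seed(21)
  n <- 50
  X <- cbind(cov1 = rnorm(n), b1 = rnorm(n), b2 = rnorm(n), b3 = rnorm(n))
  y <- 0.5 * X[, "cov1"] + 1.2 * X[, "b1"] - 0.7 * X[, "b3"] + rnorm(n, 0, 0.3)
  pf <- c(0, 1, 1, 1)
  fit <- cv_lasso(X, y, family = "gaussian", penalty_factor = pf,
                  n_folds = 5, seed = 3)
  # top of the path: every penalized coefficient exactly 0, covariate free
  top <- lasso_coef(fit, s = fit$lambda_path[1])
  expect_true(all(top[c("b1", "b2", "b3")] == 0))
  expect_gt(abs(top["cov1"]), 0)
  # lambda -> 0: ordinary least squares, via the normal-equations oracle
  ols <- coef(lm(y ~ X))
  tiny <- lasso_coef(fit, s = 1e-8)
  expect_equal(unname(tiny), unname(ols), tolerance = 1e-4)
  # the 1se rule never chooses a smaller penalty than the minimizer
  expect_gte(fit$lambda_1se, fit$lambda_min)
  expect_identical(fit$rule, "1se")

  expect_error(cv_lasso(X, y, n_folds = n + 1), "n_folds")
  expect_error(cv_lasso(X, rep(1, n)), "constant")
  expect_error(cv_lasso(X, factor(rep("a", n)), family = "multinomial"),
               "single observed class")
})

test_that("Rubin's rule pools estimates and inflates the between variance", {
  r <- rubins_rule(c(2, 2, 2), c(0.5, 0.7, 0.6))
  expect_equal(r$estimate, 2)
  expect_equal(r$between, 0)
  expect_equal(r$total_variance, 0.6)  # reduces to the mean within-variance
  r2 <- rubins_rule(c(1, 3), c(0, 0))
  expect_equal(r2$estimate, 2)
  expect_equal(r2$total_variance, (1 + 1 / 2) * 2)  # 3
  # total variance always dominates the within component
  set.seed(4)
  for (i in 1:10) {
    e <- rnorm(5); v <- runif(5)
    r3 <- rubins_rule(e, v)
    expect_gte(r3$total_variance, r3$within)
  }
  expect_error(rubins_rule(1, 1), "at least 2")
})

test_that("the pooling rule averages only the nonzero coefficients", {
  expect_equal(multimorbid:::mean_nonzero(c(0.2, 0, 0.4)), 0.3)
  expect_equal(multimorbid:::mean_nonzero(c(0, 0)), 0)
})

test_that("degenerate posteriors collapse stability selection to a single fit", {
  set.seed(31)
  n <- 240
  multimorbid_rows <- rep(c(FALSE, TRUE), c(40, 200))
  cls <- sample(1:3, 200, replace = TRUE)
  post <- diag(3)[cls, ]
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("bm", 1:5)))
  X[multimorbid_rows, 1] <- X[multimorbid_rows, 1] + 0.9 * (cls == 1)
  covars <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                  education = rbinom(n, 1, 0.8))
  d3 <- draw_memberships(post, 3, seed = 5)
  res3 <- stability_select(d3, X, covars, multimorbid_rows, n_folds = 5, seed = 7)
  expect_true(all(res3$frequency %in% c(0, 1)))
  # identical draws reduce to a single multinomial LASSO: same support and
  # retention (coefficient values differ only through per-draw CV folds)
  res1 <- stability_select(d3[1, , drop = FALSE], X, covars, multimorbid_rows,
                           n_folds = 5, seed = 7)
  expect_equal(res3$frequency, res1$frequency)
  expect_identical(res3$retained, res1$retained)
  expect_identical(sign(res3$pooled_beta), sign(res1$pooled_beta))
  expect_identical(attr(res3, "n_draws_used"), 3L)
  # retention threshold is inclusive
  expect_identical(res3$retained, res3$frequency >= 0.70)
})

test_that("a draw missing a class is skipped and excluded from the denominator", {
  post <- rbind(c(0.95, 0.05), c(0.9, 0.1), c(0.85, 0.15), c(0.95, 0.05))
  post <- post[rep(1:4, 20), ]  # class 2 rarely drawn
  n <- 100
  mm <- rep(c(FALSE, TRUE), c(20, 80))
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("bm", 1:3)))
  covars <- cbind(age = rnorm(n))
  d <- draw_memberships(post, 8, seed = 42)
  has_all <- apply(d, 1, function(r) length(unique(r)) == 2)
  if (any(!has_all)) {
    expect_warning(res <- stability_select(d, X, covars, mm, n_folds = 4, seed = 1),
                   "skipped")
    expect_identical(attr(res, "n_draws_used"), sum(has_all))
  } else succeed("all draws contained both classes")
})

test_that("pooled distal regression reduces to one fit under certainty and
           flags separation", {
  set.seed(12)
  n <- 200
  mm <- rep(c(FALSE, TRUE), c(50, 150))
  cls <- sample(1:2, 150, replace = TRUE)
  post <- diag(2)[cls, ]
  covars <- cbind(age = rnorm(n))
  d <- draw_memberships(post, 4, seed = 3)
  out <- rbinom(n, 1, 0.3)
  pooled <- pooled_distal_glm(d, out, covars, mm)
  # identical draws: between-variance 0, so se equals the single-fit se
  lab <- integer(n); lab[mm] <- cls
  y <- factor(c("ref", "class1", "class2")[lab + 1L],
              levels = c("ref", "class1", "class2"))
  single <- glm(out ~ y + age, family = binomial(),
                data = data.frame(out = out, y = y, age = covars[, 1]))
  expect_equal(pooled$log_odds,
               unname(coef(single)[c("yclass1", "yclass2")]), tolerance = 1e-8)
  expect_equal(pooled$se,
               unname(sqrt(diag(vcov(single))[c("yclass1", "yclass2")])),
               tolerance = 1e-6)
  # outcome equal to one class indicator separates perfectly
  out_sep <- as.integer(lab == 1)
  expect_warning(expect_error(pooled_distal_glm(d, out_sep, covars, mm),
                              "no usable draws"),
                 "separation")
})

test_that("null biomarker effects are rarely retained, planted ones always", {
  # pattern membership carries no biomarker signal: pooled intervals cover 0
  set.seed(77)
  covered <- 0L; total <- 0L
  for (rep in 1:10) {
    g <- generate_cohort(small_config(n = 240, K = 2, D = 8, B = 3,
                                      seed = 700 + rep,
                                      low_disease_fraction = 0.2))
    co <- zscore_biomarkers(g$cohort)
    mm <- disease_count(co) >= 2
    fit <- fit_lca(diseases(co)[mm, ], 2, n_starts = 3, seed = rep)
    post <- posterior_membership(fit, diseases(co)[mm, ])
    d <- draw_memberships(post, 12, seed = rep)
    outcome <- rbinom(n_participants(co), 1, 0.3)  # independent of classes
    covars <- as.matrix(co$baseline[c("age", "sex", "education")])
    pooled <- tryCatch(
      suppressWarnings(pooled_distal_glm(d, outcome, covars, mm)),
      error = function(e) NULL)
    if (is.null(pooled)) next
    covered <- covered + sum(pooled$ci_low <= 0 & pooled$ci_high >= 0)
    total <- total + nrow(pooled)
  }
  expect_gte(covered / total, 0.9)
})
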