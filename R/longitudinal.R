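#' Per-participant disease-accumulation slopes from a mixed model
#'
#' Fits a linear mixed-effect model to the long visit table: disease count
#' on time since baseline with fixed effects for time, baseline age, sex and
#' education, and a correlated (unstructured) random intercept and random
#' slope on time per participant, by restricted maximum likelihood. The
#' per-participant slope is the empirical-Bayes (shrinkage) prediction
#' `fixed time effect + random-slope BLUP`, in diseases/year.
#'
#' @param cohort a [cohort_table()] (visits plus baseline covariates), or a
#'   long data.frame with columns `participant_id`, `time_years`,
#'   `disease_count`, `age`, `sex`, `education`.
#' @return Object of class `slope_estimates`: `estimates` data.frame
#'   (`participant_id`, `intercept`, `slope`), `fixed_effects`, the random-
#'   effect covariance `varcorr`, residual `sigma`, and the `lme4` fit.
#' @export
fit_disease_trajectories <- function(cohort) {
  if (inherits(cohort, "cohort_table")) {
    dat <- merge(cohort$visits,
                 cohort$baseline[c("participant_id", "age", "sex", "education")],
                 by = "participant_id")
  } else {
    dat <- as.data.frame(cohort)
  }
  need <- c("participant_id", "time_years", "disease_count", "age", "sex", "education")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  nv <- table(dat$participant_id)
  if (all(nv < 2L))
    stop("all participants have a single visit; the slope variance is unidentifiable")

  fit <- suppressWarnings(suppressMessages(lme4::lmer(
    disease_count ~ time_years + age + sex + education +
      (1 + time_years | participant_id),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))))
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$participant_id
  est <- data.frame(participant_id = rownames(re),
                    intercept = fe[["(Intercept)"]] + re[["(Intercept)"]],
                    slope = fe[["time_years"]] + re[["time_years"]],
                    row.names = NULL, stringsAsFactors = FALSE)
  # return in baseline order when a cohort was given
  if (inherits(cohort, "cohort_table"))
    est <- est[match(cohort$baseline$participant_id, est$participant_id), ,
               drop = FALSE]
  vc <- lme4::VarCorr(fit)$participant_id
  structure(list(estimates = est, fixed_effects = fe,
                 varcorr = vc[seq_len(2L), seq_len(2L)],
                 sigma = stats::sigma(fit), model = fit),
            class = "slope_estimates")
}

#' @export
print.slope_estimates <- function(x, ...) {
  cat("disease-accumulation slopes for", nrow(x$estimates), "participants\n")
  cat(sprintf("  fixed time effect %.4f diseases/year; random-slope s.d. %.4f; residual s.d. %.4f\n",
              x$fixed_effects[["time_years"]], sqrt(x$varcorr[2L, 2L]), x$sigma))
  invisible(x)
}

#' Gaussian LASSO of disease-accumulation slopes on biomarkers
#'
#' The second stage of the longitudinal analysis: the empirical-Bayes
#' per-participant slopes are used as the outcome of a cross-validated
#' Gaussian LASSO (one-standard-error penalty) on the standardized
#' biomarkers, with age, sex and education forced in unpenalized. A
#' biomarker is retained when its coefficient is nonzero at the chosen
#' penalty.
#'
#' @param slopes a `slope_estimates` object, or a numeric vector of slopes
#'   aligned with the rows of `X`.
#' @param X standardized biomarker matrix.
#' @param covariates matrix of adjustment covariates (age, sex, education).
#' @param n_folds,seed,nlambda CV settings, see [cv_lasso()].
#' @return Object of class `slope_fit`: `table` (`biomarker`, `beta`,
#'   `retained`), the full frozen coefficient vector (intercept, covariates,
#'   biomarkers) used for coefficient transfer, the training mean squared
#'   error of predicted vs observed slopes, and the underlying
#'   `penalized_fit`.
#' @export
slope_lasso <- function(slopes, X, covariates, n_folds = 10, seed = 1L,
                        nlambda = 100) {
  y <- if (inherits(slopes, "slope_estimates")) slopes$estimates$slope else slopes
  X <- as.matrix(X)
  covariates <- as.matrix(covariates)
  stopifnot(length(y) == nrow(X), nrow(covariates) == nrow(X))
  bm_names <- colnames(X) %||% sprintf("bm%02d", seq_len(ncol(X)))
  cov_names <- colnames(covariates) %||% paste0("cov", seq_len(ncol(covariates)))
  design <- cbind(covariates, X)
  colnames(design) <- c(cov_names, bm_names)
  pf <- c(rep(0, ncol(covariates)), rep(1, ncol(X)))
  fit <- cv_lasso(design, y, family = "gaussian", penalty_factor = pf,
                  n_folds = n_folds, seed = seed, nlambda = nlambda)
  co <- fit$coefficients
  beta <- co[bm_names]
  pred <- as.vector(cbind(1, design) %*% co)
  structure(list(table = data.frame(biomarker = bm_names, beta = unname(beta),
                                    retained = unname(beta != 0),
                                    row.names = NULL),
                 coefficients = co,
                 covariate_names = cov_names,
                 training_mse = mean((y - pred)^2),
                 fit = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  kept <- x$table[x$table$retained, , drop = FALSE]
  cat("slope LASSO:", nrow(kept), "of", nrow(x$table),
      "biomarkers retained at lambda-1se\n")
  if (nrow(kept)) print(kept, row.names = FALSE, digits = 3)
  cat(sprintf("  training MSE %.4g (diseases/year)^2\n", x$training_mse))
  invisible(x)
}

# internal constructor: derives rmse from mse
new_validation_report <- function(observed, predicted, mse, training_mse,
                                  refit_coefficients, n) {
  structure(list(observed = observed, predicted = predicted,
                 mse = mse, rmse = sqrt(mse), training_mse = training_mse,
                 refit_coefficients = refit_coefficients, n = n),
            class = "validation_report")
}

#' Assemble a validation report from observed and predicted slopes
#'
#' @param observed,predicted numeric vectors of slopes (diseases/year).
#' @param training_mse training-cohort MSE reported for comparison.
#' @param refit_coefficients optional diagnostic refit coefficients.
#' @return Object of class `validation_report` with `mse` (diseases/year)^2
#'   and `rmse = sqrt(mse)` diseases/year.
#' @export
validation_report <- function(observed, predicted, training_mse = NA_real_,
                              refit_coefficients = NULL) {
  stopifnot(length(observed) == length(predicted))
  new_validation_report(observed, predicted,
                        mse = mean((observed - predicted)^2),
                        training_mse = training_mse,
                        refit_coefficients = refit_coefficients,
                        n = length(observed))
}

#' @export
print.validation_report <- function(x, ...) {
  cat("external validation of the slope model on", x$n, "participants\n")
  cat(sprintf("  validation MSE %.4g, RMSE %.3f diseases/year (training MSE %.4g)\n",
              x$mse, x$rmse, x$training_mse))
  invisible(x)
}

#' Coefficient-transfer external validation of the slope model
#'
#' Four-step protocol in an independent validation cohort: (1) observed
#' slopes are estimated in the validation cohort with the same random-slope
#' mixed model; (2) an age-adjusted least-squares regression of the observed
#' slopes on the retained biomarkers is fitted in the validation cohort as a
#' diagnostic (reported, never used for prediction); (3) the frozen training
#' coefficients — intercept, covariates and biomarkers at the training
#' penalty — are applied to the validation design matrix to produce
#' predicted slopes; (4) the mean squared error between predicted and
#' observed slopes is reported alongside the training cohort's own MSE.
#' Validation-cohort biomarkers are standardized with the validation
#' cohort's own means and standard deviations.
#'
#' @param training_fit a `slope_fit` from [slope_lasso()] on the training
#'   cohort.
#' @param validation_cohort a [cohort_table()] containing every retained
#'   biomarker and the model covariates.
#' @return A [validation_report()].
#' @export
external_validate <- function(training_fit, validation_cohort) {
  stopifnot(inherits(training_fit, "slope_fit"),
            inherits(validation_cohort, "cohort_table"))
  retained <- training_fit$table$biomarker[training_fit$table$retained]
  miss <- setdiff(retained, validation_cohort$biomarker_names)
  if (length(miss))
    stop("validation cohort is missing retained biomarker(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(union(training_fit$table$biomarker,
                        training_fit$covariate_names),
                  c(validation_cohort$biomarker_names,
                    names(validation_cohort$baseline)))
  if (length(miss))
    stop("validation cohort is missing model column(s): ",
         paste(miss, collapse = ", "))

  if (!validation_cohort$standardized)
    validation_cohort <- zscore_biomarkers(validation_cohort)

  # step 1: observed slopes
  obs <- fit_disease_trajectories(validation_cohort)$estimates$slope

  X <- biomarkers(validation_cohort)[, training_fit$table$biomarker, drop = FALSE]
  covars <- as.matrix(
    validation_cohort$baseline[training_fit$covariate_names])

  # step 2: diagnostic refit (age-adjusted OLS on the retained biomarkers)
  refit <- stats::coef(stats::lm(
    obs ~ ., data = data.frame(age = validation_cohort$baseline$age,
                               as.data.frame(X[, retained, drop = FALSE]))))

  # step 3: coefficient transfer
  pred <- as.vector(cbind(1, covars, X) %*% training_fit$coefficients)

  # step 4: MSE
  new_validation_report(observed = obs, predicted = pred,
                        mse = mean((obs - pred)^2),
                        training_mse = training_fit$training_mse,
                        refit_coefficients = refit,
                        n = length(obs))
}
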