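#' Pseudo-class membership draws
#'
#' Samples a hard class label for every participant from their posterior
#' membership probabilities, independently for each of `n_draws` replicates —
#' the pseudo-class device that propagates classification uncertainty into
#' downstream regressions. Deterministic given `seed`.
#'
#' @param post `n x K` posterior matrix, rows on the simplex.
#' @param n_draws number of replicates (default 1000).
#' @param seed integer seed.
#' @return `n_draws x n` integer matrix of class labels (class `draw_matrix`,
#'   with `seed` attached).
#' @export
draw_memberships <- function(post, n_draws = 1000, seed = 1L) {
  post <- as.matrix(post)
  if (n_draws < 1) stop("n_draws must be at least 1")
  if (any(abs(rowSums(post) - 1) > 1e-6) || any(post < 0))
    stop("posterior rows must lie on the simplex")
  n <- nrow(post)
  set.seed(seed)
  draws <- vapply(seq_len(n), function(i) {
    cp <- cumsum(post[i, ])
    cp[length(cp)] <- 1
    findInterval(stats::runif(n_draws), cp, left.open = TRUE) + 1L
  }, integer(n_draws))
  structure(draws, class = c("draw_matrix", class(draws)), seed = seed)
}

#' Cross-validated LASSO with the one-standard-error rule
#'
#' L1-penalized regression over a 100-step log-spaced penalty path from the
#' smallest penalty that zeroes every penalized coefficient, with K-fold
#' cross-validation (mean squared error for gaussian outcomes, deviance for
#' multinomial/binomial). The returned coefficients are taken at
#' `lambda.1se`, the largest penalty whose CV error is within one standard
#' error of the minimum (set `rule = "min"` for `lambda.min`). Adjustment
#' covariates are kept unpenalized via `penalty_factor = 0` and can never be
#' shrunk out of the model.
#'
#' @param X numeric design matrix (standardized biomarkers plus covariate
#'   columns).
#' @param y outcome: numeric (gaussian), factor (multinomial), or binary
#'   (binomial).
#' @param family `"gaussian"`, `"multinomial"` or `"binomial"`.
#' @param penalty_factor per-column 0/1 penalty multipliers (0 = covariate,
#'   never penalized); default all 1.
#' @param n_folds CV folds.
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed integer seed for the fold assignment.
#' @param nlambda path length.
#' @param lambda optional user penalty path (overrides `nlambda`).
#' @return Object of class `penalized_fit`: the `cv.glmnet` fit, the chosen
#'   `lambda_min`/`lambda_1se`, the coefficient vector (or per-class
#'   coefficient matrix) at the chosen rule, and the CV curve.
#' @export
cv_lasso <- function(X, y, family = c("gaussian", "multinomial", "binomial"),
                     penalty_factor = NULL, n_folds = 10, rule = c("1se", "min"),
                     seed = 1L, nlambda = 100, lambda = NULL) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_folds > n) stop("n_folds cannot exceed the number of observations")
  if (is.null(penalty_factor)) penalty_factor <- rep(1, ncol(X))
  if (family == "gaussian") {
    if (stats::sd(y) == 0) stop("degenerate outcome: y is constant")
  } else {
    if (length(unique(y)) < 2L) stop("degenerate outcome: single observed class")
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  type_measure <- if (family == "gaussian") "mse" else "deviance"
  fit <- glmnet::cv.glmnet(X, y, family = family, foldid = foldid,
                           penalty.factor = penalty_factor,
                           type.measure = type_measure,
                           nlambda = nlambda, lambda = lambda,
                           standardize = FALSE)
  s <- if (rule == "1se") fit$lambda.1se else fit$lambda.min
  co <- stats::coef(fit, s = s)
  if (family == "multinomial")
    co <- do.call(cbind, lapply(co, function(m) as.matrix(m)[, 1L]))
  else
    co <- as.matrix(co)[, 1L]
  structure(list(fit = fit, family = family, x = X, y = y,
                 lambda_path = fit$lambda,
                 lambda_min = fit$lambda.min, lambda_1se = fit$lambda.1se,
                 rule = rule, coefficients = co,
                 penalty_factor = penalty_factor,
                 cv_mean = fit$cvm, cv_se = fit$cvsd),
            class = "penalized_fit")
}

#' Coefficients of a penalized fit at an arbitrary penalty
#'
#' Refits the penalized path down to `s` (rather than interpolating between
#' stored path points), so the coefficients solve the penalized problem at
#' `s` itself.
#'
#' @param object a `penalized_fit`.
#' @param s penalty value.
#' @return coefficient vector (or per-class matrix for multinomial).
#' @export
lasso_coef <- function(object, s) {
  path <- sort(unique(c(object$lambda_path[object$lambda_path > s], s)),
               decreasing = TRUE)
  refit <- glmnet::glmnet(object$x, object$y, family = object$family,
                          penalty.factor = object$penalty_factor,
                          lambda = path, standardize = FALSE,
                          thresh = 1e-12)
  co <- stats::coef(refit, s = s)
  if (object$family == "multinomial")
    do.call(cbind, lapply(co, function(m) as.matrix(m)[, 1L]))
  else as.matrix(co)[, 1L]
}

#' Stability selection over pseudo-class draws
#'
#' The uncertainty-aware biomarker selection engine: for each pseudo-class
#' draw, the six-level group variable (reference stratum plus K latent
#' patterns) is regressed on the biomarkers and unpenalized covariates with
#' a cross-validated multinomial LASSO at the one-standard-error penalty;
#' per-class coefficients are re-expressed against the reference class
#' (reference-class coefficients subtracted, so the reference gets zeros).
#' A biomarker's selection frequency for a pattern is the share of usable
#' draws in which its reference-coded coefficient is nonzero; its pooled
#' coefficient is the mean of the nonzero per-draw coefficients (0 if never
#' selected); it is retained when the frequency reaches `threshold`
#' (inclusive). Draws in which some group is entirely absent are skipped
#' with a warning and excluded from the denominator.
#'
#' @param draws `n_draws x n_mm` label matrix from [draw_memberships()] for
#'   the multimorbid rows.
#' @param X `n x B` standardized biomarker matrix for all participants.
#' @param covariates `n x C` matrix of adjustment covariates (unpenalized).
#' @param multimorbid logical length-`n` vector; `FALSE` rows form the
#'   reference (no-multimorbidity) group, constant across draws.
#' @param threshold selection-frequency retention threshold (default 0.70).
#' @param n_folds,nlambda CV settings per draw.
#' @param seed integer seed; each draw re-randomizes its CV folds from a
#'   child seed.
#' @return Object of class `selection_result`: long data.frame
#'   (`class`, `biomarker`, `frequency`, `pooled_beta`, `retained`) plus the
#'   number of usable draws.
#' @export
stability_select <- function(draws, X, covariates, multimorbid,
                             threshold = 0.70, n_folds = 10, nlambda = 50,
                             seed = 1L) {
  X <- as.matrix(X)
  covariates <- as.matrix(covariates)
  n <- nrow(X)
  stopifnot(length(multimorbid) == n, nrow(covariates) == n,
            ncol(draws) == sum(multimorbid))
  B <- ncol(X)
  C <- ncol(covariates)
  bm_names <- colnames(X) %||% sprintf("bm%02d", seq_len(B))
  design <- cbind(covariates, X)
  pf <- c(rep(0, C), rep(1, B))
  K <- max(draws)
  lev <- c("ref", paste0("class", seq_len(K)))

  n_draws <- nrow(draws)
  freq <- matrix(0, K, B, dimnames = list(paste0("class", seq_len(K)), bm_names))
  beta_sum <- freq
  sign_pos <- freq
  used <- 0L
  for (d in seq_len(n_draws)) {
    lab <- integer(n)
    lab[multimorbid] <- draws[d, ]
    y <- factor(lev[lab + 1L], levels = lev)
    if (any(table(y) == 0L)) {
      warning("draw ", d, " is missing a class entirely; skipped")
      next
    }
    fit <- cv_lasso(design, y, family = "multinomial", penalty_factor = pf,
                    n_folds = n_folds, nlambda = nlambda,
                    seed = child_seed(seed, d))
    co <- fit$coefficients                  # (1 + C + B) x (K + 1)
    bm_rows <- seq.int(1L + C + 1L, 1L + C + B)
    rel <- co[bm_rows, -1L, drop = FALSE] - co[bm_rows, 1L]  # vs reference
    nz <- t(rel != 0)
    freq <- freq + nz
    beta_sum <- beta_sum + t(rel)
    sign_pos <- sign_pos + t(rel > 0)
    used <- used + 1L
  }
  if (used == 0L) stop("no usable draws")
  frequency <- freq / used
  pooled <- ifelse(freq > 0, beta_sum / pmax(freq, 1), 0)
  # flag pooled coefficients whose sign disagrees with the majority of
  # nonzero draws
  maj_pos <- sign_pos > freq / 2
  odd <- freq > 0 & (sign(pooled) == 1) != maj_pos & pooled != 0
  if (any(odd))
    message(sum(odd), " pooled coefficient(s) disagree with the majority sign")

  out <- data.frame(class = rep(rownames(frequency), times = B),
                    biomarker = rep(bm_names, each = K),
                    frequency = as.vector(frequency),
                    pooled_beta = as.vector(pooled),
                    retained = as.vector(frequency >= threshold),
                    row.names = NULL)
  structure(out, class = c("selection_result", "data.frame"),
            n_draws_used = used, threshold = threshold)
}

#' Rubin's rule for pooling across draws
#'
#' Pooled estimate = mean of the per-draw estimates; total variance =
#' mean within-draw variance plus `(1 + 1/m)` times the between-draw
#' variance of the estimates.
#'
#' @param estimates,variances numeric vectors of equal length `m >= 2`.
#' @return list with `estimate`, `total_variance`, `within`, `between`.
#' @export
rubins_rule <- function(estimates, variances) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances must have equal length")
  if (m < 2L) stop("Rubin's rule needs at least 2 draws")
  W <- mean(variances)
  B <- stats::var(estimates)
  list(estimate = mean(estimates), total_variance = W + (1 + 1 / m) * B,
       within = W, between = B)
}

#' Pooled logistic regression of a distal outcome on pattern membership
#'
#' Per pseudo-class draw, a maximum-likelihood logistic regression of a
#' binary distal outcome (e.g. incident dementia) on the group dummies
#' (reference = no-multimorbidity) plus covariates; coefficients and their
#' variances are pooled over draws with [rubins_rule()]. Draws exhibiting
#' (quasi-)separation are flagged and excluded with a warning.
#'
#' @param draws label matrix from [draw_memberships()] (multimorbid rows).
#' @param outcome binary vector, length = total participants.
#' @param covariates covariate matrix (all participants).
#' @param multimorbid logical vector marking the multimorbid rows.
#' @return data.frame: per pattern, pooled log-odds vs reference, total-
#'   variance standard error, and 95% interval; `n_draws_used` attached.
#' @export
pooled_distal_glm <- function(draws, outcome, covariates, multimorbid) {
  covariates <- as.matrix(covariates)
  n <- length(outcome)
  stopifnot(all(outcome %in% c(0, 1)), nrow(covariates) == n,
            length(multimorbid) == n, ncol(draws) == sum(multimorbid))
  K <- max(draws)
  lev <- c("ref", paste0("class", seq_len(K)))

  est <- list(); va <- list()
  n_sep <- 0L
  for (d in seq_len(nrow(draws))) {
    lab <- integer(n)
    lab[multimorbid] <- draws[d, ]
    y <- factor(lev[lab + 1L], levels = lev)
    if (any(table(y) == 0L)) next
    dat <- data.frame(outcome = outcome, group = y, covariates)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(outcome ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || !fit$converged) { n_sep <- n_sep + 1L; next }
    idx <- paste0("group", lev[-1L])
    est[[length(est) + 1L]] <- stats::coef(fit)[idx]
    va[[length(va) + 1L]] <- diag(stats::vcov(fit))[idx]
  }
  if (n_sep > 0L)
    warning(n_sep, " draw(s) excluded for separation or non-convergence")
  m <- length(est)
  if (m == 0L) stop("no usable draws")
  E <- do.call(rbind, est)
  V <- do.call(rbind, va)
  rows <- lapply(seq_len(K), function(k) {
    if (m == 1L) {
      r <- list(estimate = E[1L, k], total_variance = V[1L, k])
    } else r <- rubins_rule(E[, k], V[, k])
    se <- sqrt(r$total_variance)
    data.frame(pattern = lev[k + 1L], log_odds = r$estimate, se = se,
               ci_low = r$estimate - 1.96 * se,
               ci_high = r$estimate + 1.96 * se, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_draws_used") <- m
  out
}
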