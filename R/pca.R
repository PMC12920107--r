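#' Principal-component subprofile of LASSO-selected biomarkers
#'
#' Correlation-matrix PCA of the retained biomarkers (variables are
#' re-standardized, so the analysis is of their correlation structure).
#' Reports the leading `min(max_components, p)` components, whether their
#' cumulative explained variance reaches `min_cum_var`, and the cos2
#' variable contributions: `cos2[j, c]` is the squared correlation between
#' variable `j` and component `c`, which for correlation PCA equals
#' `(loading * component s.d.)^2`. Over all `p` components each variable's
#' cos2 sums to 1. Component signs are canonicalized so the largest-|loading|
#' variable of each component loads positively.
#'
#' @param X_selected numeric matrix (>= 3 rows) of at least 2 retained
#'   biomarkers.
#' @param min_cum_var cumulative explained-variance threshold the reported
#'   components should reach (default 40%).
#' @param max_components number of components reported (default 4).
#' @return Object of class `pca_profile`: `variables`, `eigenvalues`
#'   (all `p`, descending), `explained_fraction`, `cumulative_fraction`,
#'   `loadings` and `cos2` for the reported components, `n_components`,
#'   `reaches_threshold`.
#' @export
pca_profile <- function(X_selected, min_cum_var = 0.40, max_components = 4) {
  X_selected <- as.matrix(X_selected)
  p <- ncol(X_selected)
  if (p < 2L) stop("a PCA subprofile needs at least 2 selected biomarkers")
  if (nrow(X_selected) < 3L) stop("at least 3 rows are required")
  vars <- colnames(X_selected) %||% sprintf("v%02d", seq_len(p))

  pc <- stats::prcomp(X_selected, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  expl <- ev / sum(ev)
  ncomp <- min(max_components, p)

  rot <- pc$rotation
  # canonicalize signs: top-loading variable of each component positive
  for (c in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, c]))
    if (rot[j, c] < 0) rot[, c] <- -rot[, c]
  }
  # correlation between variable and component = loading * component sd
  cor_vc <- sweep(rot, 2L, pc$sdev, "*")
  cos2_all <- cor_vc^2

  structure(list(variables = vars,
                 eigenvalues = ev,
                 explained_fraction = expl,
                 cumulative_fraction = cumsum(expl),
                 n_components = ncomp,
                 loadings = rot[, seq_len(ncomp), drop = FALSE],
                 cos2 = cos2_all[, seq_len(ncomp), drop = FALSE],
                 cos2_all = cos2_all,
                 reaches_threshold = cumsum(expl)[ncomp] >= min_cum_var,
                 min_cum_var = min_cum_var),
            class = "pca_profile")
}

#' @export
print.pca_profile <- function(x, ...) {
  cat("PCA subprofile of", length(x$variables), "biomarkers;",
      x$n_components, "components explain",
      sprintf("%.1f%%", 100 * x$cumulative_fraction[x$n_components]),
      "of the variance",
      if (x$reaches_threshold) "(threshold reached)\n"
      else sprintf("(below the %.0f%% threshold)\n", 100 * x$min_cum_var))
  invisible(x)
}

#' Long-format cos2 table for heatmap-style export
#'
#' @param profile a `pca_profile`.
#' @param measure label of the multimorbidity measure the profile belongs to.
#' @return data.frame (`measure`, `biomarker`, `component`, `cos2`,
#'   `explained_fraction`).
#' @export
cos2_table <- function(profile, measure = "measure") {
  ncomp <- profile$n_components
  data.frame(measure = measure,
             biomarker = rep(profile$variables, times = ncomp),
             component = rep(seq_len(ncomp), each = length(profile$variables)),
             cos2 = as.vector(profile$cos2),
             explained_fraction = rep(profile$explained_fraction[seq_len(ncomp)],
                                      each = length(profile$variables)),
             row.names = NULL)
}
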