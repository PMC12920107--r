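#' Disease-eligibility filter for pattern identification
#'
#' Indices of diseases with a prevalence of at least `min_prev` (inclusive)
#' in the multimorbid population — the rows of `Y_multimorbid` must already
#' be restricted to participants with two or more diseases.
#'
#' @param Y_multimorbid binary matrix of the multimorbid subset.
#' @param min_prev prevalence threshold (default 2%).
#' @return integer vector of retained column indices.
#' @export
eligible_diseases <- function(Y_multimorbid, min_prev = 0.02) {
  Y_multimorbid <- as.matrix(Y_multimorbid)
  if (nrow(Y_multimorbid) == 0L) stop("empty disease matrix")
  which(colMeans(Y_multimorbid) >= min_prev)
}

#' Observed/expected ratio and exclusivity per disease and class
#'
#' For every (disease j, class k) pair, computed from hard (modal) class
#' labels: the O/E ratio is the prevalence of disease j inside class k
#' divided by its prevalence in the whole multimorbid population, and the
#' exclusivity is the fraction of all multimorbid cases of disease j that
#' fall in class k. Diseases never observed in the sample have both measures
#' undefined and are flagged (`NA`, `undefined = TRUE`), not zero.
#'
#' @param Y binary disease matrix of the multimorbid subset.
#' @param labels class labels, one per row of `Y`; every class level must be
#'   non-empty. Ignored when `posterior` is supplied.
#' @param posterior optional `n x K` posterior matrix; when given, hard modal
#'   counts are replaced by posterior-weighted soft counts (sensitivity
#'   analysis; the default labelling is modal).
#' @return data.frame of class `pattern_label_table` in long format:
#'   `disease`, `class`, `class_prevalence`, `overall_prevalence`,
#'   `oe_ratio`, `exclusivity`, `undefined`; class size shares are kept in
#'   the `class_sizes` attribute.
#' @export
oe_exclusivity <- function(Y, labels, posterior = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (is.null(posterior)) {
    if (length(labels) != n) stop("labels length must match rows of Y")
    classes <- sort(unique(labels))
    W <- vapply(classes, function(k) as.numeric(labels == k), numeric(n))
  } else {
    posterior <- as.matrix(posterior)
    if (nrow(posterior) != n) stop("posterior rows must match rows of Y")
    classes <- seq_len(ncol(posterior))
    W <- posterior
  }
  sizes <- colSums(W)
  if (any(sizes == 0)) stop("empty class")
  dn <- colnames(Y) %||% sprintf("d%02d", seq_len(ncol(Y)))

  count_j <- colSums(Y)
  p_j <- count_j / n
  out <- do.call(rbind, lapply(seq_along(classes), function(ki) {
    count_jk <- as.vector(t(Y) %*% W[, ki])
    p_jk <- count_jk / sizes[ki]
    undef <- count_j == 0
    data.frame(disease = dn, class = classes[ki],
               class_prevalence = p_jk, overall_prevalence = p_j,
               oe_ratio = ifelse(undef, NA_real_, p_jk / p_j),
               exclusivity = ifelse(undef, NA_real_, count_jk / count_j),
               undefined = undef,
               row.names = NULL)
  }))
  structure(out, class = c("pattern_label_table", "data.frame"),
            class_sizes = sizes / n)
}

#' Flag overexpressed diseases
#'
#' A disease is overexpressed in a pattern when its O/E ratio is at least
#' `oe_min` AND its exclusivity at least `excl_min` (both inclusive).
#' Undefined entries (zero overall prevalence) stay `NA`.
#'
#' @param table a `pattern_label_table`.
#' @param oe_min O/E threshold (default 2).
#' @param excl_min exclusivity threshold (default 25%).
#' @return The table with a logical `overexpressed` column.
#' @export
overexpressed <- function(table, oe_min = 2.0, excl_min = 0.25) {
  stopifnot(inherits(table, "pattern_label_table"))
  table$overexpressed <- table$oe_ratio >= oe_min & table$exclusivity >= excl_min
  table
}

#' Name patterns from their overexpressed diseases
#'
#' Per class: the overexpressed diseases ordered by decreasing O/E ratio, and
#' a label — the concatenated disease names, or `"Unspecific"` for a pattern
#' with no overexpressed disease.
#'
#' @param table a `pattern_label_table` with an `overexpressed` column (see
#'   [overexpressed()]).
#' @return data.frame with `class`, `label`, `n_overexpressed`.
#' @export
label_patterns <- function(table) {
  if (is.null(table$overexpressed))
    table <- overexpressed(table)
  classes <- unique(table$class)
  do.call(rbind, lapply(classes, function(k) {
    sub <- table[table$class == k & !is.na(table$overexpressed) &
                   table$overexpressed, , drop = FALSE]
    sub <- sub[order(-sub$oe_ratio), , drop = FALSE]
    data.frame(class = k,
               label = if (nrow(sub) == 0L) "Unspecific"
                       else paste(sub$disease, collapse = "+"),
               n_overexpressed = nrow(sub),
               row.names = NULL)
  }))
}
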