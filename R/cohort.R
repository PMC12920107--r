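#' Construct and validate a cohort table
#'
#' A `cohort_table` bundles the two tables an ageing-cohort analysis needs:
#' a wide baseline table (one row per participant: identifier, baseline age,
#' sex and education codes, a continuous blood-biomarker panel, and binary
#' chronic-disease indicators) and a long follow-up table of repeated visits
#' (participant, time since baseline in years, chronic-disease count).
#'
#' Validity rules enforced here: disease indicators are strictly 0/1; the
#' disease count recorded at a time-0 visit equals the row sum of the baseline
#' indicators; every visit refers to a known participant; visit times are
#' strictly increasing within participant.
#'
#' @param baseline data.frame with columns `participant_id`, `age`, `sex`,
#'   `education`, plus one column per biomarker and per disease.
#' @param visits data.frame with columns `participant_id`, `time_years`,
#'   `disease_count`.
#' @param biomarker_names,disease_names character vectors naming the biomarker
#'   and disease columns of `baseline`.
#' @param standardized logical; `TRUE` once biomarkers are z-scores.
#' @param lod_mask optional logical matrix (participants x biomarkers) flagging
#'   measurements below the assay detection limit.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(baseline, visits, biomarker_names, disease_names,
                         standardized = FALSE, lod_mask = NULL) {
  stopifnot(is.data.frame(baseline), is.data.frame(visits))
  need <- c("participant_id", "age", "sex", "education")
  miss <- setdiff(need, names(baseline))
  if (length(miss))
    stop("baseline table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c(biomarker_names, disease_names), names(baseline))
  if (length(miss))
    stop("baseline table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("participant_id", "time_years", "disease_count"), names(visits))
  if (length(miss))
    stop("visits table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(baseline$participant_id))
    stop("duplicated participant_id in baseline table")
  if (anyDuplicated(biomarker_names) || anyDuplicated(disease_names))
    stop("biomarker and disease names must be unique")

  Y <- as.matrix(baseline[disease_names])
  bad <- which(!(Y %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(Y))
    stop(sprintf("non-binary disease value %s at row %d, disease '%s'",
                 format(Y[bad[1L]]), rc[1L], disease_names[rc[2L]]))
  }

  # visits with missing disease_count are dropped per-record
  keep <- !is.na(visits$disease_count)
  if (!all(keep)) {
    message(sum(!keep), " visit record(s) with missing disease_count dropped")
    visits <- visits[keep, , drop = FALSE]
  }
  if (!all(visits$participant_id %in% baseline$participant_id))
    stop("visits refer to participant_id values absent from the baseline table")
  visits <- visits[order(match(visits$participant_id, baseline$participant_id),
                         visits$time_years), , drop = FALSE]
  rownames(visits) <- NULL
  if (any(visits$time_years < 0)) stop("negative visit time")
  by_id <- split(visits$time_years, visits$participant_id)
  if (any(vapply(by_id, function(t) any(diff(t) <= 0), logical(1L))))
    stop("visit times must be strictly increasing within participant")

  # a time-0 visit must agree with the baseline indicators
  base_count <- rowSums(Y)
  v0 <- visits[visits$time_years == 0, , drop = FALSE]
  if (nrow(v0)) {
    idx <- match(v0$participant_id, baseline$participant_id)
    if (any(v0$disease_count != base_count[idx]))
      stop("disease_count at time 0 disagrees with the baseline disease indicators")
  }

  if (!is.null(lod_mask)) {
    stopifnot(is.logical(lod_mask),
              nrow(lod_mask) == nrow(baseline),
              ncol(lod_mask) == length(biomarker_names))
  }

  structure(
    list(baseline = baseline, visits = visits,
         biomarker_names = biomarker_names, disease_names = disease_names,
         standardized = standardized, lod_mask = lod_mask,
         n_dropped = 0L),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$baseline), "participants,",
      length(x$biomarker_names), "biomarkers,",
      length(x$disease_names), "diseases,",
      nrow(x$visits), "visit records",
      if (x$standardized) "(biomarkers standardized)" else "", "\n")
  invisible(x)
}

#' Number of participants in a cohort
#' @param cohort a `cohort_table`.
#' @export
n_participants <- function(cohort) nrow(cohort$baseline)

#' Biomarker matrix of a cohort
#' @param cohort a `cohort_table`.
#' @return numeric matrix participants x biomarkers.
#' @export
biomarkers <- function(cohort) {
  m <- as.matrix(cohort$baseline[cohort$biomarker_names])
  rownames(m) <- cohort$baseline$participant_id
  m
}

#' Disease indicator matrix of a cohort
#' @param cohort a `cohort_table`.
#' @return integer 0/1 matrix participants x diseases.
#' @export
diseases <- function(cohort) {
  m <- as.matrix(cohort$baseline[cohort$disease_names])
  rownames(m) <- cohort$baseline$participant_id
  m
}

#' Baseline chronic-disease count per participant
#' @param cohort a `cohort_table`.
#' @export
disease_count <- function(cohort) rowSums(diseases(cohort))

#' Load a cohort from delimited-text files
#'
#' Reads the wide baseline table and the long visits table, renames columns
#' according to `schema`, coerces disease indicators, and applies the
#' complete-case rule: participants with any missing biomarker measurement are
#' dropped (their visits with them) and the number dropped is reported.
#'
#' @param baseline_path,visits_path paths to delimited text files with header.
#' @param schema named list mapping canonical names to file column names:
#'   `id`, `age`, `sex`, `education`, `biomarkers` (character vector),
#'   `diseases` (character vector). May also be a path to a YAML file with
#'   those keys.
#' @param sep field separator (default comma).
#' @return A validated [cohort_table()]; attribute-free, with the dropped-row
#'   count in `$n_dropped`.
#' @export
load_cohort <- function(baseline_path, visits_path, schema, sep = ",") {
  if (is.character(schema) && length(schema) == 1L) schema <- yaml::read_yaml(schema)
  for (f in c(baseline_path, visits_path))
    if (!file.exists(f)) stop("file not found: ", f)
  need <- c("id", "age", "sex", "education", "biomarkers", "diseases")
  miss <- setdiff(need, names(schema))
  if (length(miss)) stop("schema is missing entries: ", paste(miss, collapse = ", "))

  base_raw <- utils::read.table(baseline_path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE, check.names = FALSE)
  vis_raw <- utils::read.table(visits_path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, check.names = FALSE)

  mapped <- c(schema$id, schema$age, schema$sex, schema$education,
              schema$biomarkers, schema$diseases)
  miss <- setdiff(mapped, names(base_raw))
  if (length(miss))
    stop("baseline file is missing mapped column(s): ", paste(miss, collapse = ", "))
  vis_map <- c(schema$visit_id %||% "participant_id",
               schema$time %||% "time_years",
               schema$count %||% "disease_count")
  miss <- setdiff(vis_map, names(vis_raw))
  if (length(miss))
    stop("visits file is missing mapped column(s): ", paste(miss, collapse = ", "))

  baseline <- data.frame(participant_id = as.character(base_raw[[schema$id]]),
                         age = as.numeric(base_raw[[schema$age]]),
                         sex = as.numeric(base_raw[[schema$sex]]),
                         education = as.numeric(base_raw[[schema$education]]),
                         check.names = FALSE, stringsAsFactors = FALSE)
  baseline[schema$biomarkers] <- lapply(base_raw[schema$biomarkers], as.numeric)
  for (d in schema$diseases) {
    v <- base_raw[[d]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) | !(vn %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary disease value '%s' at row %d, disease '%s'",
                   as.character(v[bad[1L]]), bad[1L], d))
    baseline[[d]] <- as.integer(vn)
  }

  # complete-case rule on the biomarker panel
  B <- as.matrix(baseline[schema$biomarkers])
  complete <- stats::complete.cases(B)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " participant(s) with missing biomarker measurements excluded")
    baseline <- baseline[complete, , drop = FALSE]
    rownames(baseline) <- NULL
  }

  visits <- data.frame(participant_id = as.character(vis_raw[[vis_map[1L]]]),
                       time_years = as.numeric(vis_raw[[vis_map[2L]]]),
                       disease_count = as.numeric(vis_raw[[vis_map[3L]]]),
                       stringsAsFactors = FALSE)
  visits <- visits[visits$participant_id %in% baseline$participant_id, , drop = FALSE]

  out <- cohort_table(baseline, visits,
                      biomarker_names = schema$biomarkers,
                      disease_names = schema$diseases)
  out$n_dropped <- n_dropped
  out
}

#' Write a cohort back to delimited text
#'
#' Inverse of [load_cohort()]: writes `baseline.csv` and `visits.csv` under
#' `dir` in the same schema the loader reads, so that a load/write/load cycle
#' round-trips.
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bp <- file.path(dir, "baseline.csv")
  vp <- file.path(dir, "visits.csv")
  utils::write.csv(cohort$baseline, bp, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$visits, vp, row.names = FALSE, quote = FALSE)
  invisible(c(baseline = bp, visits = vp))
}

#' Default schema for a cohort written by [write_cohort()]
#' @param cohort a `cohort_table`.
#' @export
cohort_schema <- function(cohort) {
  list(id = "participant_id", age = "age", sex = "sex", education = "education",
       biomarkers = cohort$biomarker_names, diseases = cohort$disease_names)
}

#' Single-value imputation of below-detection-limit measurements
#'
#' Measurements flagged as below the assay's limit of detection are replaced
#' by exactly zero (not-missing-at-random single-value imputation), prior to
#' standardization. Unflagged entries are returned unchanged.
#'
#' @param values numeric vector of assay-unit measurements.
#' @param below_lod logical vector of the same length.
#' @return numeric vector with flagged entries set to 0.
#' @export
impute_below_lod <- function(values, below_lod) {
  if (length(values) != length(below_lod))
    stop("values and below_lod must have the same length")
  values[below_lod] <- 0
  values
}

#' Z-score the biomarker panel of a cohort
#'
#' Standardizes every biomarker column with the cohort's own sample mean and
#' sample (n-1) standard deviation. When the cohort carries a detection-limit
#' mask, flagged values are first imputed to zero via [impute_below_lod()].
#' Disease indicators and visit records are untouched.
#'
#' @param cohort a `cohort_table`.
#' @return The cohort with standardized biomarkers (`standardized = TRUE`).
#' @export
zscore_biomarkers <- function(cohort) {
  X <- biomarkers(cohort)
  if (!is.null(cohort$lod_mask))
    X <- matrix(impute_below_lod(as.vector(X), as.vector(cohort$lod_mask)),
                nrow = nrow(X), dimnames = dimnames(X))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant biomarker column(s): ",
         paste(cohort$biomarker_names[sds == 0], collapse = ", "))
  Xs <- scale(X)
  cohort$baseline[cohort$biomarker_names] <- as.data.frame(Xs)
  cohort$standardized <- TRUE
  cohort
}

#' Spearman correlation matrix of the biomarker panel
#'
#' Pairwise Spearman rank correlations between biomarkers; optionally
#' age-adjusted as partial rank correlations: each biomarker (and nothing
#' else) is rank-transformed, residualized on rank-transformed baseline age,
#' and the residuals are correlated. A biomarker whose rank residuals are
#' numerically zero (e.g. a copy of age) yields undefined partial
#' correlations, reported as 0 with a warning.
#'
#' @param cohort a `cohort_table` with at least 3 participants.
#' @param adjust_age logical; partial out baseline age.
#' @return list of class `correlation_matrix` with elements `values`
#'   (B x B matrix) and `adjusted_for_age`.
#' @export
spearman_matrix <- function(cohort, adjust_age = FALSE) {
  X <- biomarkers(cohort)
  if (nrow(X) < 3L) stop("at least 3 participants are required")
  if (!adjust_age) {
    V <- stats::cor(X, method = "spearman")
  } else {
    R <- apply(X, 2L, rank)
    ra <- rank(cohort$baseline$age)
    res <- apply(R, 2L, function(col) stats::residuals(stats::lm(col ~ ra)))
    sds <- apply(res, 2L, stats::sd)
    degenerate <- sds < sqrt(.Machine$double.eps) * nrow(X)
    if (any(degenerate)) {
      warning("partial correlation undefined (zero residual variance) for: ",
              paste(colnames(X)[degenerate], collapse = ", "),
              "; reported as 0")
      res[, degenerate] <- 0
    }
    V <- suppressWarnings(stats::cor(res))
    V[degenerate, ] <- 0
    V[, degenerate] <- 0
    diag(V) <- 1
  }
  structure(list(values = V, adjusted_for_age = adjust_age),
            class = "correlation_matrix")
}

#' Tabulate disease-count strata
#'
#' Descriptive stratification of a cohort by the baseline number of chronic
#' diseases into the conventional bands 0-1, 2-3, 4-5 and 6+, with counts and
#' percentages of the total.
#'
#' @param counts integer vector of per-participant disease counts.
#' @return data.frame with columns `stratum`, `n`, `pct` (percent of total,
#'   one decimal).
#' @export
disease_count_strata <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  band <- cut(counts, breaks = c(-Inf, 1, 3, 5, Inf),
              labels = c("0-1", "2-3", "4-5", "6+"))
  n <- as.integer(table(band))
  data.frame(stratum = levels(band), n = n,
             pct = round(100 * n / length(counts), 1))
}
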