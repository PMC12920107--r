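# Fixture builders shared across the suite. Everything is generated in code;
# values are kept simple so delimited-text round trips are exact.

# tiny hand-sized cohort: n participants, B biomarkers, D diseases, visits at
# 0/5/10 years with counts consistent with the baseline indicators
tiny_cohort <- function(n = 10, B = 3, D = 4, seed = 42) {
  set.seed(seed)
  ids <- sprintf("id%02d", seq_len(n))
  baseline <- data.frame(participant_id = ids,
                         age = round(runif(n, 60, 90), 1),
                         sex = as.numeric(rbinom(n, 1, 0.5)),
                         education = as.numeric(rbinom(n, 1, 0.8)),
                         stringsAsFactors = FALSE)
  bm <- sprintf("bm%d", seq_len(B))
  dz <- sprintf("dz%d", seq_len(D))
  baseline[bm] <- round(matrix(rnorm(n * B, 10, 2), n), 3)
  baseline[dz] <- matrix(rbinom(n * D, 1, 0.4), n)
  base_count <- rowSums(baseline[dz])
  visits <- data.frame(participant_id = rep(ids, each = 3),
                       time_years = rep(c(0, 5, 10), n),
                       disease_count = as.vector(vapply(base_count, function(b)
                         cummax(c(b, b + rbinom(1, 2, 0.5), b + rbinom(1, 3, 0.5))),
                         numeric(3))),
                       stringsAsFactors = FALSE)
  cohort_table(baseline, visits, bm, dz)
}

# minimal generator config used when a full preset would be overkill
small_config <- function(n = 300, K = 2, D = 8, B = 4, seed = 1, ...) {
  high <- 0.7; low <- 0.1
  P <- matrix(low, K, D)
  for (k in seq_len(K)) P[k, ((k - 1) * (D %/% K) + 1):(k * (D %/% K))] <- high
  generator_config(n_participants = n,
                   class_proportions = rep(1 / K, K),
                   item_probs = P,
                   biomarker_class_effects = matrix(0, K, B),
                   biomarker_corr = diag(B),
                   slope_effects = numeric(B),
                   seed = seed, ...)
}

# long visits table with linear trajectories; noise_sd = 1e-5 keeps the REML
# fit numerically stable while staying far below the oracles' tolerances
linear_visits <- function(n = 150, tv = c(0, 3, 6, 9, 12, 15), seed = 9,
                          slope_mean = 0.1, slope_sd = 0.08, noise_sd = 1e-5) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n))
  b <- rnorm(n, slope_mean, slope_sd)
  a <- rpois(n, 3)
  list(data = data.frame(
    participant_id = rep(ids, each = length(tv)),
    time_years = rep(tv, n),
    disease_count = rep(a, each = length(tv)) + rep(b, each = length(tv)) * rep(tv, n) +
      rnorm(n * length(tv), 0, noise_sd),
    age = rep(runif(n, 60, 90), each = length(tv)),
    sex = rep(rbinom(n, 1, 0.5), each = length(tv)),
    education = rep(rbinom(n, 1, 0.8), each = length(tv)),
    stringsAsFactors = FALSE),
    ids = ids, slopes = b)
}

# map fitted latent classes onto planted classes: perm[k] is the fitted class
# matching true class k
true_class_map <- function(true_item_probs, fitted_rho) {
  multimorbid:::match_classes(true_item_probs, fitted_rho)
}
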