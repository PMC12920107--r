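# Internal numerical and bookkeeping helpers.

# Row-wise log-sum-exp of a matrix, guarded against -Inf rows.
logsumexp_rows <- function(L) {
  m <- apply(L, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(L - m)))
}

# Deterministic child seed derived from a parent seed and a stage index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 31 + 1009 * k) %% 2147483629)
}

# Stable hash of an arbitrary configuration list (JSON-serialized, md5).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean of the nonzero entries; 0 when all entries are zero (pooling rule
# for penalized coefficients across pseudo-class draws)
mean_nonzero <- function(x) {
  nz <- x[x != 0]
  if (length(nz) == 0L) 0 else mean(nz)
}
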