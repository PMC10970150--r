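# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All permutation/bootstrap functions funnel their seed through here so a
# fixed seed gives reproducible results without disturbing the session RNG.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# derive a stream of child seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max - 1L, n))
}

# permutation p-value, (#extreme + 1) / (n_perm + 1) convention
perm_pvalue <- function(perm_stats, observed) {
  perm_stats <- perm_stats[!is.na(perm_stats)]
  (sum(perm_stats >= observed) + 1) / (length(perm_stats) + 1)
}

as_matrix_checked <- function(d, what = "distance matrix") {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop(what, " is not square", call. = FALSE)
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) {
    stop(what, " is not symmetric", call. = FALSE)
  }
  m
}
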