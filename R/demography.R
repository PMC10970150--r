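# --- basic summaries ---------------------------------------------------------

#' Number of segregating sites
#'
#' Counts polymorphic sites on the complete-deletion sites of an alignment.
#'
#' @param a a `cp_alignment`.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(a) {
  a <- clean_alignment(a)
  sum(apply(a$seq, 2L, function(col) length(unique(col)) > 1L))
}

#' Mean number of pairwise differences
#'
#' @param a a `cp_alignment` with at least two sequences.
#' @return Average difference count over all unordered pairs (k-hat).
#' @export
mean_pairwise_differences <- function(a) {
  if (n_sequences(a) < 2L) stop("need at least two sequences", call. = FALSE)
  a <- clean_alignment(a)
  d <- pairwise_difference_matrix(a)
  mean(d[lower.tri(d)])
}

# Tajima (1989) normalising constants
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Contrasts the mean pairwise difference estimate of theta with the
#' segregating-sites estimate; negative values indicate an excess of rare
#' variants, as after a recent expansion. Returns NA for monomorphic data
#' (S = 0), where the statistic is undefined.
#'
#' @param a a `cp_alignment` (n >= 2; n >= 4 recommended).
#' @return Tajima's D, or NA if there is no polymorphism.
#' @export
tajimas_d <- function(a) {
  n <- n_sequences(a)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  a <- clean_alignment(a)
  S <- segregating_sites(a)
  if (S == 0L) return(NA_real_)
  k_hat <- mean_pairwise_differences(a)
  cst <- tajima_constants(n)
  (k_hat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# --- Ewens sampling distribution and Fu's Fs ---------------------------------

#' Ewens distribution of the number of haplotypes
#'
#' Probability mass function of the number of distinct haplotypes K in a
#' sample of size n under the Ewens sampling formula,
#' `P(K = k) = |s(n, k)| theta^k / (theta)_n`, with unsigned Stirling
#' numbers of the first kind and the rising factorial `(theta)_n`.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (> 0).
#' @return Numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewens_k_pmf <- function(n, theta) {
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  # unsigned Stirling numbers |s(n, k)| via c(n+1,k) = n c(n,k) + c(n,k-1),
  # in log space to stay finite for large n
  log_s <- c(0) # n = 1: |s(1,1)| = 1
  if (n > 1L) {
    for (m in seq_len(n - 1L)) { # build row m+1 from row m
      prev <- log_s
      log_s <- numeric(m + 1L)
      log_s[1L] <- log(m) + prev[1L] # k = 1
      if (m > 1L) {
        for (k in 2:m) {
          log_s[k] <- log_add(log(m) + prev[k], prev[k - 1L])
        }
      }
      log_s[m + 1L] <- prev[m] # k = m + 1 (coefficient 1)
    }
  }
  k <- seq_len(n)
  log_rising <- sum(log(theta + 0:(n - 1L)))
  p <- exp(log_s + k * log(theta) - log_rising)
  p / sum(p)
}

log_add <- function(x, y) {
  m <- pmax(x, y)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(x, y) - m)))
}

#' Fu's Fs
#'
#' `Fs = ln(S'/(1 - S'))` where `S' = P(K >= k_obs | theta = k_hat)` under
#' the Ewens sampling distribution: the probability of observing at least as
#' many haplotypes as sampled, given the pairwise-difference estimate of
#' theta. Strongly negative values indicate a haplotype excess, as after an
#' expansion. Returns NA when the sample is monomorphic (k_hat = 0).
#'
#' @param a a `cp_alignment`.
#' @param s optional sample table; if supplied, haplotype count is taken from
#'   the cleaned alignment regardless.
#' @return Fu's Fs, or NA for monomorphic data.
#' @export
fu_fs <- function(a, s = NULL) {
  n <- n_sequences(a)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  a <- clean_alignment(a)
  k_hat <- mean_pairwise_differences(a)
  if (k_hat == 0) return(NA_real_)
  k_obs <- length(unique(alignment_strings(a)))
  fs_from_summaries(n, k_obs, k_hat)
}

# Fs from (n, observed K, theta-hat); shared with the null simulations
fs_from_summaries <- function(n, k_obs, theta) {
  if (theta <= 0) return(NA_real_)
  pmf <- ewens_k_pmf(n, theta)
  s_prime <- sum(pmf[k_obs:n])
  s_prime <- min(max(s_prime, 1e-300), 1 - 1e-15)
  log(s_prime / (1 - s_prime))
}

# --- coalescent null simulations for p-values --------------------------------

# One neutral constant-size coalescent sample of size n with mutation
# parameter theta (per sequence, theta = 2 N mu); infinite-sites mutations
# are dropped on branches. Returns S, k_hat and the number of distinct
# haplotypes K, without materialising sequences.
sim_neutral_summaries <- function(n, theta) {
  # active lineages: list of descendant leaf index vectors
  desc <- as.list(seq_len(n))
  hap_key <- character(n) # accumulating mutated-branch signature per leaf
  S <- 0L
  k_sum <- 0
  branch_id <- 0L
  k <- n
  while (k > 1L) {
    dt <- stats::rexp(1, rate = k * (k - 1) / 2)
    # mutations on each lineage during dt: rate theta/2 per lineage
    nm <- stats::rpois(k, theta / 2 * dt)
    for (l in which(nm > 0L)) {
      c_l <- length(desc[[l]])
      S <- S + nm[l]
      k_sum <- k_sum + nm[l] * c_l * (n - c_l)
      branch_id <- branch_id + 1L
      hap_key[desc[[l]]] <- paste0(hap_key[desc[[l]]], ",", branch_id, ".", nm[l])
    }
    pair <- sample.int(k, 2L)
    desc[[pair[1L]]] <- c(desc[[pair[1L]]], desc[[pair[2L]]])
    desc[[pair[2L]]] <- NULL
    k <- k - 1L
  }
  list(S = S, k_hat = k_sum / (n * (n - 1) / 2),
       K = length(unique(hap_key)))
}

#' Coalescent p-values for neutrality statistics
#'
#' Simulates constant-size neutral panmictic samples conditioned on the
#' observed theta estimate (k-hat, the mean pairwise difference), recomputes
#' the statistic on each replicate, and reports the lower-tail p-value
#' `P(stat_sim <= stat_obs)` — the expansion direction — or a two-sided
#' version.
#'
#' @param stat `"D"` (Tajima) or `"Fs"` (Fu).
#' @param observed the observed statistic.
#' @param n sample size.
#' @param theta mutation parameter for the null (use the observed k-hat).
#' @param n_reps number of coalescent replicates (at least 1000).
#' @param seed integer seed.
#' @param tail `"lower"` (default) or `"two-sided"`.
#' @return p-value in `[0, 1]`.
#' @export
neutrality_p_value <- function(stat = c("D", "Fs"), observed, n, theta,
                               n_reps = 1000, seed = NULL,
                               tail = c("lower", "two-sided")) {
  stat <- match.arg(stat)
  tail <- match.arg(tail)
  if (is.na(observed)) return(1)
  if (n_reps < 1000) stop("n_reps must be at least 1000", call. = FALSE)
  if (theta <= 0) return(1)
  cst <- if (stat == "D") tajima_constants(n)
  sims <- with_rng(seed, vapply(seq_len(n_reps), function(i) {
    sm <- sim_neutral_summaries(n, theta)
    if (stat == "D") {
      if (sm$S == 0L) return(NA_real_)
      (sm$k_hat - sm$S / cst$a1) /
        sqrt(cst$e1 * sm$S + cst$e2 * sm$S * (sm$S - 1))
    } else {
      fs_from_summaries(n, sm$K, sm$k_hat)
    }
  }, numeric(1)))
  sims <- sims[!is.na(sims)]
  if (length(sims) == 0L) return(1)
  p_low <- mean(sims <= observed)
  if (tail == "lower") p_low else min(1, 2 * min(p_low, mean(sims >= observed)))
}

#' Neutrality tests for one population
#'
#' Computes Tajima's D and Fu's Fs with coalescent p-values. Monomorphic
#' samples have undefined statistics; they are reported as NA with p = 1
#' (report writers render them as `0 (1)`).
#'
#' @param a a `cp_alignment` for one population.
#' @param n_reps coalescent replicates for the p-values.
#' @param seed integer seed.
#' @return List with `n`, `S`, `k_hat`, `tajima_d`, `p_d`, `fu_fs`, `p_fs`.
#' @export
neutrality_tests <- function(a, n_reps = 1000, seed = NULL) {
  a <- clean_alignment(a)
  n <- n_sequences(a)
  S <- segregating_sites(a)
  k_hat <- if (n >= 2L) mean_pairwise_differences(a) else 0
  D <- if (n >= 2L) tajimas_d(a) else NA_real_
  Fs <- if (n >= 2L) fu_fs(a) else NA_real_
  seeds <- derive_seeds(seed, 2L)
  p_d <- if (is.na(D)) 1 else
    neutrality_p_value("D", D, n, k_hat, n_reps, seeds[1L])
  p_fs <- if (is.na(Fs)) 1 else
    neutrality_p_value("Fs", Fs, n, k_hat, n_reps, seeds[2L])
  list(n = n, S = S, k_hat = k_hat,
       tajima_d = D, p_d = p_d, fu_fs = Fs, p_fs = p_fs)
}
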