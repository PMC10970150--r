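# Mismatch-distribution analysis under the sudden-expansion model.
#
# The demographic model: a panmictic population of scaled size theta0 = 2*N1*mu
# grew instantaneously to theta1 = 2*N2*mu at a time tau (in mutational units
# 2*u*t) before sampling. The distribution of pairwise difference counts is
# geometric at stationarity and develops a travelling unimodal wave near tau
# after a strong expansion.

#' Observed mismatch distribution
#'
#' Relative frequency of each pairwise difference count over all unordered
#' sequence pairs, on support `0..max(differences)`.
#'
#' @param a a `cp_alignment` with at least two sequences.
#' @return Numeric vector of relative frequencies named `0, 1, ...`; sums
#'   to 1.
#' @export
mismatch_observed <- function(a) {
  if (n_sequences(a) < 2L) stop("need at least two sequences", call. = FALSE)
  a <- clean_alignment(a)
  d <- pairwise_difference_matrix(a)
  dd <- d[lower.tri(d)]
  spec <- tabulate(dd + 1L, nbins = max(dd) + 1L) / length(dd)
  names(spec) <- 0:(length(spec) - 1L)
  spec
}

#' Expected mismatch distribution under sudden expansion
#'
#' Exact expected pairwise-difference distribution for the two-epoch model:
#' the stationary geometric term `theta^i/(1+theta)^(i+1)` weighted by the
#' probability of coalescing in the current (size theta1) epoch, plus the
#' transient term for pairs whose ancestry predates the expansion — a
#' Poisson(tau) mutation layer convolved with the pre-expansion geometric
#' (size theta0). At `tau = 0` this reduces to the stationary spectrum for
#' theta0; for strong growth it approaches the classic
#' sudden-expansion wave peaked near tau. The spectrum is truncated at
#' `d_max` and renormalised.
#'
#' @param theta0 pre-expansion scaled mutation parameter (>= 0).
#' @param theta1 post-expansion scaled mutation parameter (>= 0).
#' @param tau time since expansion in mutational units (>= 0).
#' @param d_max largest difference count of the support.
#' @return Numeric vector over `0..d_max`, summing to 1.
#' @export
expansion_expected_spectrum <- function(theta0, theta1, tau, d_max) {
  if (any(c(theta0, theta1, tau) < 0)) {
    stop("parameters must be non-negative", call. = FALSE)
  }
  i <- 0:d_max
  geom <- function(theta) {
    if (theta == 0) return(as.numeric(i == 0L))
    exp(i * log(theta) - (i + 1) * log1p(theta))
  }
  if (tau == 0) {
    f <- geom(theta0)
  } else {
    # recent epoch: coalescence before tau (regularised incomplete gamma)
    recent <- if (theta1 == 0) as.numeric(i == 0L) else
      geom(theta1) * stats::pgamma(tau * (1 + 1 / theta1), shape = i + 1)
    p_old <- if (theta1 == 0) 0 else exp(-tau / theta1)
    # ancestral epoch: Poisson(tau) differences accrued since the expansion
    # plus a geometric(theta0) number from the pre-expansion coalescent
    g0 <- geom(theta0)
    pois <- stats::dpois(i, tau)
    old <- vapply(i, function(ii) {
      j <- 0:ii
      sum(pois[ii - j + 1L] * g0[j + 1L])
    }, numeric(1))
    f <- recent + p_old * old
  }
  f <- pmax(f, 0)
  if (sum(f) == 0) f[1L] <- 1 else f <- f / sum(f)
  names(f) <- i
  f
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the mismatch spectrum, with the
#' spectrum padded by zero classes at both ends; smooth unimodal spectra
#' (expansion) give small values, sawtooth spectra (stationarity) large
#' ones. A point mass at zero gives 2; a uniform spectrum over `0..d` gives
#' `2/(d+1)^2`.
#'
#' @param spectrum numeric vector of relative frequencies over `0..d`.
#' @return The raggedness index.
#' @export
raggedness <- function(spectrum) {
  x <- c(0, as.numeric(spectrum), 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch spectrum
#'
#' Minimises the sum of squared deviations
#' `SSD = sum((obs_i - exp_i)^2)` over (theta0, theta1, tau) by a coarse
#' grid search refined with bounded quasi-Newton and Nelder-Mead passes.
#' Bounds: theta0 in `[0, 100]`, theta1 in `[theta0, 1e4]`, tau in
#' `[0, 100]`.
#'
#' @param observed observed mismatch spectrum (relative frequencies over
#'   `0..d_max`), e.g. from [mismatch_observed()].
#' @return Object of class `mismatch_fit`: list with `theta0`, `theta1`,
#'   `tau`, `ssd`, `raggedness`, `observed`, `expected`, `converged`.
#' @export
fit_expansion <- function(observed) {
  obs <- as.numeric(observed)
  if (length(obs) < 1L || any(obs < 0) || sum(obs) == 0) {
    stop("degenerate spectrum", call. = FALSE)
  }
  obs <- obs / sum(obs)
  d_max <- length(obs) - 1L
  ssd_of <- function(par) { # par = (theta0, delta = theta1 - theta0, tau)
    f <- expansion_expected_spectrum(par[1L], par[1L] + par[2L], par[3L], d_max)
    sum((obs - f)^2)
  }
  mean_d <- sum(obs * (0:d_max))
  grid0 <- c(0, 0.1, 0.5, 1, 2, 5, 10, 25, 50, 100)
  grid_t1 <- c(0, 0.5, 1, 5, 10, 50, 100, 500, 1000, 5000, 10000)
  grid_tau <- unique(pmin(c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 100,
                            mean_d, mean_d / 2), 100))
  best <- NULL
  best_val <- Inf
  for (t0 in grid0) for (t1 in grid_t1[grid_t1 >= t0]) for (tu in grid_tau) {
    v <- ssd_of(c(t0, t1 - t0, tu))
    if (v < best_val) {
      best_val <- v
      best <- c(t0, t1 - t0, tu)
    }
  }
  lo <- c(0, 0, 0)
  hi <- c(100, 1e4, 100)
  refined <- tryCatch(
    stats::optim(best, ssd_of, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(factr = 1e4, maxit = 500)),
    error = function(e) list(par = best, value = best_val)
  )
  start <- if (refined$value <= best_val) refined$par else best
  polished <- tryCatch({
    o <- stats::optim(start, function(p) ssd_of(pmin(pmax(p, lo), hi)),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    o$par <- pmin(pmax(o$par, lo), hi)
    o
  }, error = function(e) NULL)
  candidates <- list(list(par = best, value = best_val), refined, polished)
  candidates <- Filter(Negate(is.null), candidates)
  vals <- vapply(candidates, `[[`, numeric(1), "value")
  par <- candidates[[which.min(vals)]]$par
  val <- min(vals)
  converged <- !is.null(polished)
  if (!converged) warning("optimisation failed; reporting best grid point")
  expected <- expansion_expected_spectrum(par[1L], par[1L] + par[2L],
                                          par[3L], d_max)
  structure(
    list(theta0 = par[1L], theta1 = par[1L] + par[2L], tau = par[3L],
         ssd = val, raggedness = raggedness(obs),
         observed = stats::setNames(obs, 0:d_max), expected = expected,
         converged = converged),
    class = "mismatch_fit"
  )
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("Sudden-expansion fit: theta0 = %.4g, theta1 = %.4g, tau = %.4g\n",
              x$theta0, x$theta1, x$tau))
  cat(sprintf("  SSD = %.4g, raggedness = %.4g\n", x$ssd, x$raggedness))
  invisible(x)
}

#' Parametric bootstrap tests for the mismatch fit
#'
#' Simulates coalescent samples of the original size under the fitted
#' expansion model, refits each, and reports
#' `p = P(bootstrap statistic >= observed)` for the SSD and raggedness:
#' small p means the data fit the expansion model worse than the model's own
#' sampling variation allows.
#'
#' @param fit a `mismatch_fit`.
#' @param n number of sequences in the original sample.
#' @param L sequence length used when simulating bootstrap samples.
#' @param n_reps bootstrap replicates (at least 100).
#' @param seed integer seed.
#' @return List with `p_ssd`, `p_rag` and the bootstrap statistic matrix.
#' @export
bootstrap_mismatch_tests <- function(fit, n, L = 600, n_reps = 100,
                                     seed = NULL) {
  if (n_reps < 100) stop("n_reps must be at least 100", call. = FALSE)
  if (n < 2L || (fit$theta1 == 0 && fit$theta0 == 0 && fit$tau == 0)) {
    return(list(p_ssd = 1, p_rag = 1, boot = NULL))
  }
  seeds <- derive_seeds(seed, n_reps)
  boot <- t(vapply(seq_len(n_reps), function(b) {
    sim <- simulate_expansion_sample(fit$theta0, fit$theta1, fit$tau,
                                     n = n, L = L, seed = seeds[b])
    bf <- fit_expansion(mismatch_observed(sim))
    c(ssd = bf$ssd, rag = raggedness(bf$observed))
  }, numeric(2)))
  list(
    p_ssd = (sum(boot[, "ssd"] >= fit$ssd) + 1) / (n_reps + 1),
    p_rag = (sum(boot[, "rag"] >= fit$raggedness) + 1) / (n_reps + 1),
    boot = boot
  )
}
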