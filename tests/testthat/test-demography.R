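test_that("Tajima's D matches an independently coded textbook oracle", {
  toys <- list(
    c("AAAA", "AAAT", "AATT", "TAAA", "AAAA"),
    c("ACGTACGT", "ACGTACGA", "ACGTACGA", "TCGTACGT", "ACGAACGT", "ACGTACGT"),
    c("AAAAA", "AAAAT", "AAATT", "AATTT", "ATTTT", "TTTTT", "AAAAA", "AAAAA")
  )
  for (seqs in toys) {
    a <- new_alignment(seqs, sprintf("s%d", seq_along(seqs)))
    expect_equal(tajimas_d(a), oracle_tajimas_d(seqs))
  }
})

test_that("monomorphic samples yield NA for both neutrality statistics", {
  a <- new_alignment(rep("ACGTACGT", 6), sprintf("s%d", 1:6))
  expect_true(is.na(tajimas_d(a)))
  expect_true(is.na(fu_fs(a)))
  expect_equal(neutrality_p_value("D", NA, 6, 1, 1000, 1), 1)
})

test_that("an excess of singletons drives Tajima's D negative", {
  # star-like data: every sequence carries its own private mutation
  n <- 10
  L <- 40
  base <- strsplit(paste(rep("A", L), collapse = ""), "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    s[i] <- "T"
    paste(s, collapse = "")
  }, character(1))
  a <- new_alignment(seqs, sprintf("s%02d", 1:n))
  expect_lt(tajimas_d(a), 0)
})

test_that("the Ewens haplotype-number pmf normalises and matches the CRP oracle", {
  for (n in c(2, 5, 10, 20)) {
    for (theta in c(0.3, 1, 2.7, 10)) {
      pmf <- ewens_k_pmf(n, theta)
      expect_equal(sum(pmf), 1)
      expect_equal(pmf, oracle_ewens_pmf(n, theta), tolerance = 1e-12)
    }
  }
  expect_error(ewens_k_pmf(5, 0), "positive")
})

test_that("Fu's Fs matches enumeration on small samples and detects haplotype excess", {
  toys <- list(
    c("AAAA", "AAAT", "AATT", "TAAA", "AAAA"),
    c("ACGT", "ACGA", "TCGT", "ACAT", "GCGT", "ACCT"),
    c("AAAAAA", "AAAAAT", "AAAAAT", "AAAATT")
  )
  for (seqs in toys) {
    a <- new_alignment(seqs, sprintf("s%d", seq_along(seqs)))
    expect_equal(fu_fs(a), oracle_fu_fs(seqs))
  }
  # many unique haplotypes at moderate k_hat: strongly negative
  n <- 12
  base <- rep("A", 30)
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    s[i] <- "T"
    paste(s, collapse = "")
  }, character(1))
  a <- new_alignment(seqs, sprintf("s%02d", 1:n))
  expect_lt(fu_fs(a), -3)
})

test_that("coalescent neutrality p-values behave like a null CDF", {
  # monotone in the observed value, near 0/1 at the extremes, mid for D ~ 0
  p_lo <- neutrality_p_value("D", -3, n = 15, theta = 3, n_reps = 1000,
                             seed = 11)
  p_mid <- neutrality_p_value("D", 0, n = 15, theta = 3, n_reps = 1000,
                              seed = 11)
  p_hi <- neutrality_p_value("D", 3, n = 15, theta = 3, n_reps = 1000,
                             seed = 11)
  expect_lt(p_lo, p_mid)
  expect_lt(p_mid, p_hi)
  expect_lt(p_lo, 0.05)
  expect_gt(p_hi, 0.95)
  expect_gt(p_mid, 0.3)
  expect_lt(p_mid, 0.8)
  expect_identical(
    neutrality_p_value("Fs", -2, 10, 2, 1000, seed = 5),
    neutrality_p_value("Fs", -2, 10, 2, 1000, seed = 5)
  )
  expect_error(neutrality_p_value("D", 0, 10, 2, n_reps = 100), "1000")
})

test_that("expansion samples yield negative D and Fs in most replicates", {
  signs <- sapply(1:12, function(i) {
    a <- simulate_expansion_sample(0.5, 60, 4, n = 20, L = 500,
                                   seed = 400 + i)
    c(d = tajimas_d(a), fs = fu_fs(a))
  })
  expect_gt(mean(signs["d", ] < 0, na.rm = TRUE), 0.5)
  expect_gt(mean(signs["fs", ] < 0, na.rm = TRUE), 0.5)
})

test_that("observed mismatch spectra enumerate pairwise differences", {
  mono <- new_alignment(rep("ACGT", 5), sprintf("s%d", 1:5))
  sp <- mismatch_observed(mono)
  expect_equal(unname(sp), 1)
  expect_equal(names(sp), "0")

  # two haplotypes at distance 3, counts (4, 2): mass 8/15 at 3
  a <- new_alignment(c(rep("AAAAAA", 4), rep("TTTAAA", 2)),
                     sprintf("s%d", 1:6))
  sp2 <- mismatch_observed(a)
  expect_equal(unname(sp2["3"]), 8 / 15)
  expect_equal(unname(sp2["0"]), 7 / 15)
  expect_equal(sum(sp2), 1)

  set.seed(31)
  r <- random_alignment(8, 25)
  d <- oracle_distance_matrix(r)
  dd <- d[lower.tri(d)]
  spr <- mismatch_observed(r)
  expect_equal(unname(spr[as.character(max(dd))]),
               sum(dd == max(dd)) / length(dd))
  expect_equal(sum(spr), 1)
})

test_that("the expected expansion spectrum has its limiting shapes", {
  # stationary limit: geometric
  th <- 2.5
  sp <- expansion_expected_spectrum(th, th, 0, 20)
  i <- 0:20
  geo <- th^i / (1 + th)^(i + 1)
  expect_equal(unname(sp), geo / sum(geo))
  # always a distribution
  expect_equal(sum(expansion_expected_spectrum(1, 100, 5, 40)), 1)
  expect_equal(sum(expansion_expected_spectrum(0, 0, 0, 5)), 1)
  # strong expansion: unimodal Poisson-like wave near tau
  sp2 <- expansion_expected_spectrum(0, 5000, 12, 50)
  expect_lte(abs(unname(which.max(sp2)) - 1 - 12), 1)
  # compare transient shape against direct Poisson mixture for theta1 -> inf
  pois <- dpois(0:50, 12)
  expect_gt(cor(sp2, pois / sum(pois)), 0.99)
  expect_error(expansion_expected_spectrum(-1, 1, 1, 5), "non-negative")
})

test_that("raggedness follows its closed forms and a direct-sum oracle", {
  expect_equal(raggedness(1), 2)
  for (d in c(1, 3, 9)) {
    expect_equal(raggedness(rep(1 / (d + 1), d + 1)), 2 / (d + 1)^2)
  }
  set.seed(37)
  x <- runif(8)
  x <- x / sum(x)
  padded <- c(0, x, 0)
  oracle <- sum((padded[-1] - padded[-length(padded)])^2)
  expect_equal(raggedness(x), oracle)
})

test_that("the expansion fit recovers its own expected spectrum exactly", {
  obs <- expansion_expected_spectrum(1, 100, 5, 30)
  fit <- fit_expansion(obs)
  expect_lt(fit$ssd, 1e-8)
  expect_equal(fit$theta0, 1, tolerance = 0.05)
  expect_equal(fit$theta1, 100, tolerance = 0.1)
  expect_equal(fit$tau, 5, tolerance = 0.05)
})

test_that("a point mass at zero drives the fit to the stationary boundary", {
  fit <- fit_expansion(c(1))
  expect_lt(fit$ssd, 1e-6)
  expect_lt(fit$theta0, 0.01)
  expect_error(fit_expansion(numeric(0)), "degenerate")
})

test_that("bootstrap mismatch tests are calibrated for model-generated data", {
  sim <- simulate_expansion_sample(1, 80, 5, n = 20, L = 500, seed = 61)
  fit <- fit_expansion(mismatch_observed(sim))
  bt <- bootstrap_mismatch_tests(fit, n = 20, L = 500, n_reps = 100, seed = 62)
  expect_gte(bt$p_ssd, 0)
  expect_lte(bt$p_ssd, 1)
  expect_gt(bt$p_ssd, 0.05) # data from the model should not be rejected
  bt2 <- bootstrap_mismatch_tests(fit, n = 20, L = 500, n_reps = 100, seed = 62)
  expect_identical(bt2$p_ssd, bt$p_ssd)
  expect_identical(bt2$p_rag, bt$p_rag)
})
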