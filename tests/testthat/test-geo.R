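test_that("haversine distances match closed-form great circles", {
  expect_equal(haversine_km(110, 25, 110, 25), 0)
  expect_equal(haversine_km(0, 0, 180, 0), pi * 6371, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-6)
})

test_that("haversine is symmetric and satisfies the triangle inequality", {
  set.seed(3)
  for (i in 1:10) {
    p <- cbind(runif(3, -180, 180), runif(3, -60, 60))
    d12 <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d21 <- haversine_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d13 <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d23 <- haversine_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_equal(d12, d21)
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("population distance matrix uses one coordinate per population", {
  s <- data.frame(sample_id = sprintf("s%d", 1:4),
                  population = c("A", "A", "B", "B"),
                  longitude = c(100, 100, 103, 103),
                  latitude = c(25, 25, 25, 25), elevation = 1)
  m <- geographic_distance_matrix(s)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["A", "B"], haversine_km(100, 25, 103, 25))
  expect_equal(diag(m), c(A = 0, B = 0))
})

test_that("Mantel r on identical matrices is 1 and equals plain Pearson", {
  set.seed(7)
  m <- matrix(runif(36), 6, 6)
  m <- m + t(m)
  diag(m) <- 0
  r <- mantel_test(m, m, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_lte(r$p_value, 0.05)

  m2 <- matrix(runif(36), 6, 6)
  m2 <- m2 + t(m2)
  diag(m2) <- 0
  r2 <- mantel_test(m, m2, n_perm = 99, seed = 1)
  expect_equal(r2$r, cor(m[lower.tri(m)], m2[lower.tri(m2)]))
  expect_identical(mantel_test(m, m2, n_perm = 99, seed = 1)$p_value,
                   r2$p_value)
  expect_error(mantel_test(m, m2, n_perm = 50), "at least 99")
})

test_that("Mantel agrees with vegan on statistic and null behaviour", {
  skip_if_not_installed("vegan")
  set.seed(15)
  m1 <- as.matrix(dist(runif(8)))
  m2 <- as.matrix(dist(runif(8)))
  ours <- mantel_test(m1, m2, n_perm = 999, seed = 4)
  ref <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic))
  expect_lt(abs(ours$p_value - ref$signif), 0.12)
})

test_that("null Mantel p-values are roughly uniform", {
  set.seed(19)
  ps <- replicate(60, {
    m1 <- as.matrix(dist(runif(7)))
    m2 <- as.matrix(dist(runif(7)))
    mantel_test(m1, m2, n_perm = 99)$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("IBD regression recovers an exact log-linear relationship", {
  pops <- paste0("P", 1:6)
  km <- as.matrix(dist(cbind(seq(0, 500, length.out = 6), 0))) + 0
  km[km == 0] <- 0
  km <- km + 1 # avoid zero off-diagonal distances
  diag(km) <- 0
  dimnames(km) <- list(pops, pops)
  a <- 0.02
  b <- 0.05
  y <- a + b * log(km)
  fst <- y / (1 + y) # inverse of the transform
  diag(fst) <- 0
  dimnames(fst) <- list(pops, pops)
  fit <- ibd_regression(fst, km, n_perm = 99, seed = 2)
  expect_equal(fit$slope, b, tolerance = 1e-9)
  expect_equal(fit$intercept, a, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_pairs, 15)
  expect_lte(fit$p_mantel, 0.05)
})

test_that("IBD OLS matches closed-form normal equations on a 4-population toy", {
  pops <- paste0("P", 1:4)
  km <- matrix(0, 4, 4, dimnames = list(pops, pops))
  km[lower.tri(km)] <- c(10, 20, 40, 80, 160, 320)
  km <- km + t(km)
  fst <- matrix(0, 4, 4, dimnames = list(pops, pops))
  fst[lower.tri(fst)] <- c(0.05, 0.1, 0.12, 0.2, 0.22, 0.3)
  fst <- fst + t(fst)
  fit <- ibd_regression(fst, km, n_perm = 99, seed = 5)
  x <- log(km[lower.tri(km)])
  y <- fst[lower.tri(fst)] / (1 - fst[lower.tri(fst)])
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hat <- mean(y) - b_hat * mean(x)
  expect_equal(fit$slope, b_hat)
  expect_equal(fit$intercept, a_hat)
  # relabelling populations leaves the fit unchanged
  ix <- c(3, 1, 4, 2)
  fit2 <- ibd_regression(fst[ix, ix], km[ix, ix], n_perm = 99, seed = 5)
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$r_squared, fit$r_squared)
})

test_that("IBD excludes degenerate pairs and reports their count", {
  pops <- paste0("P", 1:4)
  km <- matrix(0, 4, 4, dimnames = list(pops, pops))
  km[lower.tri(km)] <- c(0, 5, 8, 12, 20, 33) # first pair: log undefined
  km <- km + t(km)
  fst <- matrix(0.2, 4, 4, dimnames = list(pops, pops))
  fst[3, 4] <- fst[4, 3] <- 1 # excluded: transform undefined
  fst[1, 3] <- fst[3, 1] <- -0.05 # clamped, kept
  diag(fst) <- 0
  fit <- ibd_regression(fst, km, n_perm = 99, seed = 1)
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$n_pairs, 4)
})

test_that("slope p-values are near-uniform when there is no IBD", {
  set.seed(23)
  ps <- replicate(80, {
    pops <- paste0("P", 1:5)
    km <- as.matrix(dist(cbind(runif(5, 0, 800), runif(5, 0, 800)))) + 1
    diag(km) <- 0
    dimnames(km) <- list(pops, pops)
    fst <- matrix(0, 5, 5, dimnames = list(pops, pops))
    fst[lower.tri(fst)] <- runif(10, 0.05, 0.4)
    fst <- fst + t(fst)
    ibd_regression(fst, km, n_perm = 99)$p_slope
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("diversity-elevation correlation reproduces cor.test exactly", {
  set.seed(27)
  pops <- paste0("P", 1:8)
  h <- runif(8)
  elev <- runif(8, 300, 1800)
  s <- data.frame(sample_id = pops, population = pops, longitude = 1,
                  latitude = 1, elevation = elev)
  summaries <- data.frame(population = pops, h = h)
  res <- diversity_elevation_correlation(summaries, s)
  ref <- cor.test(h, elev)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$n, 8)
  # perfectly linear data
  s2 <- s
  summaries2 <- data.frame(population = pops, h = elev / 2000)
  expect_equal(diversity_elevation_correlation(summaries2, s2)$r, 1)
})
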