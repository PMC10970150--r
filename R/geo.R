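#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over
#' coordinates.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Pairwise geographic distance matrix between populations
#'
#' Uses one coordinate per population (the first sample's longitude and
#' latitude; in a typical survey all samples of a population share the
#' population's coordinates).
#'
#' @param s a sample table (see [read_sample_table()]).
#' @return Symmetric matrix of great-circle distances in km, labelled by
#'   population code.
#' @export
geographic_distance_matrix <- function(s) {
  s <- validate_sample_table(s)
  first <- s[!duplicated(s$population), ]
  P <- nrow(first)
  m <- matrix(0, P, P, dimnames = list(first$population, first$population))
  for (i in seq_len(P - 1)) {
    j <- seq(i + 1, P)
    m[i, j] <- m[j, i] <- haversine_km(first$longitude[i], first$latitude[i],
                                       first$longitude[j], first$latitude[j])
  }
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal entries, with significance from
#' jointly permuting the row/column order of the second matrix. One-sided
#' p-value (correlation at least as large as observed) with the
#' `(extreme + 1)/(n_perm + 1)` convention. Entries that are NA in either
#' matrix are excluded pairwise.
#'
#' @param m1,m2 symmetric matrices over the same labels.
#' @param n_perm number of permutations (at least 99).
#' @param seed integer seed.
#' @return List with `r`, `p_value` and `n` (number of pairs used).
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = NULL) {
  m1 <- as_matrix_checked(m1)
  m2 <- as_matrix_checked(m2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) {
      stop("matrices have different labels", call. = FALSE)
    }
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  lw <- lower.tri(m1)
  x <- m1[lw]
  ok_pairs <- !is.na(x)
  if (stats::sd(x[ok_pairs & !is.na(m2[lw])]) == 0) {
    stop("constant matrix: Mantel r undefined", call. = FALSE)
  }
  r_with <- function(m) {
    y <- m[lw]
    ok <- ok_pairs & !is.na(y)
    suppressWarnings(stats::cor(x[ok], y[ok])) # NA when degenerate
  }
  r_obs <- r_with(m2)
  n <- nrow(m1)
  perm <- with_rng(seed, vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(n)
    r_with(m2[ix, ix])
  }, numeric(1)))
  list(r = r_obs, p_value = perm_pvalue(perm, r_obs),
       n = sum(ok_pairs & !is.na(m2[lw])))
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of the linearised differentiation `Fst/(1 - Fst)`
#' on the natural log of pairwise geographic distance (km), over unordered
#' population pairs. Negative pairwise Fst values are clamped to 0 before
#' the transform; pairs with Fst >= 1, missing Fst, or zero distance are
#' excluded (their count is reported). A Mantel test on the transformed
#' matrices accompanies the parametric slope t-test, since population pairs
#' are not independent.
#'
#' @param pairwise_fst symmetric matrix of pairwise Fst over populations.
#' @param pairwise_km symmetric matrix of geographic distances in km with
#'   the same labels.
#' @param n_perm permutations for the Mantel test.
#' @param seed integer seed for the Mantel permutations.
#' @param clamp_negative clamp negative Fst to 0 before transforming
#'   (default TRUE).
#' @return An object of class `ibd_fit`: list with `intercept`, `slope`,
#'   `r_squared`, `p_slope`, `p_mantel`, `n_pairs`, `n_excluded`, the fitted
#'   `model`, and the pair table `pairs`.
#' @export
ibd_regression <- function(pairwise_fst, pairwise_km, n_perm = 999,
                           seed = NULL, clamp_negative = TRUE) {
  fst <- as_matrix_checked(pairwise_fst, "Fst matrix")
  km <- as_matrix_checked(pairwise_km, "distance matrix")
  if (!setequal(rownames(fst), rownames(km))) {
    stop("Fst and distance matrices have different labels", call. = FALSE)
  }
  km <- km[rownames(fst), rownames(fst)]
  pops <- rownames(fst)
  lw <- which(lower.tri(fst), arr.ind = TRUE)
  f <- fst[lower.tri(fst)]
  d <- km[lower.tri(km)]
  if (clamp_negative) f <- pmax(f, 0)
  usable <- !is.na(f) & f < 1 & d > 0
  n_excl <- sum(!usable)
  if (sum(usable) < 3L) stop("fewer than 3 usable pairs", call. = FALSE)
  y <- f[usable] / (1 - f[usable])
  x <- log(d[usable])
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope_ok <- "x" %in% rownames(sm$coefficients) &&
    !is.na(stats::coef(fit)["x"])
  if (!slope_ok) {
    warning("slope inestimable (constant distances among usable pairs)")
  }
  # Mantel on the transformed matrices (NA out unusable pairs)
  tf <- fst
  tf[] <- NA_real_
  tf[lower.tri(tf)][usable] <- y
  tf <- pmin(tf, t(tf), na.rm = TRUE)
  diag(tf) <- 0
  lkm <- km
  lkm[km <= 0] <- NA_real_
  lkm <- log(lkm)
  diag(lkm) <- 0
  mt <- mantel_test(tf, lkm, n_perm = n_perm, seed = seed)
  pairs <- data.frame(
    pop1 = pops[lw[usable, 2L]], pop2 = pops[lw[usable, 1L]],
    km = d[usable], fst = f[usable], fst_transformed = y,
    stringsAsFactors = FALSE
  )
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = if (slope_ok) unname(stats::coef(fit)["x"]) else NA_real_,
         r_squared = sm$r.squared,
         p_slope = if (slope_ok) sm$coefficients["x", "Pr(>|t|)"] else NA_real_,
         p_mantel = mt$p_value, mantel_r = mt$r,
         n_pairs = sum(usable), n_excluded = n_excl,
         model = fit, pairs = pairs),
    class = "ibd_fit"
  )
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat("Isolation by distance: Fst/(1-Fst) ~ ln(km)\n")
  cat(sprintf("  intercept a = %.4g, slope b = %.4g, R^2 = %.4g\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  slope t-test p = %.3g; Mantel r = %.4g, p = %.3g (%d pairs, %d excluded)\n",
              x$p_slope, x$mantel_r, x$p_mantel, x$n_pairs, x$n_excluded))
  invisible(x)
}

#' Correlation of haplotype diversity with elevation
#'
#' Pearson correlation of the per-population haplotype diversity against
#' population elevation, with the two-sided t-test on n - 2 degrees of
#' freedom.
#'
#' @param summaries a per-population summary data frame with columns
#'   `population` and `h` (e.g. from [population_summary()]; a `Total` row is
#'   ignored), or a numeric vector of diversities named by population.
#' @param s a sample table supplying one elevation per population.
#' @return List with `r`, `p_value` and `n`.
#' @export
diversity_elevation_correlation <- function(summaries, s) {
  s <- validate_sample_table(s)
  if (is.data.frame(summaries)) {
    summaries <- summaries[summaries$population != "Total", ]
    hvals <- stats::setNames(summaries$h, summaries$population)
  } else {
    hvals <- summaries
  }
  first <- s[!duplicated(s$population), ]
  elev <- stats::setNames(first$elevation, first$population)
  pops <- intersect(names(hvals), names(elev))
  if (length(pops) < 3L) stop("need at least 3 populations", call. = FALSE)
  x <- hvals[pops]
  y <- elev[pops]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(pops))
}
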