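#' Pairwise sequence difference matrix
#'
#' Number of differing sites between every pair of sequences. Sites where
#' either sequence carries a gap or N count as differences, so apply
#' [clean_alignment()] first (the usual workflow).
#'
#' @param a a `cp_alignment`.
#' @return A symmetric integer matrix with zero diagonal, labelled by sample
#'   id.
#' @export
pairwise_difference_matrix <- function(a) {
  m <- a$seq
  n <- nrow(m)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- ncol(m) - matches
  diag(d) <- 0
  dimnames(d) <- list(a$sample_ids, a$sample_ids)
  round(d)
}

#' Pairwise difference matrix between haplotype sequences
#'
#' Convenience wrapper building the haplotype-level distance matrix used by
#' [nst()] from the distinct sequences of a haplotype table.
#'
#' @param h a `haplotype_table`.
#' @return Symmetric matrix of difference counts, labelled by haplotype id.
#' @export
haplotype_distance_matrix <- function(h) {
  a <- new_alignment(unname(h$haplotype_seqs), h$haplotype_ids, h$locus_name)
  pairwise_difference_matrix(a)
}

# Pons & Petit within/total diversity components. With dist = NULL the
# unordered (Gst) case is computed, i.e. d(i,j) = 1 - delta(i,j).
pons_petit_components <- function(h, dist = NULL) {
  counts <- h$counts
  n_k <- rowSums(counts)
  keep <- n_k >= 2L # unbiased per-population term needs n_k > 1
  counts <- counts[keep, , drop = FALSE]
  n_k <- n_k[keep]
  K <- nrow(counts)
  if (K < 2L) stop("need at least two populations with n >= 2", call. = FALSE)
  p <- sweep(counts, 1L, n_k, "/")
  if (is.null(dist)) {
    v_k <- n_k / (n_k - 1) * (1 - rowSums(p^2))
  } else {
    dist <- as_matrix_checked(dist, "haplotype distance matrix")
    dist <- dist[colnames(counts), colnames(counts)]
    v_k <- n_k / (n_k - 1) * vapply(seq_len(K), function(k) {
      drop(p[k, ] %*% dist %*% p[k, ])
    }, numeric(1))
  }
  vS <- mean(v_k)
  p_bar <- colMeans(p)
  n_harm <- 1 / mean(1 / n_k)
  base <- if (is.null(dist)) 1 - sum(p_bar^2) else drop(p_bar %*% dist %*% p_bar)
  vT <- base + vS / (n_harm * K)
  list(vS = vS, vT = vT)
}

#' Gst from haplotype frequencies
#'
#' Differentiation of unordered haplotypes, `(hT - hS)/hT`, using the
#' Pons & Petit sample-size-unbiased estimators of within-population (hS)
#' and total (hT) diversity (populations weighted equally, harmonic-mean
#' sample size in the total term).
#'
#' @param h a `haplotype_table`; populations with fewer than two samples are
#'   dropped.
#' @return Gst, or `NA` with a warning when the total diversity is zero.
#' @export
gst <- function(h) {
  comp <- pons_petit_components(h)
  if (comp$vT <= 0) {
    warning("total diversity is zero; Gst undefined")
    return(NA_real_)
  }
  (comp$vT - comp$vS) / comp$vT
}

#' Nst from haplotype frequencies and haplotype distances
#'
#' The ordered-allele analogue of [gst()]: diversities are weighted by the
#' pairwise distances between haplotype sequences, so Nst exceeds Gst when
#' closely related haplotypes co-occur geographically (phylogeographic
#' structure). When all pairwise distances are equal, Nst equals Gst.
#'
#' @param h a `haplotype_table`.
#' @param hap_dist symmetric distance matrix indexed by haplotype id;
#'   defaults to the pairwise difference counts between haplotype sequences.
#' @return Nst, or `NA` with a warning when total diversity is zero.
#' @export
nst <- function(h, hap_dist = haplotype_distance_matrix(h)) {
  comp <- pons_petit_components(h, dist = hap_dist)
  if (comp$vT <= 0) {
    warning("total distance-weighted diversity is zero; Nst undefined")
    return(NA_real_)
  }
  (comp$vT - comp$vS) / comp$vT
}

#' Permutation test for Nst > Gst
#'
#' Builds the null distribution of `Nst - Gst` by permuting haplotype
#' identities over the haplotype distance matrix (reassigning rows/columns
#' to labels), which destroys any association between haplotype relatedness
#' and geography while keeping frequencies fixed. One-sided p-value with the
#' `(extreme + 1)/(n_perm + 1)` convention.
#'
#' @param h a `haplotype_table` with at least two haplotypes.
#' @param hap_dist haplotype distance matrix (default: sequence differences).
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed for reproducibility.
#' @return List with `nst`, `gst`, `observed` (Nst - Gst) and `p_value`.
#' @export
nst_gst_permutation_test <- function(h, hap_dist = haplotype_distance_matrix(h),
                                     n_perm = 1000, seed = NULL) {
  if (length(h$haplotype_ids) < 2L) {
    stop("fewer than two haplotypes; test undefined", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  hap_dist <- as_matrix_checked(hap_dist)[h$haplotype_ids, h$haplotype_ids]
  g <- gst(h)
  n_obs <- nst(h, hap_dist)
  obs <- n_obs - g
  k <- length(h$haplotype_ids)
  perm <- with_rng(seed, vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(k)
    pd <- hap_dist[ix, ix]
    dimnames(pd) <- dimnames(hap_dist) # relabel: identities permuted
    nst(h, pd) - g
  }, numeric(1)))
  list(nst = n_obs, gst = g, observed = obs,
       p_value = perm_pvalue(perm, obs))
}

#' Hudson's Fst from sequence data
#'
#' `Fst = 1 - Hw/Hb`, where Hw is the mean number of pairwise differences
#' within populations (pooled over all within-population pairs) and Hb the
#' mean over all between-population pairs. Estimates can be negative; they
#' are reported as computed.
#'
#' @param a a cleaned `cp_alignment`.
#' @param s the matching sample table.
#' @param level `"overall"` for a single estimate or `"pairwise"` for a
#'   population-by-population matrix.
#' @return For `"overall"`, a list with `fst`, `hw`, `hb`; for
#'   `"pairwise"`, a symmetric matrix of Fst values (NA diagonal entries on
#'   the diagonal are 0, undefined pairs are NA).
#' @export
hudson_fst <- function(a, s, level = c("overall", "pairwise")) {
  level <- match.arg(level)
  s <- validate_sample_table(s)
  pop <- s$population[match(a$sample_ids, s$sample_id)]
  if (anyNA(pop)) stop("alignment contains samples absent from sample table",
                       call. = FALSE)
  pops <- unique(pop)
  if (length(pops) < 2L) stop("need at least two populations", call. = FALSE)
  d <- pairwise_difference_matrix(a)
  same <- outer(pop, pop, "==")
  lower <- lower.tri(d)
  if (level == "overall") {
    hw <- mean(d[lower & same])
    hb <- mean(d[lower & !same])
    if (!is.finite(hb) || hb == 0) {
      warning("between-population diversity is zero; Fst undefined")
      return(list(fst = NA_real_, hw = hw, hb = hb))
    }
    return(list(fst = 1 - hw / hb, hw = hw, hb = hb))
  }
  P <- length(pops)
  out <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(out) <- 0
  for (i in seq_len(P - 1)) {
    for (j in seq(i + 1, P)) {
      sel <- pop %in% c(pops[i], pops[j])
      dd <- d[sel, sel, drop = FALSE]
      pp <- pop[sel]
      sm <- outer(pp, pp, "==")
      lw <- lower.tri(dd)
      win <- dd[lw & sm]
      btw <- dd[lw & !sm]
      if (length(win) == 0L || length(btw) == 0L || mean(btw) == 0) next
      out[i, j] <- out[j, i] <- 1 - mean(win) / mean(btw)
    }
  }
  out
}

#' Single-level AMOVA with Phi-st
#'
#' Analysis of molecular variance partitioning squared-distance variation
#' among vs within populations (Excoffier-Smouse-Quattro). The supplied
#' matrix of raw pairwise difference counts is treated as squared Euclidean
#' distances ("number of different alleles" convention). Variance components
#' use the unequal-sample-size coefficient n0; significance is assessed by
#' permuting samples among populations.
#'
#' @param d sample-by-sample matrix (or `dist`) of pairwise difference
#'   counts, labelled by sample id.
#' @param s the matching sample table.
#' @param n_perm number of permutations (at least 100); 0 skips the test.
#' @param seed integer seed for the permutations.
#' @return An object of class `amova_result`: list with the AMOVA table
#'   (`df`, `ss`, `sigma2`, `pct`), `phi_st` and `p_value`.
#' @export
amova <- function(d, s, n_perm = 1000, seed = NULL) {
  d <- as_matrix_checked(d)
  s <- validate_sample_table(s)
  ids <- rownames(d)
  pop <- s$population[match(ids, s$sample_id)]
  if (anyNA(pop)) stop("distance matrix contains samples absent from sample table",
                       call. = FALSE)
  keep_pops <- names(which(table(pop) > 0L))
  if (length(keep_pops) < 2L) stop("need at least two populations", call. = FALSE)
  if (n_perm != 0 && n_perm < 100) stop("n_perm must be 0 or >= 100", call. = FALSE)
  obs <- amova_components(d, pop)
  p <- NA_real_
  if (n_perm > 0) {
    perm <- with_rng(seed, vapply(seq_len(n_perm), function(i) {
      suppressWarnings(amova_components(d, sample(pop))$phi_st)
    }, numeric(1)))
    p <- perm_pvalue(perm, obs$phi_st)
  }
  structure(
    list(df = c(among = obs$df_a, within = obs$df_w),
         ss = c(among = obs$ss_a, within = obs$ss_w, total = obs$ss_t),
         sigma2 = c(among = obs$sigma_a, within = obs$sigma_w),
         pct = c(among = obs$pct_a, within = obs$pct_w),
         phi_st = obs$phi_st, p_value = p, n_perm = n_perm),
    class = "amova_result"
  )
}

# core AMOVA algebra on one grouping vector; d entries are squared distances
amova_components <- function(d, pop) {
  n <- length(pop)
  groups <- unique(pop)
  K <- length(groups)
  lower <- lower.tri(d)
  ss_t <- sum(d[lower]) / n
  ss_w <- 0
  n_k <- numeric(K)
  for (g in seq_len(K)) {
    sel <- pop == groups[g]
    n_k[g] <- sum(sel)
    if (n_k[g] > 1L) {
      dd <- d[sel, sel, drop = FALSE]
      ss_w <- ss_w + sum(dd[lower.tri(dd)]) / n_k[g]
    }
  }
  ss_a <- ss_t - ss_w
  df_a <- K - 1L
  df_w <- n - K
  ms_a <- ss_a / df_a
  ms_w <- if (df_w > 0L) ss_w / df_w else 0
  n0 <- (n - sum(n_k^2) / n) / df_a
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  tot <- sigma_a + sigma_w
  if (tot <= 0) {
    phi <- 0
    pct_a <- 0
    pct_w <- 100
    if (ss_t == 0) warning("all pairwise distances are zero; Phi-st undefined, reporting 0")
  } else {
    phi <- sigma_a / tot
    pct_a <- 100 * sigma_a / tot
    pct_w <- 100 * sigma_w / tot
  }
  list(df_a = df_a, df_w = df_w, ss_a = ss_a, ss_w = ss_w, ss_t = ss_t,
       sigma_a = sigma_a, sigma_w = sigma_w, pct_a = pct_a, pct_w = pct_w,
       phi_st = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  tab <- data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(x$df["among"], x$df["within"], sum(x$df)),
    ss = round(c(x$ss["among"], x$ss["within"], x$ss["total"]), 3),
    sigma2 = c(round(x$sigma2["among"], 4), round(x$sigma2["within"], 4), NA),
    pct = c(round(x$pct["among"], 2), round(x$pct["within"], 2), NA)
  )
  print(tab, row.names = FALSE)
  cat("Phi-st =", round(x$phi_st, 4), " permutation p =",
      format(x$p_value), "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Convert an AMOVA result to a report table
#'
#' @param x an `amova_result`.
#' @param marker label for the marker/locus column.
#' @return Data frame in the shape of a published AMOVA table (source, d.f.,
#'   sum of squares, variance component, percentage of variance, Phi-st,
#'   p-value).
#' @export
amova_table <- function(x, marker = "") {
  data.frame(
    marker = marker,
    source = c("Among populations", "Within populations", "Total"),
    df = c(x$df["among"], x$df["within"], sum(x$df)),
    sum_of_squares = c(x$ss["among"], x$ss["within"], x$ss["total"]),
    variance_component = c(x$sigma2["among"], x$sigma2["within"],
                           sum(x$sigma2)),
    pct_variance = c(x$pct["among"], x$pct["within"], NA),
    phi_st = c(x$phi_st, NA, NA),
    p_value = c(x$p_value, NA, NA),
    stringsAsFactors = FALSE
  )
}
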