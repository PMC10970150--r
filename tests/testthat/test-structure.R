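test_that("pairwise difference counts match brute force and ape", {
  expect_equal(pairwise_difference_matrix(
    new_alignment(c("AAAA", "AATT"), c("x", "y")))["x", "y"], 2)
  expect_equal(pairwise_difference_matrix(
    new_alignment(c("ACGT", "ACGT"), c("x", "y")))["x", "y"], 0)
  set.seed(13)
  a <- random_alignment(10, 50)
  d <- pairwise_difference_matrix(a)
  expect_equal(unname(d), oracle_distance_matrix(a))
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # independent C implementation as a second oracle
  bin <- ape::as.DNAbin(matrix(tolower(a$seq), nrow = nrow(a$seq),
                               dimnames = dimnames(a$seq)))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "N"))
  expect_equal(unname(d), unname(d_ape))
})

make_hap_table <- function(counts, seqs = NULL) {
  k <- ncol(counts)
  ids <- paste0("H", seq_len(k))
  dimnames(counts) <- list(rownames(counts, do.NULL = FALSE, prefix = "P"), ids)
  if (is.null(seqs)) seqs <- sapply(seq_len(k), function(i) {
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
  })
  structure(list(haplotype_ids = ids,
                 haplotype_seqs = setNames(seqs, ids),
                 counts = counts, locus_name = "toy"),
            class = "haplotype_table")
}

test_that("Gst spans its limits and matches the double-sum oracle", {
  fixed <- make_hap_table(matrix(c(6L, 0L, 0L, 6L), 2, byrow = TRUE))
  expect_equal(gst(fixed), 1)

  same <- make_hap_table(matrix(rep(c(40L, 40L, 20L), 2), 2, byrow = TRUE))
  expect_lt(abs(gst(same)), 0.02)

  set.seed(17)
  for (i in 1:5) {
    cnt <- matrix(rpois(9, 4) + 1L, 3, 3)
    h <- make_hap_table(cnt)
    expect_equal(gst(h), oracle_pons_petit(cnt))
  }

  mono <- make_hap_table(matrix(c(5L, 4L), 2, 1))
  expect_warning(g <- gst(mono), "undefined")
  expect_true(is.na(g))
})

test_that("Nst reduces to Gst for constant distances and matches its oracle", {
  set.seed(19)
  cnt <- matrix(rpois(12, 3) + 1L, 3, 4)
  h <- make_hap_table(cnt)
  const <- matrix(4, 4, 4) - diag(4) * 4
  dimnames(const) <- list(h$haplotype_ids, h$haplotype_ids)
  expect_equal(nst(h, const), gst(h))

  d <- matrix(rpois(16, 5), 4, 4)
  d <- d + t(d)
  diag(d) <- 0
  dimnames(d) <- list(h$haplotype_ids, h$haplotype_ids)
  expect_equal(nst(h, d), oracle_pons_petit(cnt, d))

  fixed <- make_hap_table(matrix(c(6L, 0L, 0L, 6L), 2, byrow = TRUE),
                          seqs = c("AAAA", "TTTT"))
  expect_equal(nst(fixed), 1)
})

test_that("the Nst > Gst permutation test detects structured haplotype distances", {
  # equal distances: observed Nst - Gst is 0, p near 1
  set.seed(23)
  cnt <- matrix(rpois(8, 4) + 1L, 2, 4)
  h <- make_hap_table(cnt)
  const <- matrix(2, 4, 4) - diag(4) * 2
  dimnames(const) <- list(h$haplotype_ids, h$haplotype_ids)
  r0 <- nst_gst_permutation_test(h, const, n_perm = 200, seed = 1)
  expect_equal(r0$observed, 0)
  expect_gt(r0$p_value, 0.9)

  # two demes each holding a cluster of 4 similar haplotypes, the clusters
  # far apart: only cluster-preserving label permutations (a 2 * 4!4!/8!
  # fraction) reach the observed Nst - Gst
  cnt2 <- matrix(c(rep(3L, 4), rep(0L, 4), rep(0L, 4), rep(3L, 4)),
                 2, byrow = TRUE)
  west <- c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATA", "AAAAAAATAA")
  east <- c("TTTTTTTTTT", "TTTTTTTTTA", "TTTTTTTTAT", "TTTTTTTATT")
  h2 <- make_hap_table(cnt2, seqs = c(west, east))
  r1 <- nst_gst_permutation_test(h2, n_perm = 500, seed = 2)
  expect_gt(r1$nst, r1$gst)
  expect_lt(r1$p_value, 0.05)
  expect_gte(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  # seed reproducibility
  r1b <- nst_gst_permutation_test(h2, n_perm = 500, seed = 2)
  expect_identical(r1b$p_value, r1$p_value)
  expect_error(nst_gst_permutation_test(h2, n_perm = 50, seed = 1),
               "at least 100")
})

test_that("Hudson's Fst spans its limits and matches brute-force sums", {
  mono2 <- new_alignment(c(rep("AAAA", 4), rep("TTTT", 4)),
                         sprintf("s%d", 1:8))
  s <- two_pop_table(mono2$sample_ids, 4)
  expect_equal(hudson_fst(mono2, s)$fst, 1)

  set.seed(29)
  a <- random_alignment(12, 40)
  s2 <- two_pop_table(a$sample_ids, 6)
  res <- hudson_fst(a, s2)
  d <- oracle_distance_matrix(a)
  pop <- s2$population
  win <- c()
  btw <- c()
  for (i in 1:11) for (j in (i + 1):12) {
    if (pop[i] == pop[j]) win <- c(win, d[i, j]) else btw <- c(btw, d[i, j])
  }
  expect_equal(res$fst, 1 - mean(win) / mean(btw))
  expect_lt(abs(res$fst), 0.25) # panmictic-ish random data

  pw <- hudson_fst(a, s2, "pairwise")
  expect_equal(pw["A", "B"], res$fst)
  expect_true(isSymmetric(pw))
})

test_that("AMOVA gives all-among variance for fixed distinct demes", {
  a <- new_alignment(c(rep("AAAAAA", 8), rep("TTTTTT", 8)),
                     sprintf("s%d", 1:16))
  s <- two_pop_table(a$sample_ids, 8)
  am <- amova(pairwise_difference_matrix(a), s, n_perm = 200, seed = 3)
  expect_equal(am$phi_st, 1)
  expect_equal(unname(am$pct["among"]), 100)
  # observed Phi-st is maximal; a permutation ties only by recreating the
  # exact split (probability 2/choose(16,8) each), so allow one tie
  expect_lte(am$p_value, 2 / (200 + 1))
  expect_equal(unname(am$df), c(1, 14))
})

test_that("AMOVA variance components match hand algebra on a 3-population toy", {
  # n = 2,2,2; squared distances chosen by hand
  ids <- sprintf("s%d", 1:6)
  d <- matrix(0, 6, 6, dimnames = list(ids, ids))
  d["s1", "s2"] <- d["s2", "s1"] <- 2
  d["s3", "s4"] <- d["s4", "s3"] <- 4
  d["s5", "s6"] <- d["s6", "s5"] <- 0
  between <- combn(6, 2)
  for (k in seq_len(ncol(between))) {
    i <- between[1, k]; j <- between[2, k]
    if (ceiling(i / 2) != ceiling(j / 2) && d[i, j] == 0 && i != j) {
      d[i, j] <- d[j, i] <- 10
    }
  }
  s <- data.frame(sample_id = ids, population = rep(c("P1", "P2", "P3"), each = 2),
                  longitude = 0, latitude = 0, elevation = 0)
  am <- amova(d, s, n_perm = 0)
  # hand solution: SS_T = sum(d)/6, SS_W = (2+4+0)/2, MS algebra with n0 = 2
  ss_t <- (2 + 4 + 0 + 10 * 12) / 6
  ss_w <- (2 + 4 + 0) / 2
  ss_a <- ss_t - ss_w
  ms_a <- ss_a / 2
  ms_w <- ss_w / 3
  sigma_a <- (ms_a - ms_w) / 2
  expect_equal(unname(am$ss["total"]), ss_t)
  expect_equal(unname(am$ss["within"]), ss_w)
  expect_equal(unname(am$sigma2["among"]), sigma_a)
  expect_equal(unname(am$sigma2["within"]), ms_w)
  expect_equal(am$phi_st, sigma_a / (sigma_a + ms_w))
})

test_that("balanced two-deme AMOVA Phi-st equals Hudson's Fst", {
  set.seed(37)
  for (i in 1:3) {
    a <- random_alignment(14, 60)
    s <- two_pop_table(a$sample_ids, 7)
    am <- amova(pairwise_difference_matrix(a), s, n_perm = 0)
    hf <- hudson_fst(a, s)$fst
    expect_equal(am$phi_st, hf, tolerance = 1e-6)
  }
})

test_that("AMOVA permutation p-values are seed-reproducible", {
  set.seed(43)
  a <- random_alignment(10, 30)
  s <- two_pop_table(a$sample_ids, 5)
  d <- pairwise_difference_matrix(a)
  p1 <- amova(d, s, n_perm = 100, seed = 9)$p_value
  p2 <- amova(d, s, n_perm = 100, seed = 9)$p_value
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 101)
  expect_error(amova(d, s, n_perm = 10), ">= 100")
})

test_that("higher migration lowers island-model Phi-st", {
  phis <- sapply(c(2e-4, 5e-3), function(m) {
    reps <- sapply(1:8, function(r) {
      a <- sim_island_alignment(c(8, 8, 8), ne = 300, m = m,
                               mu_site = 5e-6, L = 300,
                               seed = 1000 * r + round(m * 1e6))
      s <- sample_table_for(a, rep(c("A", "B", "C"), each = 8))
      amova(pairwise_difference_matrix(clean_alignment(a)), s, n_perm = 0)$phi_st
    })
    median(reps)
  })
  expect_gt(phis[1], phis[2])
})
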