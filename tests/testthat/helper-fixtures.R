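# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (loops, enumeration) and share no code with
# the package implementations they check.

random_alignment <- function(n, L, alphabet = c("A", "C", "G", "T"),
                             locus = "rand") {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  new_alignment(seqs, sprintf("r%03d", seq_len(n)), locus)
}

two_pop_table <- function(ids, n1) {
  data.frame(
    sample_id = ids,
    population = rep(c("A", "B"), c(n1, length(ids) - n1)),
    longitude = rep(c(100, 110), c(n1, length(ids) - n1)),
    latitude = rep(c(25, 26), c(n1, length(ids) - n1)),
    elevation = rep(c(500, 800), c(n1, length(ids) - n1)),
    stringsAsFactors = FALSE
  )
}

sample_table_for <- function(a, populations, lon = NULL, lat = NULL,
                             elev = NULL) {
  pops <- unique(populations)
  if (is.null(lon)) lon <- seq(100, 100 + length(pops) - 1)
  if (is.null(lat)) lat <- rep(25, length(pops))
  if (is.null(elev)) elev <- seq(400, by = 100, length.out = length(pops))
  i <- match(populations, pops)
  data.frame(
    sample_id = a$sample_ids, population = populations,
    longitude = lon[i], latitude = lat[i], elevation = elev[i],
    stringsAsFactors = FALSE
  )
}

# brute-force Hamming distance over sequence strings
oracle_hamming <- function(s1, s2) {
  x <- strsplit(s1, "")[[1]]
  y <- strsplit(s2, "")[[1]]
  sum(x != y)
}

oracle_distance_matrix <- function(a) {
  seqs <- apply(a$seq, 1L, paste, collapse = "")
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- oracle_hamming(seqs[i], seqs[j])
    }
  }
  d
}

# independently coded Pons & Petit estimators via explicit double sums
oracle_pons_petit <- function(counts, dist = NULL) {
  counts <- counts[rowSums(counts) >= 2, , drop = FALSE]
  K <- nrow(counts)
  k <- ncol(counts)
  if (is.null(dist)) {
    dist <- matrix(1, k, k) - diag(k)
  }
  n_k <- rowSums(counts)
  v_k <- numeric(K)
  for (g in seq_len(K)) {
    acc <- 0
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        acc <- acc + (counts[g, i] / n_k[g]) * (counts[g, j] / n_k[g]) * dist[i, j]
      }
    }
    v_k[g] <- n_k[g] / (n_k[g] - 1) * acc
  }
  vS <- mean(v_k)
  p_bar <- colMeans(sweep(counts, 1, n_k, "/"))
  acc <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) acc <- acc + p_bar[i] * p_bar[j] * dist[i, j]
  }
  vT <- acc + vS / (K / sum(1 / n_k) * K)
  (vT - vS) / vT
}

# textbook Tajima's D, recomputed from scratch on sequence strings
oracle_tajimas_d <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k_sum <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) k_sum <- k_sum + sum(m[i, ] != m[j, ])
  }
  k_hat <- k_sum / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Ewens K distribution by the Chinese-restaurant-process recursion,
# independent of the Stirling-number route used by the package
oracle_ewens_pmf <- function(n, theta) {
  p <- 1 # P(K = 1) after the first customer
  for (m in seq_len(n - 1)) {
    newp <- numeric(length(p) + 1)
    for (k in seq_along(p)) {
      newp[k] <- newp[k] + p[k] * m / (theta + m)
      newp[k + 1] <- newp[k + 1] + p[k] * theta / (theta + m)
    }
    p <- newp
  }
  p
}

oracle_fu_fs <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  k_sum <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) k_sum <- k_sum + sum(m[i, ] != m[j, ])
  }
  theta <- k_sum / choose(n, 2)
  if (theta == 0) return(NA_real_)
  k_obs <- length(unique(seqs))
  pmf <- oracle_ewens_pmf(n, theta)
  sp <- sum(pmf[k_obs:n])
  log(sp / (1 - sp))
}

# simulate one island-model alignment in one call
sim_island_alignment <- function(sizes, ne, m, mu_site, L, seed) {
  g <- simulate_island_genealogy(sizes, ne, m, seed = seed)
  apply_mutations(g, mu_site, L, seed = seed + 7L)
}

write_tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_tmp_samples <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
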