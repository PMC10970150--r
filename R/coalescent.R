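# Structured-coalescent simulator for haploid, non-recombining organelle
# loci under a finite island model, with an optional stepwise population
# size change shared by all demes. Time runs backwards in generations.
#
# Migration convention: each lineage migrates at rate m per generation and
# picks its destination uniformly over ALL demes (migrant pool includes the
# home deme). Under this convention the expected between- minus
# within-deme coalescence time is d/(2m) and the equilibrium
# Fst = 1/(1 + 2 Ne m) holds for any number of demes, matching the island
# model formula the package's estimators are built on.

#' Simulate a genealogy under the finite island model
#'
#' @param sample_sizes integer vector: number of sampled lineages per deme.
#' @param ne haploid effective size per deme (generations time scale).
#' @param migration_rate per-lineage migration rate per generation; either a
#'   scalar or one rate per deme (rate at which a lineage currently in that
#'   deme migrates).
#' @param size_change optional list `list(time =, factor =)`: at `time`
#'   generations in the past every deme's size becomes `ne * factor`
#'   (factor < 1 encodes an expansion seen forward in time).
#' @param seed integer seed.
#' @return Object of class `genealogy`: list with `parent` (index of the
#'   parent node, 0 for the root), `time` (node times in generations; leaves
#'   at 0), `n_leaves` and `deme` (deme of each leaf).
#' @export
simulate_island_genealogy <- function(sample_sizes, ne, migration_rate,
                                      size_change = NULL, seed = NULL) {
  stopifnot(all(sample_sizes >= 1), ne > 0, all(migration_rate >= 0))
  d <- length(sample_sizes)
  n <- sum(sample_sizes)
  mig <- rep_len(migration_rate, d)
  if (d > 1L && all(mig == 0)) {
    warning("zero migration with multiple demes: lineages that cannot ",
            "coalesce within demes will be merged into one panmictic pool")
  }
  epoch_time <- if (is.null(size_change)) Inf else size_change$time
  epoch_factor <- if (is.null(size_change)) 1 else size_change$factor
  with_rng(seed, {
    parent <- integer(2L * n - 1L)
    node_time <- numeric(2L * n - 1L)
    lin_node <- seq_len(n) # active lineage -> node id
    lin_deme <- rep.int(seq_len(d), sample_sizes)
    next_node <- n + 1L
    t_now <- 0
    ne_now <- ne
    k <- n
    while (k > 1L) {
      k_by_deme <- tabulate(lin_deme, nbins = d)
      coal_rates <- k_by_deme * (k_by_deme - 1) / 2 / ne_now
      mig_rates <- k_by_deme * mig
      total <- sum(coal_rates) + sum(mig_rates)
      if (total == 0) { # isolated singletons with m = 0: pool panmictically
        lin_deme[] <- 1L
        next
      }
      dt <- stats::rexp(1, total)
      if (t_now + dt >= epoch_time && t_now < epoch_time) {
        t_now <- epoch_time
        ne_now <- ne * epoch_factor
        next
      }
      t_now <- t_now + dt
      ev_deme <- sample.int(d, 1L, prob = coal_rates + mig_rates)
      if (stats::runif(1) < coal_rates[ev_deme] /
          (coal_rates[ev_deme] + mig_rates[ev_deme])) {
        here <- which(lin_deme == ev_deme)
        pair <- here[sample.int(length(here), 2L)]
        parent[lin_node[pair]] <- next_node
        node_time[next_node] <- t_now
        lin_node[pair[1L]] <- next_node
        lin_node <- lin_node[-pair[2L]]
        lin_deme <- lin_deme[-pair[2L]]
        next_node <- next_node + 1L
        k <- k - 1L
      } else {
        here <- which(lin_deme == ev_deme)
        mover <- here[sample.int(length(here), 1L)]
        lin_deme[mover] <- sample.int(d, 1L) # uniform over all demes
      }
    }
    structure(
      list(parent = parent, time = node_time, n_leaves = n,
           deme = rep.int(seq_len(d), sample_sizes)),
      class = "genealogy"
    )
  })
}

#' Drop mutations on a genealogy and build an alignment
#'
#' Poisson mutations on each branch (rate `mu * L` per generation) are
#' placed at uniformly chosen sites of an ancestral sequence of A's; each
#' mutation substitutes a random different base (infinite sites on a finite
#' length: repeat hits are possible but rare at realistic rates).
#'
#' @param g a `genealogy`.
#' @param mu per-site per-generation mutation rate.
#' @param L sequence length in sites.
#' @param sample_ids ids for the leaf sequences (default S001..).
#' @param locus_name locus label.
#' @param seed integer seed.
#' @return A `cp_alignment` of the leaf sequences.
#' @export
apply_mutations <- function(g, mu, L, sample_ids = NULL,
                            locus_name = "simulated", seed = NULL) {
  n <- g$n_leaves
  n_nodes <- 2L * n - 1L
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(n))
  }
  with_rng(seed, {
    root <- which(g$parent == 0L)[1L]
    seqs <- matrix("", nrow = n, ncol = L)
    anc <- rep("A", L)
    # children lists for a root-to-leaf traversal
    kids <- split(seq_len(n_nodes)[-root], g$parent[-root])
    node_seq <- vector("list", n_nodes)
    node_seq[[root]] <- anc
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in kids[[as.character(v)]]) {
        s <- node_seq[[v]]
        blen <- g$time[v] - g$time[w]
        nm <- stats::rpois(1, blen * mu * L)
        if (nm > 0L) {
          sites <- sample.int(L, nm, replace = TRUE)
          for (site in sites) {
            s[site] <- sample(setdiff(c("A", "C", "G", "T"), s[site]), 1L)
          }
        }
        if (w <= n) {
          seqs[w, ] <- s
        } else {
          node_seq[[w]] <- s
          stack <- c(stack, w)
        }
      }
      node_seq[v] <- list(NULL)
    }
    new_alignment(apply(seqs, 1L, paste, collapse = ""), sample_ids,
                  locus_name)
  })
}

#' Simulate a single-population sample under sudden expansion
#'
#' Single-deme coalescent with a stepwise size change, parameterised
#' directly in mutational units: the current scaled size is `theta1`, the
#' ancestral (pre-expansion) size `theta0`, and the change happens `tau`
#' mutational time units (2*u*t) in the past. Mutations are placed at
#' uniform positions of a length-`L` sequence, so the expected pairwise
#' difference count of a stationary population equals its theta.
#'
#' @param theta0 pre-expansion scaled mutation parameter (>= 0).
#' @param theta1 current scaled mutation parameter (>= 0).
#' @param tau time of the size change in mutational units (>= 0).
#' @param n sample size.
#' @param L sequence length.
#' @param seed integer seed.
#' @return A `cp_alignment`.
#' @export
simulate_expansion_sample <- function(theta0, theta1, tau, n, L = 600,
                                      seed = NULL) {
  stopifnot(theta0 >= 0, theta1 >= 0, tau >= 0, n >= 2, L >= 1)
  with_rng(seed, {
    # coalescent in mutational time: pair rate 1/theta(t), mutation rate 1/2
    # per lineage per unit time
    eps <- 1e-12
    lin <- as.list(seq_len(n)) # active lineages: leaf sets
    seqs <- matrix("A", n, L)
    t_now <- 0
    k <- n
    while (k > 1L) {
      th <- if (t_now < tau) theta1 else theta0
      rate <- k * (k - 1) / 2 / max(th, eps)
      dt <- stats::rexp(1, rate)
      if (t_now < tau && t_now + dt >= tau) {
        seqs <- mutate_lineages(seqs, lin, tau - t_now, L)
        t_now <- tau
        next
      }
      seqs <- mutate_lineages(seqs, lin, dt, L)
      t_now <- t_now + dt
      pair <- sample.int(k, 2L)
      lin[[pair[1L]]] <- c(lin[[pair[1L]]], lin[[pair[2L]]])
      lin[[pair[2L]]] <- NULL
      k <- k - 1L
    }
    new_alignment(apply(seqs, 1L, paste, collapse = ""),
                  sprintf("S%03d", seq_len(n)), "expansion_sim")
  })
}

# add Poisson(dt/2) mutations per active lineage to all its descendant leaves
mutate_lineages <- function(seqs, lin, dt, L) {
  if (dt <= 0) return(seqs)
  nm <- stats::rpois(length(lin), dt / 2)
  for (l in which(nm > 0L)) {
    leaves <- lin[[l]]
    sites <- sample.int(L, nm[l], replace = TRUE)
    for (site in sites) {
      cur <- seqs[leaves[1L], site]
      seqs[leaves, site] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seqs
}
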