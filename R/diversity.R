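#' Observed haplotype diversity
#'
#' `h = 1 - sum(p_i^2)`, the probability that two haplotypes drawn with
#' replacement differ. No `n/(n-1)` sample-size correction is applied: for a
#' population of 3 carrying haplotypes in a (2,1) composition this gives
#' 0.4444 (the corrected estimator would give 0.6667).
#'
#' @param x a vector of haplotype counts or frequencies for one population.
#' @return Haplotype diversity in `[0, 1)`.
#' @export
haplotype_diversity <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty frequency vector", call. = FALSE)
  if (any(x < 0)) stop("negative haplotype frequencies", call. = FALSE)
  tot <- sum(x)
  if (tot == 0) stop("all haplotype frequencies are zero", call. = FALSE)
  p <- x / tot
  1 - sum(p^2)
}

#' Nucleotide diversity per site
#'
#' Mean proportion of differing sites over all unordered sequence pairs,
#' computed on the complete-deletion sites (no `n/(n-1)` correction): for
#' exactly two sequences differing at d of L sites it equals d/L.
#'
#' @param a a `cp_alignment` with at least two sequences.
#' @return Per-site nucleotide diversity (pi).
#' @export
nucleotide_diversity <- function(a) {
  if (n_sequences(a) < 2L) {
    stop("nucleotide diversity needs at least two sequences", call. = FALSE)
  }
  a <- clean_alignment(a)
  d <- pairwise_difference_matrix(a)
  n <- n_sequences(a)
  sum(d[lower.tri(d)]) / (a$length * n * (n - 1) / 2)
}

#' Per-population diversity summary
#'
#' One row per population plus a pooled `Total` row, in the shape of a
#' published per-population cpDNA diversity table: sample size, haplotype
#' diversity h, per-site nucleotide diversity pi, and the abundance classes
#' x (haplotypes whose overall abundance is at least two) and y (haplotypes
#' that are singletons in the overall sample).
#'
#' @param h a `haplotype_table` from [collapse_haplotypes()].
#' @param a the cleaned `cp_alignment` the table was derived from.
#' @param s the matching sample table.
#' @return A data frame with columns `population`, `n`, `h`, `pi`,
#'   `n_hap_ge2`, `n_singletons`, `haplotypes` (space-separated labels of the
#'   non-singleton haplotypes present).
#' @export
population_summary <- function(h, a, s) {
  s <- validate_sample_table(s)
  a <- clean_alignment(a)
  overall <- colSums(h$counts)
  ge2 <- overall >= 2L
  pops <- rownames(h$counts)
  n_by_pop <- rowSums(h$counts)
  if (any(n_by_pop == 0L)) {
    warning("excluding population(s) with no samples: ",
            paste(pops[n_by_pop == 0L], collapse = ", "))
    pops <- pops[n_by_pop > 0L]
  }
  pop_of <- s$population[match(a$sample_ids, s$sample_id)]
  row_for <- function(pop) {
    cnt <- h$counts[pop, ]
    present <- cnt > 0L
    ids <- a$sample_ids[pop_of == pop]
    pi <- if (length(ids) >= 2L) nucleotide_diversity(subset_alignment(a, ids)) else 0
    data.frame(
      population = pop, n = sum(cnt),
      h = haplotype_diversity(cnt),
      pi = pi,
      n_hap_ge2 = sum(present & ge2),
      n_singletons = sum(present & !ge2),
      haplotypes = paste(h$haplotype_ids[present & ge2], collapse = " "),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(pops, row_for))
  total <- data.frame(
    population = "Total", n = sum(h$counts),
    h = haplotype_diversity(overall),
    pi = nucleotide_diversity(a),
    n_hap_ge2 = sum(ge2), n_singletons = sum(!ge2),
    haplotypes = paste(h$haplotype_ids[ge2], collapse = " "),
    stringsAsFactors = FALSE
  )
  rbind(out, total)
}

#' Mean and standard deviation across populations
#'
#' Summarises a per-population statistic as `mean +- SD`. The SD convention
#' is the sample SD (n-1 denominator) by default; set `sd_type =
#' "population"` for the n-denominator version.
#'
#' @param values numeric vector (one value per population).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return List with elements `mean`, `sd` and `n`.
#' @export
across_population_mean <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarise", call. = FALSE)
  m <- mean(values)
  n <- length(values)
  s <- if (n == 1L) 0 else stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  list(mean = m, sd = s, n = n)
}
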