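# Bundled summary tables from a published range-wide chloroplast DNA survey
# of the Toona ciliata (Chinese mahogany) complex: 447 trees from 29
# populations across southern China, genotyped at the psbA-trnH and
# trnL-trnL intergenic spacers. The raw alignments were not deposited
# publicly, but the per-population summaries printed in the survey are
# sufficient inputs for the desk-scale analyses (column summaries,
# elevation correlations, and the island-model mutation/seed-flow
# estimator).

#' Population table of the T. ciliata cpDNA survey
#'
#' Locality, sample size, decimal coordinates and elevation (m) for each of
#' the 29 surveyed populations.
#'
#' @return Data frame with columns `population`, `location`, `n`,
#'   `longitude`, `latitude`, `elevation`.
#' @export
tciliata_populations <- function() {
  utils::read.delim(system.file("extdata", "tciliata_populations.tsv",
                                package = "plastidpop"),
                    stringsAsFactors = FALSE)
}

#' Per-population diversity of the T. ciliata cpDNA survey
#'
#' Observed haplotype diversity (h) and per-site nucleotide diversity (pi)
#' for both chloroplast fragments, as printed per population.
#'
#' @return Data frame with columns `population`, `h_psba_trnh`,
#'   `pi_psba_trnh`, `h_trnl_trnl`, `pi_trnl_trnl`.
#' @export
tciliata_diversity <- function() {
  utils::read.delim(system.file("extdata", "tciliata_diversity_by_population.tsv",
                                package = "plastidpop"),
                    stringsAsFactors = FALSE)
}

#' Differentiation coefficients of the T. ciliata surveys
#'
#' Gst/Nst per fragment, AMOVA Phi-st per fragment and for the concatenated
#' fragments, and the mtDNA Fst of the same populations from a companion
#' mitochondrial survey (the pairing used by the island-model
#' mutation-to-seed-migration estimator).
#'
#' @return Data frame with columns `marker`, `statistic`, `value`.
#' @export
tciliata_differentiation <- function() {
  utils::read.delim(system.file("extdata", "tciliata_differentiation.tsv",
                                package = "plastidpop"),
                    stringsAsFactors = FALSE)
}

#' Expand a population table into a per-sample table
#'
#' Utility for analyses that need a sample-level metadata table (one row per
#' individual) from a population-level table with an `n` column.
#'
#' @param pops data frame with columns `population`, `n`, `longitude`,
#'   `latitude`, `elevation`.
#' @return A sample table as produced by [read_sample_table()], with ids
#'   `<population>_<i>`.
#' @export
expand_population_table <- function(pops) {
  idx <- rep(seq_len(nrow(pops)), pops$n)
  within_i <- sequence(pops$n)
  validate_sample_table(data.frame(
    sample_id = paste0(pops$population[idx], "_", within_i),
    population = pops$population[idx],
    longitude = pops$longitude[idx],
    latitude = pops$latitude[idx],
    elevation = pops$elevation[idx],
    stringsAsFactors = FALSE
  ))
}
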