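#' Equilibrium Fst under drift, migration and mutation
#'
#' Wright's island-model equilibrium for a haploid, uniparentally inherited
#' locus whose gene flow is mediated by seed movement:
#' `Fst = 1 / (1 + 2 Ne (ms + mu))`, with haploid effective deme size `Ne`,
#' seed migration rate `ms` and mutation rate `mu` (per locus per
#' generation).
#'
#' @param ne haploid effective population size (> 0).
#' @param ms seed migration rate (>= 0).
#' @param mu mutation rate (>= 0).
#' @return Equilibrium Fst in (0, 1].
#' @export
equilibrium_fst <- function(ne, ms, mu) {
  if (any(ne <= 0)) stop("ne must be positive", call. = FALSE)
  if (any(ms < 0) || any(mu < 0)) stop("rates must be non-negative", call. = FALSE)
  1 / (1 + 2 * ne * (ms + mu))
}

#' Mutation-to-seed-migration ratio from paired organelle Fst values
#'
#' For two maternally inherited markers that share the same seed-mediated
#' gene flow and drift — chloroplast and mitochondrial DNA in an angiosperm —
#' the equilibrium formulas `Fst_cp = 1/(1 + 2 Ne (ms + mu_cp))` and
#' `Fst_mt = 1/(1 + 2 Ne (ms + mu_mt))` combine, under the assumption that
#' the mitochondrial mutation rate is negligible (`mu_mt ~ 0`), into
#' `mu_cp/ms = (1/Fst_cp - 1) / (1/Fst_mt - 1) - 1`. A ratio well above 1
#' means mutation, not seed flow, dominates the chloroplast marker's
#' differentiation.
#'
#' @param fst_cp chloroplast differentiation coefficient, in (0, 1).
#' @param fst_mt mitochondrial differentiation coefficient, in (0, 1).
#' @return Object of class `island_model_estimate`: list with `fst_cp`,
#'   `fst_mt`, `mu_over_ms` and `assumptions`.
#' @export
mu_over_ms <- function(fst_cp, fst_mt) {
  if (!is.finite(fst_cp) || !is.finite(fst_mt) ||
      fst_cp <= 0 || fst_cp >= 1 || fst_mt <= 0 || fst_mt >= 1) {
    stop("both Fst values must lie strictly between 0 and 1", call. = FALSE)
  }
  ratio <- (1 / fst_cp - 1) / (1 / fst_mt - 1) - 1
  structure(
    list(fst_cp = fst_cp, fst_mt = fst_mt, mu_over_ms = ratio,
         assumptions = "mu_mt ~ 0; shared Ne and ms across markers"),
    class = "island_model_estimate"
  )
}

#' @export
print.island_model_estimate <- function(x, ...) {
  cat(sprintf("mu_cp/ms = %.4f  (Fst_cp = %.4f, Fst_mt = %.4f)\n",
              x$mu_over_ms, x$fst_cp, x$fst_mt))
  cat("assumes:", x$assumptions, "\n")
  invisible(x)
}
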