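# Orchestration: the full per-locus and concatenated analysis, written as
# TSV reports mirroring the table shapes of a range-wide cpDNA survey
# (per-population diversity, AMOVA, Gst/Nst, pairwise Fst, IBD fit,
# neutrality + mismatch, island-model estimate) plus a JSON run manifest.

round_df <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_report <- function(df, dir, name, digits = 4) {
  utils::write.table(round_df(df, digits), file.path(dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(df, file.path(dir, paste0(name, "_raw.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# per-locus block: haplotypes, diversity table, Gst/Nst, Fst, AMOVA
analyse_locus <- function(a, s, label, n_perm, seed) {
  a <- clean_alignment(a)
  h <- collapse_haplotypes(a, s)
  seeds <- derive_seeds(seed, 2L)
  summary_tab <- population_summary(h, a, s)
  ng <- tryCatch(
    nst_gst_permutation_test(h, n_perm = n_perm, seed = seeds[1L]),
    error = function(e) list(nst = NA, gst = NA, observed = NA, p_value = NA)
  )
  fst_overall <- hudson_fst(a, s, "overall")
  fst_pair <- hudson_fst(a, s, "pairwise")
  am <- amova(pairwise_difference_matrix(a), s, n_perm = n_perm,
              seed = seeds[2L])
  list(label = label, alignment = a, haplotypes = h, diversity = summary_tab,
       gst = ng$gst, nst = ng$nst, p_nst_gt_gst = ng$p_value,
       fst = fst_overall, pairwise_fst = fst_pair, amova = am)
}

#' Run the full phylogeographic analysis
#'
#' Reads two per-locus alignments and the sample metadata, then produces,
#' for each locus and for the concatenated sequences: haplotype and
#' diversity tables, Gst/Nst with the phylogeographic permutation test,
#' Hudson's Fst (overall and pairwise), and AMOVA. On the concatenated data
#' it additionally runs the isolation-by-distance regression and Mantel
#' test, the diversity-elevation correlations per locus, per-population
#' neutrality tests and mismatch-distribution fits, and (when a
#' mitochondrial Fst is supplied) the island-model mutation-to-seed-flow
#' estimate. All reports are written to `out_dir` as TSV (4-decimal and
#' full-precision variants) with a JSON manifest recording the seed and
#' replicate counts.
#'
#' @param locus1_path,locus2_path FASTA paths of the two aligned loci.
#' @param samples_path TSV path of the sample metadata.
#' @param out_dir output directory (created if missing).
#' @param n_perm permutations for AMOVA/Gst-Nst/Mantel tests.
#' @param n_coal_sims coalescent replicates for neutrality p-values.
#' @param n_boot parametric-bootstrap replicates for the mismatch tests
#'   (0 skips them).
#' @param seed master seed; every stochastic stage draws a child seed from
#'   it, so reruns are byte-identical.
#' @param fst_mt optional mitochondrial differentiation coefficient for the
#'   island-model estimator.
#' @param min_n smallest per-population sample size analysed in the
#'   demographic block.
#' @return Invisibly, a list with all result objects (`locus1`, `locus2`,
#'   `concatenated`, `ibd`, `elevation_correlations`, `neutrality`,
#'   `island_model`, `manifest`).
#' @export
run_full_analysis <- function(locus1_path, locus2_path, samples_path,
                              out_dir, n_perm = 1000, n_coal_sims = 1000,
                              n_boot = 100, seed, fst_mt = NULL, min_n = 4) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- read_sample_table(samples_path)
  a1 <- read_alignment(locus1_path)
  a2 <- read_alignment(locus2_path)
  seeds <- derive_seeds(seed, 6L)

  res1 <- analyse_locus(a1, s, a1$locus_name, n_perm, seeds[1L])
  res2 <- analyse_locus(a2, s, a2$locus_name, n_perm, seeds[2L])
  cc <- concat_alignments(a1, a2)
  resc <- analyse_locus(cc, s, cc$locus_name, n_perm, seeds[3L])

  for (r in list(res1, res2, resc)) {
    tag <- gsub("[^A-Za-z0-9]+", "_", r$label)
    write_report(r$diversity, out_dir, paste0("diversity_", tag))
    write_report(amova_table(r$amova, r$label), out_dir, paste0("amova_", tag))
    pf <- data.frame(population = rownames(r$pairwise_fst), r$pairwise_fst,
                     check.names = FALSE)
    write_report(pf, out_dir, paste0("pairwise_fst_", tag))
  }
  struct_tab <- do.call(rbind, lapply(list(res1, res2, resc), function(r) {
    data.frame(marker = r$label, gst = r$gst, nst = r$nst,
               p_nst_gt_gst = r$p_nst_gt_gst, fst_hudson = r$fst$fst,
               phi_st = r$amova$phi_st, p_amova = r$amova$p_value,
               stringsAsFactors = FALSE)
  }))
  write_report(struct_tab, out_dir, "differentiation")

  # isolation by distance on the concatenated pairwise Fst
  km <- geographic_distance_matrix(s)
  ibd <- tryCatch(
    ibd_regression(resc$pairwise_fst, km, n_perm = max(n_perm, 99),
                   seed = seeds[4L]),
    error = function(e) NULL
  )
  if (!is.null(ibd)) {
    write_report(ibd$pairs, out_dir, "ibd_pairs")
    write_report(data.frame(
      intercept = ibd$intercept, slope = ibd$slope,
      r_squared = ibd$r_squared, p_slope = ibd$p_slope,
      mantel_r = ibd$mantel_r, p_mantel = ibd$p_mantel,
      n_pairs = ibd$n_pairs, n_excluded = ibd$n_excluded
    ), out_dir, "ibd_fit")
  }

  elev <- do.call(rbind, lapply(list(res1, res2), function(r) {
    ec <- tryCatch(diversity_elevation_correlation(r$diversity, s),
                   error = function(e) list(r = NA, p_value = NA, n = NA))
    data.frame(marker = r$label, r = ec$r, p_value = ec$p_value, n = ec$n)
  }))
  write_report(elev, out_dir, "elevation_correlation")

  # demographic block on the concatenated sequences, per population
  pops <- unique(s$population)
  demo_seeds <- derive_seeds(seeds[5L], 2L * length(pops))
  demo <- list()
  for (i in seq_along(pops)) {
    ids <- s$sample_id[s$population == pops[i]]
    sub <- subset_alignment(resc$alignment, ids)
    if (n_sequences(sub) < max(2L, min_n)) next
    nt <- neutrality_tests(sub, n_reps = n_coal_sims,
                           seed = demo_seeds[2L * i - 1L])
    fit <- fit_expansion(mismatch_observed(sub))
    bt <- if (n_boot > 0) {
      bootstrap_mismatch_tests(fit, n = n_sequences(sub), L = sub$length,
                               n_reps = n_boot, seed = demo_seeds[2L * i])
    } else {
      list(p_ssd = NA_real_, p_rag = NA_real_)
    }
    demo[[pops[i]]] <- list(neutrality = nt, fit = fit, boot = bt)
  }
  if (length(demo)) {
    demo_tab <- do.call(rbind, lapply(names(demo), function(p) {
      x <- demo[[p]]
      data.frame(
        population = p, n = x$neutrality$n, S = x$neutrality$S,
        # monomorphic populations: statistic undefined, rendered 0 with p = 1
        tajima_d = ifelse(is.na(x$neutrality$tajima_d), 0,
                          x$neutrality$tajima_d),
        p_d = x$neutrality$p_d,
        fu_fs = ifelse(is.na(x$neutrality$fu_fs), 0, x$neutrality$fu_fs),
        p_fs = x$neutrality$p_fs,
        ssd = x$fit$ssd, p_ssd = x$boot$p_ssd,
        raggedness = x$fit$raggedness, p_rag = x$boot$p_rag,
        theta0 = x$fit$theta0, theta1 = x$fit$theta1, tau = x$fit$tau,
        stringsAsFactors = FALSE
      )
    }))
    write_report(demo_tab, out_dir, "neutrality_mismatch")
    spectra <- do.call(rbind, lapply(names(demo), function(p) {
      x <- demo[[p]]
      data.frame(population = p,
                 differences = as.integer(names(x$fit$observed)),
                 observed = as.numeric(x$fit$observed),
                 expected = as.numeric(x$fit$expected))
    }))
    write_report(spectra, out_dir, "mismatch_spectra", digits = 6)
  }

  island <- NULL
  if (!is.null(fst_mt)) {
    island <- mu_over_ms(resc$amova$phi_st, fst_mt)
    write_report(data.frame(fst_cp = island$fst_cp, fst_mt = island$fst_mt,
                            mu_over_ms = island$mu_over_ms),
                 out_dir, "island_model")
  }

  manifest <- list(
    package = "plastidpop",
    version = as.character(utils::packageVersion("plastidpop")),
    seed = seed, n_perm = n_perm, n_coal_sims = n_coal_sims,
    n_boot = n_boot,
    inputs = c(locus1 = locus1_path, locus2 = locus2_path,
               samples = samples_path),
    n_samples = nrow(s), n_populations = length(pops)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(locus1 = res1, locus2 = res2, concatenated = resc,
                 ibd = ibd, elevation_correlations = elev,
                 neutrality = demo, island_model = island,
                 manifest = manifest))
}
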