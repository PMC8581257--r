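#' Replicated comparison of pBLUP, GBLUP and ssGBLUP
#'
#' Simulates `n_replicates` herd data sets and cross-validates four
#' evaluations on each, mirroring the two real-data designs:
#' * `ALL` — every phenotyped cow, with the genotyped subset revealed:
#'   pBLUP and ssGBLUP;
#' * `GENO` — only cows that are both phenotyped and genotyped:
#'   pBLUP and GBLUP.
#' All four share the same pedigree `A^{-1}`, and the genomic structures
#' are built once per replicate.
#'
#' @param n_replicates Number of simulated replicates.
#' @param sim_cfg A [sim_config()].
#' @param cfg A [run_config()] (h2, repeatability, QC thresholds, blend).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param verbose Log per-replicate progress.
#' @return Data frame with one row per replicate x dataset x method:
#'   `replicate`, `dataset`, `method`, `accuracy`, `slope` (fold means).
#' @export
method_comparison <- function(n_replicates = 10, sim_cfg = sim_config(),
                              cfg = run_config(), seed = 1L,
                              verbose = TRUE) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_herd(sim_cfg, seed = seed + r)
    matrices <- build_relationships(sim$pedigree, sim$genotypes_revealed,
                                    cfg)
    all_rec <- sim$records
    geno_rec <- geno_subset(sim)
    runs <- list(list(dataset = "ALL", method = "pblup", rec = all_rec),
                 list(dataset = "ALL", method = "ssgblup", rec = all_rec),
                 list(dataset = "GENO", method = "pblup", rec = geno_rec),
                 list(dataset = "GENO", method = "gblup", rec = geno_rec))
    rows <- lapply(runs, function(run) {
      rep_ <- run_cross_validation(run$rec, run$method, cfg,
                                   matrices = matrices)
      data.frame(replicate = r, dataset = run$dataset,
                 method = run$method,
                 accuracy = rep_$summary$accuracy_mean,
                 slope = rep_$summary$slope_mean)
    })
    out[[r]] <- do.call(rbind, rows)
    if (verbose) {
      hb_log("method_comparison: replicate %d/%d done", r, n_replicates)
    }
  }
  do.call(rbind, out)
}
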