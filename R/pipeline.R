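#' Run the full drug-prescription pipeline
#'
#' Orchestrates the stages in dependency order on in-memory inputs:
#' CNS construction (case-control GSEA per cancer), generality scoring,
#' MoA consensus classification with generality-based reassignment,
#' prognostic screening (ssGSEA + optimal-cutoff log-rank scan), PNS
#' computation over the perturbation library, and triplet-network assembly.
#' All stage thresholds default to the method's canonical values:
#' significance p < 0.05, prognostic p < 0.001, |CNS| > 1.5, 1000
#' permutations, 500 consensus resamples at 80%. Every artifact is written
#' to `outdir` and the applied thresholds are recorded in a run log.
#'
#' @param cohorts Named list of [expression_matrix()] per cancer.
#' @param sets A [gene_set_collection()].
#' @param clinical_tables Named list of [clinical_table()] per cancer
#'   (NULL skips the prognostic and prescription stages with an error if
#'   prescription is requested).
#' @param profiles List of [perturbation_profile()] (NULL skips PNS and
#'   the network).
#' @param outdir Output directory (created if missing).
#' @param n_perm GSEA permutation trials (default 1000).
#' @param alpha Significance level for generality weights (default 0.05).
#' @param p_threshold Prognostic log-rank threshold (default 0.001).
#' @param min_group_frac Minimum stratum fraction in the cutoff scan.
#' @param cns_abs_threshold Network |CNS| threshold (default 1.5).
#' @param n_resample,subsample Consensus clustering parameters
#'   (default 500, 0.8).
#' @param seed Integer seed controlling every stochastic stage.
#' @return Invisible list with all artifacts (cns, generality, moa,
#'   prognostic, pns, triplets and file paths).
#' @export
run_cdp_pipeline <- function(cohorts, sets, clinical_tables = NULL,
                             profiles = NULL, outdir = tempfile("cdp_run_"),
                             n_perm = 1000L, alpha = 0.05,
                             p_threshold = 0.001, min_group_frac = 0.1,
                             cns_abs_threshold = 1.5, n_resample = 500L,
                             subsample = 0.8, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("cdprx pipeline, seed=%d\n", seed), file = log_path)
  logf("thresholds: significance p<%.3g, prognostic p<%.3g, |CNS|>%.3g, n_perm=%d, consensus %dx%.0f%%",
       alpha, p_threshold, cns_abs_threshold, n_perm, n_resample, 100 * subsample)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cns <- stage("cns", compute_cns(cohorts, sets, n_perm = n_perm, seed = seed))
  write_score_matrix(cns, file.path(outdir, "cns.tsv"))
  logf("cns: %d pathways x %d cancers", nrow(cns$nes), ncol(cns$nes))

  gen <- stage("generality", {
    w <- significance_weights(cns, alpha = alpha)
    generality_score(build_rank_matrix(cns), w)
  })
  utils::write.table(gen, file.path(outdir, "generality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  moa <- stage("moa", {
    m <- classify_moa(cns, n_resample = n_resample, subsample = subsample,
                      seed = seed)
    reassign_moa(m, gen)
  })
  utils::write.table(moa, file.path(outdir, "moa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  prognostic <- NULL
  if (!is.null(clinical_tables)) {
    prognostic <- stage("prognostic",
      prognostic_screen(cohorts, sets, clinical_tables,
                        p_threshold = p_threshold,
                        min_group_frac = min_group_frac))
    utils::write.table(prognostic, file.path(outdir, "prognostic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("prognostic: %d (pathway, cancer) pairs below p<%.3g",
         nrow(prognostic), p_threshold)
  }

  pns <- triplets <- NULL
  if (!is.null(profiles)) {
    if (is.null(prognostic))
      stop("stage 'prescription' failed: prognostic filter unavailable ",
           "(no clinical tables supplied)", call. = FALSE)
    pns <- stage("pns", compute_pns(profiles, sets, n_perm = n_perm,
                                    seed = seed))
    write_score_matrix(pns, file.path(outdir, "pns.tsv"))
    triplets <- stage("prescribe",
      build_triplet_network(cns, pns, prognostic,
                            cns_abs_threshold = cns_abs_threshold))
    export_triplet_network(triplets, file.path(outdir, "triplets.tsv"),
                           "edge_table")
    export_triplet_network(triplets, file.path(outdir, "triplets.sif"), "sif")
    logf("network: %d triplets", nrow(triplets))
  }

  invisible(list(cns = cns, generality = gen, moa = moa,
                 prognostic = prognostic, pns = pns, triplets = triplets,
                 outdir = outdir))
}
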