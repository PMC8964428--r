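#' Construct a perturbation (drug) profile
#'
#' One instance = one cell line treated with a drug at a dose plus its
#' untreated control, summarized as a treated-versus-control ranked gene
#' list.
#'
#' @param drug_id Drug identifier.
#' @param instance_id Instance identifier.
#' @param ranked A [ranked_list()] of the treated-vs-control differential
#'   metric.
#' @return An object of class `PerturbationProfile`.
#' @export
perturbation_profile <- function(drug_id, instance_id, ranked) {
  stopifnot(inherits(ranked, "RankedList"))
  structure(list(drug_id = as.character(drug_id),
                 instance_id = as.character(instance_id), ranked = ranked),
            class = "PerturbationProfile")
}

#' NES of a pathway on a drug instance's ranked list
#'
#' GSEA of the pathway gene set against the instance's treated-vs-control
#' ranking, with a gene-set permutation null. A positive NES means the
#' drug pushes the pathway's genes up; a drug reverses an enriched cancer
#' pathway when its NES is negative.
#'
#' @param profile A [perturbation_profile()].
#' @param gene_set Character vector of gene ids.
#' @param n_perm Permutation trials (default 1000).
#' @param seed Integer seed.
#' @return As [nes_and_significance()].
#' @export
drug_pathway_nes <- function(profile, gene_set, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(profile, "PerturbationProfile"))
  nes_and_significance(profile$ranked, gene_set, n_perm = n_perm, seed = seed)
}

#' Aggregate per-instance NES values into a drug-level PNS
#'
#' Unweighted arithmetic mean over all instances of a drug, regardless of
#' cell line.
#'
#' @param per_instance_nes Numeric vector of instance NES values (>= 1).
#' @return The mean (numeric scalar).
#' @export
aggregate_instances <- function(per_instance_nes) {
  if (length(per_instance_nes) == 0L) stop("no instance NES values")
  mean(per_instance_nes)
}

#' Drugs x pathways PNS matrix
#'
#' Scores every pathway against every instance's ranked list and averages
#' instances within each drug.
#'
#' @param profiles List of [perturbation_profile()] objects.
#' @param sets A [gene_set_collection()].
#' @param n_perm Permutation trials per (instance, set).
#' @param seed Integer seed.
#' @return A [score_matrix()], drugs x pathways (NES layer only).
#' @export
compute_pns <- function(profiles, sets, n_perm = 1000L, seed = NULL) {
  stopifnot(length(profiles) >= 1L, inherits(sets, "GeneSetCollection"))
  if (!is.null(seed)) set.seed(seed)
  drugs <- vapply(profiles, `[[`, character(1), "drug_id")
  drug_ids <- unique(drugs)
  nes <- matrix(NA_real_, length(drug_ids), length(sets),
                dimnames = list(drug_ids, names(sets)))
  for (d in drug_ids) {
    inst <- profiles[drugs == d]
    per_set <- sapply(names(sets), function(pw) {
      vapply(inst, function(pr) {
        r <- pr$ranked
        es <- enrichment_score(r, sets[[pw]])
        k <- sum(r$gene_ids %in% sets[[pw]])
        null_es <- .null_es_geneset(abs(r$metric), k, n_perm)
        .nes_from_null(es, null_es)$nes
      }, numeric(1))
    })
    per_set <- matrix(per_set, nrow = length(inst))
    nes[d, ] <- apply(per_set, 2L, aggregate_instances)
  }
  score_matrix(nes)
}

#' Prescription score of a drug against a dysregulated pathway
#'
#' PS = CNS - PNS (signed). A drug whose perturbation NES opposes the
#' cancer's dysregulation gets a PS of large magnitude and the same sign
#' as the CNS; reversal potency ranks by |PS| within an effect class.
#' `effect` is `"Enrichment"` when the pathway is enriched in the cancer
#' (CNS > 0), `"Depletion"` otherwise.
#'
#' @param cns_value CNS of the pathway in the cancer.
#' @param pns_value PNS of the drug for the pathway.
#' @return List with `ps`, `effect`.
#' @export
prescription_score <- function(cns_value, pns_value) {
  stopifnot(is.finite(cns_value), is.finite(pns_value))
  list(ps = cns_value - pns_value,
       effect = if (cns_value > 0) "Enrichment" else "Depletion")
}

#' Build the filtered drug-pathway-cancer triplet network
#'
#' For each (cancer, pathway) with the pathway prognostic in that cancer
#' (log-rank p < p_threshold) and |CNS| strictly above
#' `cns_abs_threshold`, every drug whose prescription score opposes the
#' dysregulation (sign(PS) = sign(CNS)) contributes a triplet. Triplets
#' are ranked by |PS| within each (cancer, pathway); `top_k` keeps the
#' strongest reversers. Drugs whose PNS sign opposes the CNS sign are
#' labeled true `reverser`s; same-sign drugs with smaller magnitude are
#' retained but rank low.
#'
#' @param cns A [score_matrix()] (pathways x cancers).
#' @param pns A [score_matrix()] (drugs x pathways).
#' @param prognostic Data frame from [prognostic_screen()].
#' @param cns_abs_threshold Minimum |CNS| (default 1.5, strict).
#' @param top_k Keep at most this many drugs per (cancer, pathway)
#'   (default Inf).
#' @return Data frame (drug, pathway, cancer, ps, cns, pns, logrank_p,
#'   reverser), sorted by cancer, pathway, then decreasing |PS|.
#' @export
build_triplet_network <- function(cns, pns, prognostic,
                                  cns_abs_threshold = 1.5, top_k = Inf) {
  stopifnot(inherits(cns, "ScoreMatrix"), inherits(pns, "ScoreMatrix"))
  empty <- data.frame(drug = character(), pathway = character(),
                      cancer = character(), ps = numeric(), cns = numeric(),
                      pns = numeric(), logrank_p = numeric(),
                      reverser = logical(), stringsAsFactors = FALSE)
  if (nrow(prognostic) == 0L) return(empty)
  shared <- intersect(rownames(cns$nes), colnames(pns$nes))
  rows <- list()
  for (i in seq_len(nrow(prognostic))) {
    pw <- prognostic$pathway[i]; ca <- prognostic$cancer[i]
    if (!(pw %in% shared) || !(ca %in% colnames(cns$nes))) next
    cv <- cns$nes[pw, ca]
    if (!(abs(cv) > cns_abs_threshold)) next
    pv <- pns$nes[, pw]
    ps <- cv - pv
    keep <- sign(ps) == sign(cv) & ps != 0
    if (!any(keep)) next
    df <- data.frame(drug = rownames(pns$nes)[keep], pathway = pw,
                     cancer = ca, ps = ps[keep], cns = cv, pns = pv[keep],
                     logrank_p = prognostic$p[i],
                     reverser = sign(pv[keep]) == -sign(cv),
                     stringsAsFactors = FALSE)
    df <- df[order(-abs(df$ps)), , drop = FALSE]
    if (is.finite(top_k)) df <- utils::head(df, top_k)
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
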