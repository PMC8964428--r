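#' Rank genes of a case/control cohort by a differential metric
#'
#' Signal-to-noise is the GSEA default for case/control designs:
#' (mean_case - mean_control) / (sd_case + sd_control), with each group's sd
#' floored at max(0.2 * |group mean|, 0.2) so zero-variance genes cannot
#' produce infinite metrics. For cohorts with a single sample in either
#' class the signal-to-noise metric is undefined; use the log2 fold change
#' of (mean + 1) instead.
#'
#' @param expr An [expression_matrix()].
#' @param metric `"signal_to_noise"` or `"log2_fold_change"`.
#' @return A [ranked_list()], genes sorted descending by the metric (ties
#'   broken by gene id).
#' @export
rank_genes <- function(expr, metric = c("signal_to_noise", "log2_fold_change")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  metric <- match.arg(metric)
  case <- expr$values[, expr$condition == "case", drop = FALSE]
  ctrl <- expr$values[, expr$condition == "control", drop = FALSE]
  m <- .rank_metric(case, ctrl, metric)
  ranked_list(rownames(expr$values), m)
}

# metric vector for a case/control split; used by rank_genes and the
# phenotype-permutation null
.rank_metric <- function(case, ctrl, metric) {
  if (metric == "signal_to_noise") {
    if (ncol(case) < 2L || ncol(ctrl) < 2L)
      stop("signal_to_noise needs >= 2 samples per class; ",
           "use metric = \"log2_fold_change\"")
    mc <- rowMeans(case); mn <- rowMeans(ctrl)
    sc <- apply(case, 1L, stats::sd); sn <- apply(ctrl, 1L, stats::sd)
    sc <- pmax(sc, pmax(0.2 * abs(mc), 0.2))
    sn <- pmax(sn, pmax(0.2 * abs(mn), 0.2))
    (mc - mn) / (sc + sn)
  } else {
    log2(rowMeans(case) + 1) - log2(rowMeans(ctrl) + 1)
  }
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score, computed from
# the positions of the set members ("hits") in the ranked list. Hits step
# the running sum up by |metric|^1 normalized over the set; misses step it
# down by 1/(N - k). The extrema of the running sum occur only immediately
# before and after hit positions, so the score is O(k) per set given the
# hit positions -- this is what makes permutation nulls affordable.
.es_from_positions <- function(abs_metric_ranked, hit_pos, n) {
  k <- length(hit_pos)
  w <- abs_metric_ranked[hit_pos]
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / k, k)
  miss <- 1 / (n - k)
  cw <- cumsum(w)
  deficit <- (hit_pos - seq_len(k)) * miss
  after <- cw - deficit
  before <- c(0, cw[-k]) - deficit
  # interleave in list order (before hit 1, after hit 1, before hit 2, ...);
  # when the positive and negative extrema tie in magnitude (within float
  # noise) the earliest extremum along the list wins, deterministically
  vals <- as.vector(rbind(before, after))
  i_max <- which.max(vals); i_min <- which.min(vals)
  vmax <- vals[i_max]; vmin <- vals[i_min]
  if (abs(vmax) - abs(vmin) > 1e-9) vmax
  else if (abs(vmin) - abs(vmax) > 1e-9) vmin
  else if (i_max < i_min) vmax else vmin
}

#' GSEA enrichment score of a gene set on a ranked list
#'
#' Signed maximum deviation of the weighted Kolmogorov-Smirnov running sum
#' (weight exponent 1): walking down the ranked list, genes in the set
#' increment the sum by their normalized |metric|, genes outside decrement
#' it by 1/(N - |set|). The score lies in \[-1, 1\].
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of gene ids.
#' @return The enrichment score (numeric scalar).
#' @export
enrichment_score <- function(ranked, gene_set) {
  stopifnot(inherits(ranked, "RankedList"))
  gene_set <- unique(gene_set)
  pos <- which(ranked$gene_ids %in% gene_set)
  n <- length(ranked$gene_ids)
  if (length(pos) == 0L) stop("gene set has no measured members")
  if (length(pos) == n) stop("gene set covers the entire ranked list")
  .es_from_positions(abs(ranked$metric), pos, n)
}

# null ES values by gene-set permutation: random position sets of size k
.null_es_geneset <- function(abs_metric, k, n_perm) {
  n <- length(abs_metric)
  vapply(seq_len(n_perm), function(i) {
    .es_from_positions(abs_metric, sort.int(sample.int(n, k)), n)
  }, numeric(1))
}

# NES + empirical p from an observed ES and its permutation null.
# NES normalizes by the mean |null ES| of matching sign (GSEA 2005
# convention); the empirical p carries a +1/+1 pseudo-count so a finite
# permutation count never reports p = 0.
.nes_from_null <- function(es, null_es) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) == 0L || mean(abs(same)) == 0) {
    return(list(nes = NA_real_, p_emp = NA_real_, flagged = TRUE))
  }
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p_emp = p, flagged = FALSE)
}

#' Normalized enrichment score and empirical significance
#'
#' Builds a permutation null for a gene set on a ranked list (gene-set
#' permutation: random sets of the same size drawn from the list), then
#' normalizes the observed enrichment score by the mean |null ES| of the
#' matching sign and reports the empirical p with a +1/+1 pseudo-count.
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of gene ids.
#' @param n_perm Number of permutation trials (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param es Optional precomputed observed enrichment score.
#' @return List with `es`, `nes`, `p_emp`, `flagged` (TRUE when no null
#'   values of matching sign exist so the NES is undefined).
#' @export
nes_and_significance <- function(ranked, gene_set, n_perm = 1000L, seed = NULL,
                                 es = NULL) {
  stopifnot(n_perm >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(es)) es <- enrichment_score(ranked, gene_set)
  k <- sum(ranked$gene_ids %in% unique(gene_set))
  null_es <- .null_es_geneset(abs(ranked$metric), k, n_perm)
  out <- .nes_from_null(es, null_es)
  c(list(es = es), out)
}

#' Compute the cancer NES (CNS) matrix over a list of cohorts
#'
#' For each cancer cohort, genes are ranked case-versus-control and every
#' gene set is scored by GSEA; NES, empirical p and Benjamini-Hochberg FDR
#' (across sets, within each cancer) are assembled into a pathways x cancers
#' [score_matrix()]. The permutation null is phenotype permutation (class
#' labels reshuffled, metric recomputed) when both classes have at least
#' `min_phenotype_n` samples, otherwise gene-set permutation — small paired
#' cohorts (3-6 per class) cannot support 1000 distinct phenotype
#' relabelings.
#'
#' @param cohorts Named list of [expression_matrix()] objects, one per
#'   cancer; names become column names.
#' @param sets A [gene_set_collection()]; filtered to the genes shared by
#'   all cohorts (sets retaining < `min_set_size` genes are dropped).
#' @param metric Ranking metric, see [rank_genes()].
#' @param scheme `"auto"`, `"phenotype"` or `"gene_set"` permutation.
#' @param n_perm Permutation trials per cancer (default 1000).
#' @param seed Integer seed.
#' @param min_phenotype_n Minimum per-class size for phenotype permutation
#'   under `"auto"` (default 7).
#' @param min_set_size Minimum measured genes per set (default 2).
#' @return A [score_matrix()] (sets x cancers) with `p` and `fdr` layers.
#' @export
compute_cns <- function(cohorts, sets, metric = "signal_to_noise",
                        scheme = c("auto", "phenotype", "gene_set"),
                        n_perm = 1000L, seed = NULL, min_phenotype_n = 7L,
                        min_set_size = 2L) {
  scheme <- match.arg(scheme)
  stopifnot(length(cohorts) >= 1L, inherits(sets, "GeneSetCollection"))
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cancer", seq_along(cohorts))
  universe <- Reduce(intersect, lapply(cohorts, function(e) rownames(e$values)))
  sets <- filter_gene_sets(sets, universe, min_size = min_set_size)
  set_names <- names(sets)
  nes <- p <- matrix(NA_real_, length(set_names), length(cohorts),
                     dimnames = list(set_names, names(cohorts)))
  # per-cohort seed keyed to the cohort name (not its position), so
  # reordering the cohort list only permutes the columns
  cohort_seed <- if (is.null(seed)) rep(list(NULL), length(cohorts)) else
    as.list(seed + match(names(cohorts), sort(names(cohorts))))
  for (j in seq_along(cohorts)) {
    if (!is.null(cohort_seed[[j]])) set.seed(cohort_seed[[j]])
    res <- .cohort_enrichment(cohorts[[j]], sets, metric, scheme, n_perm,
                              min_phenotype_n)
    nes[, j] <- res$nes
    p[, j] <- res$p
  }
  fdr <- matrix(apply(p, 2L, stats::p.adjust, method = "BH"),
                nrow = nrow(p), dimnames = dimnames(p))
  score_matrix(nes, p, fdr)
}

# enrichment of all sets on one cohort, with the chosen permutation null
.cohort_enrichment <- function(expr, sets, metric, scheme, n_perm,
                               min_phenotype_n) {
  n_case <- sum(expr$condition == "case")
  n_ctrl <- sum(expr$condition == "control")
  use_pheno <- switch(scheme,
    phenotype = TRUE,
    gene_set = FALSE,
    auto = min(n_case, n_ctrl) >= min_phenotype_n)
  if (use_pheno && min(n_case, n_ctrl) < 2L) {
    warning("fewer than 2 samples per class: falling back to gene-set permutation")
    use_pheno <- FALSE
  }
  genes <- rownames(expr$values)
  set_idx <- lapply(unclass(sets), function(g) which(genes %in% g))
  ranked <- rank_genes(expr, metric)
  rank_pos <- match(ranked$gene_ids, genes)
  inv <- integer(length(genes)); inv[rank_pos] <- seq_along(genes)
  abs_obs <- abs(ranked$metric)
  n <- length(genes)
  es_obs <- vapply(set_idx, function(ix)
    .es_from_positions(abs_obs, sort.int(inv[ix]), n), numeric(1))

  if (use_pheno) {
    null_es <- .null_es_phenotype(expr, set_idx, metric, n_perm)
  } else {
    sizes <- lengths(set_idx)
    null_by_size <- lapply(unique(sizes), function(k)
      .null_es_geneset(abs_obs, k, n_perm))
    names(null_by_size) <- as.character(unique(sizes))
    null_es <- lapply(sizes, function(k) null_by_size[[as.character(k)]])
  }
  stats_out <- Map(.nes_from_null, es_obs, null_es)
  list(nes = vapply(stats_out, `[[`, numeric(1), "nes"),
       p = vapply(stats_out, `[[`, numeric(1), "p_emp"))
}

# phenotype-permutation null: reshuffle class labels, recompute the metric,
# re-sort, and rescore every set against the permuted ranking
.null_es_phenotype <- function(expr, set_idx, metric, n_perm) {
  X <- expr$values
  n <- nrow(X)
  n_case <- sum(expr$condition == "case")
  null_es <- matrix(NA_real_, length(set_idx), n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(ncol(X), n_case)
    m <- .rank_metric(X[, idx, drop = FALSE], X[, -idx, drop = FALSE], metric)
    o <- order(-m, rownames(X), method = "radix")
    inv <- integer(n); inv[o] <- seq_len(n)
    am <- abs(m[o])
    null_es[, b] <- vapply(set_idx, function(ix)
      .es_from_positions(am, sort.int(inv[ix]), n), numeric(1))
  }
  lapply(seq_along(set_idx), function(i) null_es[i, ])
}

#' Single-sample (ssGSEA) pathway activation score
#'
#' Rank-based activation of a gene set within one sample: genes are ranked
#' by expression, and the score sums, over all ranked positions, the gap
#' between the weighted empirical CDF of set members (weights = rank^alpha,
#' higher expression = higher rank) and the unweighted CDF of non-members.
#' Depends only on within-sample ranks, so any monotone rescaling of the
#' expression vector leaves the score unchanged.
#'
#' @param expr_sample Named numeric vector: expression values of one sample.
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank weighting exponent (default 0.25).
#' @return The activation score (numeric scalar).
#' @export
ssgsea_score <- function(expr_sample, gene_set, alpha = 0.25) {
  stopifnot(alpha >= 0, !is.null(names(expr_sample)))
  if (length(unique(expr_sample)) == 1L)
    stop("constant expression vector: ranks undefined")
  gene_set <- unique(gene_set)
  n <- length(expr_sample)
  in_set <- names(expr_sample) %in% gene_set
  if (!any(in_set)) stop("sample covers no gene-set member")
  if (all(in_set)) stop("gene set covers the entire sample")
  o <- order(-expr_sample, names(expr_sample), method = "radix")
  in_set <- in_set[o]
  r <- (n:1)^alpha            # rank weight, highest expression first
  w_in <- ifelse(in_set, r, 0)
  cdf_in <- cumsum(w_in) / sum(w_in)
  cdf_out <- cumsum(!in_set) / sum(!in_set)
  sum(cdf_in - cdf_out)
}

#' Pathway-activation score matrix for a cohort
#'
#' Applies [ssgsea_score()] to every (sample, set) pair of an expression
#' matrix; used to feed the prognostic cutoff scan.
#'
#' @param expr An [expression_matrix()] (typically tumor samples only).
#' @param sets A [gene_set_collection()].
#' @param alpha Rank weighting exponent.
#' @return Numeric matrix, sets x samples.
#' @export
pa_score_matrix <- function(expr, sets, alpha = 0.25) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(sets, "GeneSetCollection"))
  out <- matrix(NA_real_, length(sets), ncol(expr$values),
                dimnames = list(names(sets), colnames(expr$values)))
  for (j in seq_len(ncol(expr$values))) {
    v <- expr$values[, j]
    names(v) <- rownames(expr$values)
    for (i in seq_along(sets)) out[i, j] <- ssgsea_score(v, sets[[i]], alpha)
  }
  out
}
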