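#' Rank cancers within each pathway by NES
#'
#' For each pathway (row), the n cancers are sorted ascending by NES and
#' assigned ranks 1..n (rank 1 = most depleted). Ties are broken by cancer
#' label order (stable), so each row is a permutation of 1..n.
#'
#' @param cns A [score_matrix()] (pathways x cancers).
#' @return Integer matrix of ranks, same dimnames as the NES layer.
#' @export
build_rank_matrix <- function(cns) {
  stopifnot(inherits(cns, "ScoreMatrix"))
  if (anyNA(cns$nes)) stop("NES layer contains missing values")
  r <- matrix(0L, nrow(cns$nes), ncol(cns$nes), dimnames = dimnames(cns$nes))
  for (i in seq_len(nrow(r))) {
    x <- cns$nes[i, ]
    o <- order(x, seq_along(x), method = "radix")
    r[i, o] <- seq_along(x)
  }
  r
}

#' Count significantly enriched / depleted cancers per pathway
#'
#' Significant enrichment of a pathway in a cancer requires NES > 0 and
#' empirical p < alpha; significant depletion requires NES < 0 and
#' p < alpha. The counts w1 (enriched) and w2 (depleted) weight the
#' generality statistics, and the logical masks select which cancers enter
#' the sums.
#'
#' @param cns A [score_matrix()] with a `p` layer.
#' @param alpha Significance level (default 0.05).
#' @return List with integer vectors `w1`, `w2` and logical matrices
#'   `enriched`, `depleted` (pathways x cancers).
#' @export
significance_weights <- function(cns, alpha = 0.05) {
  stopifnot(inherits(cns, "ScoreMatrix"))
  if (is.null(cns$p)) stop("score matrix has no p layer")
  enr <- cns$nes > 0 & cns$p < alpha
  dep <- cns$nes < 0 & cns$p < alpha
  enr[is.na(enr)] <- FALSE
  dep[is.na(dep)] <- FALSE
  list(w1 = rowSums(enr), w2 = rowSums(dep), enriched = enr, depleted = dep)
}

#' Pan-cancer generality score of each pathway
#'
#' For pathway i with cancer ranks r_ik (ascending NES, 1..n) and
#' significance counts w1 (enriched), w2 (depleted):
#' a_i = w1/(w1+w2) * sum over significantly enriched cancers of r_ik / n,
#' b_i = w2/(w1+w2) * sum over significantly depleted cancers of
#' -(1 - (r_ik - 1)/n). The score S_i is a_i if |a_i| > |b_i|, b_i if
#' |a_i| < |b_i|, and 0 if |a_i| = |b_i| (including pathways nowhere
#' significant, w1 + w2 = 0). |S_i| is bounded by (n+1)/2, attained when a
#' pathway is significant in all n cancers.
#'
#' @param ranks Rank matrix from [build_rank_matrix()].
#' @param weights Output of [significance_weights()].
#' @return Data frame (pathway, a, b, w1, w2, s).
#' @export
generality_score <- function(ranks, weights) {
  n <- ncol(ranks)
  m <- nrow(ranks)
  stopifnot(identical(dim(weights$enriched), dim(ranks)))
  a <- b <- s <- numeric(m)
  for (i in seq_len(m)) {
    w1 <- weights$w1[[i]]; w2 <- weights$w2[[i]]
    if (w1 + w2 == 0L) { a[i] <- 0; b[i] <- 0; s[i] <- 0; next }
    r <- ranks[i, ]
    a[i] <- w1 / (w1 + w2) * sum(r[weights$enriched[i, ]] / n)
    b[i] <- w2 / (w1 + w2) * sum(-(1 - (r[weights$depleted[i, ]] - 1) / n))
    s[i] <- if (abs(a[i]) > abs(b[i])) a[i]
            else if (abs(a[i]) < abs(b[i])) b[i]
            else 0
  }
  data.frame(pathway = rownames(ranks), a = a, b = b,
             w1 = as.integer(weights$w1), w2 = as.integer(weights$w2),
             s = s, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify pathway modes of action by consensus clustering
#'
#' Pathways are partitioned into k = 3 clusters on their NES profile across
#' cancers: consensus is accumulated over `n_resample` subsamplings of
#' `subsample` of the pathways, each clustered by agglomerative
#' hierarchical clustering (Euclidean distance, average linkage); the final
#' partition cuts a hierarchical clustering of 1 - consensus at k. Clusters
#' are labeled by their median NES across cancers: most negative = LoF
#' (loss of function), most positive = GoF (gain of function), the
#' remainder SoF (switch of function). Pathways whose NES standard
#' deviation falls below `sd_min` are held out of the consensus and
#' assigned afterwards to the nearest cluster centroid.
#'
#' @param cns A [score_matrix()] (pathways x cancers).
#' @param k Number of clusters (default 3).
#' @param n_resample Number of subsamplings (default 500).
#' @param subsample Fraction of pathways per subsample (default 0.8).
#' @param seed Integer seed.
#' @param sd_min Minimum per-pathway NES standard deviation to enter the
#'   consensus (default 1.0).
#' @return Data frame (pathway, cluster in LoF/SoF/GoF, consensus_fraction,
#'   filtered).
#' @export
classify_moa <- function(cns, k = 3L, n_resample = 500L, subsample = 0.8,
                         seed = NULL, sd_min = 1.0) {
  stopifnot(inherits(cns, "ScoreMatrix"))
  X <- cns$nes
  if (k > nrow(X)) stop("k exceeds the number of pathways")
  if (!is.null(seed)) set.seed(seed)
  sds <- apply(X, 1L, stats::sd)
  core <- which(sds > sd_min)
  if (length(core) < k) core <- seq_len(nrow(X))  # too few variable pathways
  Xc <- X[core, , drop = FALSE]
  m <- nrow(Xc)
  n_sub <- max(k, floor(subsample * m))
  hits <- cooc <- matrix(0, m, m)
  for (b in seq_len(n_resample)) {
    idx <- if (n_sub >= m) seq_len(m) else sort.int(sample.int(m, n_sub))
    cl <- stats::cutree(stats::hclust(stats::dist(Xc[idx, , drop = FALSE]),
                                      method = "average"), k = k)
    same <- outer(cl, cl, "==") * 1
    hits[idx, idx] <- hits[idx, idx] + 1
    cooc[idx, idx] <- cooc[idx, idx] + same
  }
  consensus <- ifelse(hits > 0, cooc / hits, 0)
  diag(consensus) <- 1
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  cl <- stats::cutree(hc, k = k)
  # per-pathway mean co-clustering fraction with its own cluster
  cons_frac <- vapply(seq_len(m), function(i) {
    mates <- which(cl == cl[i] & seq_len(m) != i)
    if (!length(mates)) 1 else mean(consensus[i, mates])
  }, numeric(1))
  centroids <- do.call(rbind, lapply(split(seq_len(m), cl), function(ix)
    colMeans(Xc[ix, , drop = FALSE])))
  med_nes <- vapply(split(seq_len(m), cl), function(ix)
    stats::median(Xc[ix, , drop = FALSE]), numeric(1))
  lab <- rep("SoF", k)
  lab[which.min(med_nes)] <- "LoF"
  lab[which.max(med_nes)] <- "GoF"
  cluster <- lab[cl]
  out <- data.frame(pathway = rownames(X), cluster = NA_character_,
                    consensus_fraction = NA_real_,
                    filtered = !(seq_len(nrow(X)) %in% core),
                    stringsAsFactors = FALSE)
  out$cluster[core] <- cluster
  out$consensus_fraction[core] <- cons_frac
  held <- which(out$filtered)
  if (length(held)) {
    for (i in held) {
      dcent <- apply(centroids, 1L, function(cen) sum((X[i, ] - cen)^2))
      out$cluster[i] <- lab[as.integer(names(dcent)[which.min(dcent)])]
      out$consensus_fraction[i] <- 0
    }
  }
  out
}

#' Reassign pathways between LoF and GoF by generality
#'
#' A pathway clustered as LoF whose generality score is at or above
#' +threshold moves to GoF; a GoF pathway at or below -threshold moves to
#' LoF. SoF assignments are untouched. Idempotent.
#'
#' @param assignments Data frame from [classify_moa()].
#' @param generality Data frame from [generality_score()].
#' @param threshold Generality magnitude triggering reassignment
#'   (default 7).
#' @return `assignments` with updated `cluster` and a `reassigned` flag.
#' @export
reassign_moa <- function(assignments, generality, threshold = 7.0) {
  stopifnot(threshold > 0)
  s <- generality$s[match(assignments$pathway, generality$pathway)]
  to_gof <- assignments$cluster == "LoF" & !is.na(s) & s >= threshold
  to_lof <- assignments$cluster == "GoF" & !is.na(s) & s <= -threshold
  assignments$reassigned <- to_gof | to_lof
  assignments$cluster[to_gof] <- "GoF"
  assignments$cluster[to_lof] <- "LoF"
  assignments
}

#' Hypergeometric enrichment of an annotation list in a query set
#'
#' Upper-tail probability P(X >= k) of drawing at least the observed
#' overlap, with the measured gene universe as population, the annotation
#' list (restricted to the universe) as successes, and the query set as
#' draws. Used to test whether e.g. significantly mutated genes or drug
#' targets concentrate in a pathway cluster's differential genes.
#'
#' @param query_set Character vector, must lie within `universe`.
#' @param annotation Character vector (e.g. SMG or drug-target list).
#' @param universe Character vector of measured genes.
#' @return The enrichment p-value.
#' @export
hypergeometric_enrichment <- function(query_set, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query_set <- unique(query_set)
  if (!all(query_set %in% universe))
    stop("query set contains genes outside the universe")
  ann <- unique(annotation[annotation %in% universe])
  k <- length(intersect(query_set, ann))
  stats::phyper(k - 1, length(ann), length(universe) - length(ann),
                length(query_set), lower.tail = FALSE)
}

#' Cluster cancers by their pathway dysregulation profiles
#'
#' Utility mirroring the tumor-side view of the landscape: hierarchical
#' clustering of cancers with Spearman-correlation distance
#' (1 - rho) and average linkage. Deterministic given input order.
#'
#' @param cns A [score_matrix()] (pathways x cancers) or a plain numeric
#'   matrix with cancers in columns.
#' @return An `hclust` object over the cancers.
#' @export
cluster_cancers <- function(cns) {
  X <- if (inherits(cns, "ScoreMatrix")) cns$nes else cns
  rho <- stats::cor(X, method = "spearman")
  stats::hclust(stats::as.dist(1 - rho), method = "average")
}
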