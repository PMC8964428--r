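#' SAM moderated d-statistic for one gene
#'
#' Tusher-style modification of the two-sample t statistic: the pooled
#' standard error is offset by a fudge factor s0 so genes with tiny
#' variance cannot dominate. d = (mean_case - mean_control) / (s + s0) with
#' s the pooled standard error
#' sqrt((1/n1 + 1/n2) * (SS_case + SS_control) / (n1 + n2 - 2)).
#'
#' @param case_values,control_values Numeric vectors, >= 2 values each.
#' @param s0 Non-negative fudge factor (expression units).
#' @return The d statistic (numeric scalar).
#' @export
sam_statistic <- function(case_values, control_values, s0 = 0) {
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop("each group needs >= 2 values")
  stopifnot(s0 >= 0)
  .sam_d(matrix(case_values, nrow = 1), matrix(control_values, nrow = 1), s0)$d
}

# vectorized d over a genes x samples split
.sam_d <- function(case, ctrl, s0) {
  n1 <- ncol(case); n2 <- ncol(ctrl)
  mc <- rowMeans(case); mn <- rowMeans(ctrl)
  ss <- rowSums((case - mc)^2) + rowSums((ctrl - mn)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(d = (mc - mn) / (s + s0), r = mc - mn, s = s)
}

#' Select the SAM fudge factor s0
#'
#' Tusher procedure: candidate s0 values are the percentiles
#' \{0, 5, ..., 100\} of the per-gene pooled standard errors; for each
#' candidate, genes are binned into quantile windows of the standard error
#' and the spread of d (MAD/0.64) is computed per window; the s0 minimizing
#' the coefficient of variation of these spreads — i.e. making the scale of
#' d independent of the gene's standard error — is selected.
#'
#' @param r Per-gene numerator (mean difference).
#' @param s Per-gene pooled standard error (same length).
#' @param n_windows Number of SE-quantile windows (default 10).
#' @return Selected s0 (numeric scalar, >= 0).
#' @export
select_s0 <- function(r, s, n_windows = 10L) {
  stopifnot(length(r) == length(s))
  if (length(unique(s)) < 2L) {
    warning("fewer than 2 distinct standard errors: s0 = 0")
    return(0)
  }
  if (length(s) < 100L)
    warning("fewer than 100 genes: s0 selection may be unstable")
  cand <- c(0, unname(stats::quantile(s, probs = seq(0, 1, by = 0.05))))
  brk <- unique(stats::quantile(s, probs = seq(0, 1, length.out = n_windows + 1)))
  win <- cut(s, breaks = brk, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, function(x) stats::mad(x) / 0.64)
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2L) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' SAM differential expression with permutation FDR
#'
#' Computes per-gene d statistics (with s0 selected by [select_s0()] unless
#' given), a pooled permutation p-value, and a q-value from the median
#' number of null |d| values exceeding each observed |d| over label
#' permutations, monotonized so q is non-increasing in |d|.
#'
#' @param expr An [expression_matrix()] with >= 2 samples per class.
#' @param n_perm Number of label permutations (default 200; >= 100
#'   recommended). When fewer distinct label splits exist they are
#'   enumerated exhaustively.
#' @param seed Integer seed.
#' @param s0 Optional fixed fudge factor; selected from the data when NULL.
#' @param fc_pseudo Pseudo-count added to group means before the log2 fold
#'   change (default 1, avoids infinite FC at zero expression).
#' @return Data frame (gene, d, log2fc, p, q) plus attribute `s0`.
#' @export
permutation_fdr <- function(expr, n_perm = 200L, seed = NULL, s0 = NULL,
                            fc_pseudo = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!is.null(seed)) set.seed(seed)
  X <- expr$values
  is_case <- expr$condition == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  obs <- .sam_d(X[, is_case, drop = FALSE], X[, !is_case, drop = FALSE], 0)
  if (is.null(s0)) s0 <- select_s0(obs$r, obs$s)
  d_obs <- obs$r / (obs$s + s0)
  log2fc <- log2(rowMeans(X[, is_case, drop = FALSE]) + fc_pseudo) -
    log2(rowMeans(X[, !is_case, drop = FALSE]) + fc_pseudo)

  n_splits <- choose(n1 + n2, n1)
  if (n_splits <= n_perm) {
    perms <- utils::combn(n1 + n2, n1, simplify = FALSE)
  } else {
    perms <- replicate(n_perm, sample.int(n1 + n2, n1), simplify = FALSE)
  }
  abs_obs <- abs(d_obs)
  ord <- order(-abs_obs)
  # per permutation: how many null |d| exceed each observed |d| threshold
  exceed <- matrix(0L, length(d_obs), length(perms))
  sorted_obs <- abs_obs[ord]
  pooled_count <- 0
  for (b in seq_along(perms)) {
    idx <- perms[[b]]
    nd <- .sam_d(X[, idx, drop = FALSE], X[, -idx, drop = FALSE], s0)$d
    sa <- sort(abs(nd))
    # count of null |d| >= each sorted observed threshold
    exceed[, b] <- length(sa) - findInterval(sorted_obs, sa,
                                             left.open = TRUE)
    pooled_count <- pooled_count + exceed[, b]
  }
  med_fp <- apply(exceed, 1L, stats::median)
  called <- seq_along(sorted_obs)
  fdr <- pmin(1, med_fp / called)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(length(d_obs)); q[ord] <- q_sorted
  # pooled permutation p with +1/+1 pseudo-count
  p_sorted <- (1 + pooled_count) / (1 + length(perms) * length(d_obs))
  p <- numeric(length(d_obs)); p[ord] <- p_sorted
  out <- data.frame(gene = rownames(X), d = d_obs, log2fc = log2fc,
                    p = p, q = q, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  attr(out, "n_perm") <- length(perms)
  out
}

#' Filter differential-expression results into up/down signatures
#'
#' Strict thresholds, as in `|log2FC| > fc_threshold` and
#' `q < q_threshold`: a gene at exactly the fold-change threshold is
#' excluded.
#'
#' @param results Data frame with columns `gene`, `log2fc`, `q` (as from
#'   [permutation_fdr()]).
#' @param fc_threshold Absolute log2 fold-change threshold (default 2).
#' @param q_threshold FDR threshold (default 0.01).
#' @return List with `up` and `down` gene-id vectors and a `direction`
#'   column added to `results`.
#' @export
deg_filter <- function(results, fc_threshold = 2, q_threshold = 0.01) {
  stopifnot(fc_threshold > 0, q_threshold > 0)
  up <- results$log2fc > fc_threshold & results$q < q_threshold
  down <- results$log2fc < -fc_threshold & results$q < q_threshold
  results$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = results$gene[up], down = results$gene[down], results = results)
}
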