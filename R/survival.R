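#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) comparing the survival of two
#' groups, via [survival::survdiff()]. Deterministic; symmetric in the two
#' groups.
#'
#' @param time_a,event_a Times and event indicators of group A.
#' @param time_b,event_b Times and event indicators of group B.
#' @return List with `statistic` (chi-square) and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0L)
    stop("no events to compare")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Optimal-cutoff scan of a pathway-activation score against survival
#'
#' Every distinct observed PA score is tried as a threshold splitting the
#' cohort into low (PA <= cutoff) and high (PA > cutoff) strata; splits
#' leaving either stratum below `min_group_frac` of the cohort are
#' skipped. The cutoff minimizing the log-rank p is returned, ties broken
#' toward the more balanced split. Scaling all PA scores by a positive
#' constant leaves the chosen stratification unchanged.
#'
#' @param pa Named numeric vector of PA scores (names = sample ids).
#' @param clinical A [clinical_table()]; only samples present in both are
#'   used.
#' @param min_group_frac Minimum stratum size as a fraction of the cohort
#'   (default 0.1; must be in (0, 0.5)).
#' @return List with `best_cutoff`, `best_p`, `statistic`, `n_high`,
#'   `n_low`, `scanned` (number of candidate cutoffs evaluated) and
#'   `valid` (FALSE when no admissible split exists, e.g. constant PA).
#' @export
optimal_cutoff_scan <- function(pa, clinical, min_group_frac = 0.1) {
  stopifnot(min_group_frac > 0, min_group_frac < 0.5,
            inherits(clinical, "ClinicalTable"))
  common <- intersect(names(pa), clinical$sample)
  if (length(common) == 0L) stop("no samples shared between PA scores and clinical table")
  pa <- pa[common]
  cl <- clinical[match(common, clinical$sample), ]
  n <- length(pa)
  min_n <- ceiling(min_group_frac * n)
  cutoffs <- sort(unique(pa))
  cutoffs <- cutoffs[-length(cutoffs)]  # splitting above the max is empty
  no_split <- list(best_cutoff = NA_real_, best_p = NA_real_,
                   statistic = NA_real_, n_high = NA_integer_,
                   n_low = NA_integer_, scanned = 0L, valid = FALSE)
  if (length(cutoffs) == 0L || sum(cl$event) == 0L) return(no_split)
  best <- NULL
  scanned <- 0L
  for (cut in cutoffs) {
    high <- pa > cut
    if (sum(high) < min_n || sum(!high) < min_n) next
    scanned <- scanned + 1L
    lr <- logrank_test(cl$time[high], cl$event[high],
                       cl$time[!high], cl$event[!high])
    balance <- abs(sum(high) - sum(!high))
    if (is.null(best) || lr$p < best$best_p ||
        (lr$p == best$best_p && balance < best$balance)) {
      best <- list(best_cutoff = cut, best_p = lr$p, statistic = lr$statistic,
                   n_high = sum(high), n_low = sum(!high), balance = balance)
    }
  }
  if (is.null(best)) return(no_split)
  best$balance <- NULL
  c(best, list(scanned = scanned, valid = TRUE))
}

# restricted-mean survival of one stratum up to a shared horizon tau
.rmst <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, rmean = tau)
  unname(s$table["rmean"])
}

#' Classify a scanned pathway as prognostic
#'
#' A pathway is prognostic in a cancer when its optimal-cutoff log-rank p
#' is strictly below `p_threshold` (default 0.001). Direction is
#' determined by restricted-mean survival at the largest follow-up time
#' shared by both strata: `"favorable"` when the high-PA stratum survives
#' longer, `"adverse"` otherwise.
#'
#' @param scan Result of [optimal_cutoff_scan()].
#' @param pa,clinical The inputs the scan was run on.
#' @param p_threshold Significance threshold (default 0.001, strict).
#' @return `NULL` when not prognostic; otherwise a list with `p`, `cutoff`,
#'   `direction`, `n_high`, `n_low`.
#' @export
classify_prognostic <- function(scan, pa, clinical, p_threshold = 0.001) {
  if (!isTRUE(scan$valid)) return(NULL)
  if (!(scan$best_p < p_threshold)) return(NULL)
  common <- intersect(names(pa), clinical$sample)
  pa <- pa[common]
  cl <- clinical[match(common, clinical$sample), ]
  high <- pa > scan$best_cutoff
  tau <- min(max(cl$time[high]), max(cl$time[!high]))
  rm_high <- .rmst(cl$time[high], cl$event[high], tau)
  rm_low <- .rmst(cl$time[!high], cl$event[!high], tau)
  list(p = scan$best_p, cutoff = scan$best_cutoff,
       direction = if (rm_high >= rm_low) "favorable" else "adverse",
       n_high = scan$n_high, n_low = scan$n_low)
}

#' Screen all (pathway, cancer) pairs for prognostic pathways
#'
#' Computes ssGSEA PA scores for every pathway in every cancer's tumor
#' samples, runs the optimal-cutoff log-rank scan against that cancer's
#' clinical table, and keeps pairs with best p < `p_threshold`.
#'
#' @param cohorts Named list of [expression_matrix()] per cancer (case
#'   samples are scored).
#' @param sets A [gene_set_collection()].
#' @param clinical_tables Named list of [clinical_table()] aligned with
#'   `cohorts`.
#' @param p_threshold Log-rank significance threshold (default 0.001).
#' @param min_group_frac See [optimal_cutoff_scan()].
#' @param alpha ssGSEA rank-weight exponent.
#' @return Data frame (pathway, cancer, cutoff, p, direction, n_high,
#'   n_low) sorted by p, with a per-cancer scan count in attribute
#'   `n_scanned`.
#' @export
prognostic_screen <- function(cohorts, sets, clinical_tables,
                              p_threshold = 0.001, min_group_frac = 0.1,
                              alpha = 0.25) {
  stopifnot(identical(names(cohorts), names(clinical_tables)))
  rows <- list()
  n_scanned <- stats::setNames(integer(length(cohorts)), names(cohorts))
  for (cancer in names(cohorts)) {
    expr <- cohorts[[cancer]]
    tumor <- expression_subset(expr, "case")
    sets_c <- filter_gene_sets(sets, rownames(tumor$values))
    pa_mat <- pa_score_matrix(tumor, sets_c, alpha)
    for (pw in rownames(pa_mat)) {
      pa <- pa_mat[pw, ]
      scan <- optimal_cutoff_scan(pa, clinical_tables[[cancer]], min_group_frac)
      if (!scan$valid) next
      n_scanned[[cancer]] <- n_scanned[[cancer]] + 1L
      hit <- classify_prognostic(scan, pa, clinical_tables[[cancer]], p_threshold)
      if (!is.null(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw, cancer = cancer, cutoff = hit$cutoff, p = hit$p,
          direction = hit$direction, n_high = hit$n_high, n_low = hit$n_low,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway = character(), cancer = character(),
               cutoff = numeric(), p = numeric(), direction = character(),
               n_high = integer(), n_low = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scanned") <- n_scanned
  out
}

#' Subset an expression matrix to one condition
#'
#' @param expr An [expression_matrix()].
#' @param condition `"case"` or `"control"`.
#' @return A plain list with `values` (matrix) and `condition`, keeping the
#'   `ExpressionMatrix` class for downstream scoring. Note a single-class
#'   subset is no longer a valid case/control cohort and is intended only
#'   for per-sample scoring.
#' @export
expression_subset <- function(expr, condition = c("case", "control")) {
  condition <- match.arg(condition)
  keep <- expr$condition == condition
  structure(list(values = expr$values[, keep, drop = FALSE],
                 condition = expr$condition[keep]),
            class = "ExpressionMatrix")
}
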