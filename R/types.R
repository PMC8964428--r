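#' Construct an expression matrix with case/control labels
#'
#' The basic container for a paired cohort: a genes x samples numeric matrix
#' plus a per-sample condition label. "case" is tumor (or drug-treated),
#' "control" is matched normal (or vehicle).
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param condition Character vector, one of `"case"`/`"control"` per column.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (length(condition) != ncol(values))
    stop("`condition` length must equal the number of samples")
  if (!all(condition %in% c("case", "control")))
    stop("`condition` must contain only \"case\" and \"control\"")
  if (sum(condition == "case") < 1L || sum(condition == "control") < 1L)
    stop("need at least one case and one control sample")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  structure(list(values = values, condition = as.character(condition)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "case"), sum(x$condition == "control")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene ids. Gene ids are
#'   opaque, case-sensitive strings; duplicates within a set are removed
#'   preserving first occurrence.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return An object of class `GeneSetCollection` (a named list of gene-id
#'   vectors with a `descriptions` attribute).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L) stop("no gene sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene set")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Restrict gene sets to the measured gene universe
#'
#' Sets retaining fewer than `min_size` measured genes are dropped (GSEA
#' needs at least two positions to form a running sum); the number dropped
#' is reported via a message and the `n_dropped` attribute. The operation is
#' idempotent.
#'
#' @param gsc A [gene_set_collection()].
#' @param genes Character vector of measured gene ids.
#' @param min_size Minimum number of measured genes a set must retain
#'   (default 2).
#' @return Filtered `GeneSetCollection` with attribute `n_dropped`.
#' @export
filter_gene_sets <- function(gsc, genes, min_size = 2L) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  trimmed <- lapply(unclass(gsc), function(g) g[g %in% genes])
  keep <- lengths(trimmed) >= min_size
  if (!any(keep)) stop("no gene sets overlap the measured genes")
  if (any(!keep))
    message(sum(!keep), " gene set(s) dropped: fewer than ", min_size,
            " measured genes")
  out <- gene_set_collection(trimmed[keep],
                             attr(gsc, "descriptions")[names(trimmed)[keep]])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Construct a clinical survival table
#'
#' @param sample_ids Unique sample identifiers.
#' @param time Follow-up times in days (non-negative).
#' @param event Event indicator: 1 = death observed, 0 = censored.
#' @param dropped_count Number of records excluded upstream for missing
#'   survival information.
#' @return A `ClinicalTable` data frame with columns sample, time, event.
#' @export
clinical_table <- function(sample_ids, time, event, dropped_count = 0L) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stop("sample_ids, time and event must have equal length")
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  out <- data.frame(sample = sample_ids, time = as.numeric(time),
                    event = as.integer(event), stringsAsFactors = FALSE)
  attr(out, "dropped_count") <- as.integer(dropped_count)
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

#' Construct a score matrix (NES with optional significance layers)
#'
#' Holds pathways x cancers (CNS) or drugs x pathways (PNS) normalized
#' enrichment scores, optionally with aligned empirical p-value and FDR
#' matrices.
#'
#' @param nes Numeric matrix with row and column names.
#' @param p,fdr Optional matrices of the same shape, values in \[0, 1\].
#' @return An object of class `ScoreMatrix`.
#' @export
score_matrix <- function(nes, p = NULL, fdr = NULL) {
  if (!is.matrix(nes) || !is.numeric(nes)) stop("`nes` must be a numeric matrix")
  if (is.null(rownames(nes)) || is.null(colnames(nes)))
    stop("`nes` must have row and column names")
  check_layer <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!identical(dim(m), dim(nes)))
      stop("`", what, "` dimensions do not match `nes`")
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop("`", what, "` values must lie in [0, 1]")
    dimnames(m) <- dimnames(nes)
    m
  }
  structure(list(nes = nes, p = check_layer(p, "p"), fdr = check_layer(fdr, "fdr")),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d x %d NES%s%s\n", nrow(x$nes), ncol(x$nes),
              if (!is.null(x$p)) " + p" else "",
              if (!is.null(x$fdr)) " + fdr" else ""))
  invisible(x)
}

#' @export
dim.ScoreMatrix <- function(x) dim(x$nes)

#' Construct a ranked gene list
#'
#' Genes ordered by a ranking metric, descending. Ties are broken by gene id
#' (stable, deterministic).
#'
#' @param gene_ids Character vector of gene ids (unique).
#' @param metric Numeric ranking metric, same length; the list is sorted
#'   descending on it.
#' @return An object of class `RankedList`: list with `gene_ids`, `metric`.
#' @export
ranked_list <- function(gene_ids, metric) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids in ranked list")
  if (length(metric) != length(gene_ids))
    stop("metric length must match gene_ids")
  if (!all(is.finite(metric))) stop("ranking metric must be finite")
  o <- order(-metric, gene_ids, method = "radix")
  structure(list(gene_ids = gene_ids[o], metric = as.numeric(metric[o])),
            class = "RankedList")
}

#' @export
print.RankedList <- function(x, ...) {
  cat(sprintf("RankedList: %d genes, metric range [%.3g, %.3g]\n",
              length(x$gene_ids), min(x$metric), max(x$metric)))
  invisible(x)
}

#' @export
length.RankedList <- function(x) length(x$gene_ids)
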