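#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are removed preserving order.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no gene sets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(stats::setNames(sets, nm), desc)
}

#' Write gene sets to a GMT file
#'
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  desc <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, desc[[nm]], gsc[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a case/control expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids. Every
#' sample must appear in exactly one of `case_labels` / `control_labels`.
#'
#' @param path Path to a TSV file.
#' @param case_labels,control_labels Character vectors of sample ids.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, case_labels, control_labels) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene-id column and samples")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]])) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric expression value at gene %s, sample %s",
                   gene_ids[i], colnames(vals)[j]))
    }
    if (anyNA(v))
      stop(sprintf("missing expression value in sample %s", colnames(vals)[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (length(intersect(case_labels, control_labels)))
    stop("samples listed as both case and control")
  cond <- ifelse(colnames(m) %in% case_labels, "case",
                 ifelse(colnames(m) %in% control_labels, "control", NA))
  if (anyNA(cond))
    stop("samples not in case or control labels: ",
         paste(colnames(m)[is.na(cond)], collapse = ", "))
  expression_matrix(m, cond)
}

#' Read a clinical survival table from TSV
#'
#' Columns: sample, time (days), event (1 = death, 0 = censored). Rows with
#' missing time or event are dropped and counted (`dropped_count`
#' attribute); patients lacking survival information never enter the
#' analysis.
#'
#' @param path Path to a TSV file.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("clinical TSV must have columns: ", paste(need, collapse = ", "))
  time <- suppressWarnings(as.numeric(df$time))
  event <- suppressWarnings(as.numeric(df$event))
  miss <- is.na(time) | is.na(event)
  df <- df[!miss, , drop = FALSE]
  time <- time[!miss]; event <- event[!miss]
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1)))
    stop("event values must be 0 or 1; found: ",
         paste(unique(event[!event %in% c(0, 1)]), collapse = ", "))
  clinical_table(df$sample, time, event, dropped_count = sum(miss))
}

#' Read a flat gene list (one id per line)
#'
#' @param path Path to a text file.
#' @param name Name of the list (defaults to the file name).
#' @return Character vector of unique gene ids with a `name` attribute.
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- unique(genes[nzchar(genes)])
  if (length(genes) == 0L) stop("empty gene list: ", path)
  structure(genes, name = if (is.null(name)) basename(path) else name)
}

#' Write / read a score matrix as TSV
#'
#' The NES layer is written as a row-id-keyed TSV; optional p and fdr layers
#' go to sibling files `<path>.p` and `<path>.fdr`. The round trip is
#' lossless at full stored precision (values serialized with 17 significant
#' digits).
#'
#' @param x A [score_matrix()].
#' @param path Output path for the NES table.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "ScoreMatrix"))
  write_one <- function(m, p) {
    df <- data.frame(id = rownames(m),
                     format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("id", colnames(m))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(x$nes, path)
  if (!is.null(x$p)) write_one(x$p, paste0(path, ".p"))
  if (!is.null(x$fdr)) write_one(x$fdr, paste0(path, ".fdr"))
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  read_one <- function(p) {
    df <- utils::read.delim(p, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1L]]
    m
  }
  nes <- read_one(path)
  p <- if (file.exists(paste0(path, ".p"))) read_one(paste0(path, ".p"))
  fdr <- if (file.exists(paste0(path, ".fdr"))) read_one(paste0(path, ".fdr"))
  if (!is.null(p) && !identical(dim(p), dim(nes)))
    stop("p layer dimensions do not match NES layer")
  if (!is.null(fdr) && !identical(dim(fdr), dim(nes)))
    stop("fdr layer dimensions do not match NES layer")
  score_matrix(nes, p, fdr)
}

#' Export a drug-pathway-cancer triplet network
#'
#' Two formats: `"sif"` (Cytoscape simple interaction format; each triplet
#' contributes a `drug reverses pathway` and a `pathway dysregulated_in
#' cancer` edge) and `"edge_table"` (TSV with one row per triplet carrying
#' PS, CNS, PNS and the log-rank p of the prognostic filter).
#'
#' @param triplets A data frame of triplets as built by
#'   [build_triplet_network()].
#' @param path Output path.
#' @param format `"sif"` or `"edge_table"`.
#' @return `path`, invisibly.
#' @export
export_triplet_network <- function(triplets, path, format = c("edge_table", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    if (nrow(triplets) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    lines <- c(paste(triplets$drug, "reverses", triplets$pathway),
               unique(paste(triplets$pathway, "dysregulated_in", triplets$cancer)))
    writeLines(lines, path)
  } else {
    cols <- c("drug", "pathway", "cancer", "ps", "cns", "pns", "logrank_p")
    df <- if (nrow(triplets) == 0L) {
      stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
    } else triplets[, cols]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
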