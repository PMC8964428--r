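#' Simulation configuration for synthetic study fixtures
#'
#' Collects the knobs of the synthetic cohort generators: background
#' expression is log-normal with gene-specific (heteroscedastic) variances;
#' planted gene sets are shifted in the case class by an effect size in
#' per-gene sd units; survival follows an exponential model whose hazard
#' scales with the standardized pathway-activation score; a perturbation
#' library contains reverser drugs whose instance rankings push the planted
#' genes down.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_sets Number of gene sets (default 50).
#' @param set_size Integer range of set sizes (default c(20, 80)).
#' @param n_cancers Number of cancers (default 3).
#' @param n_per_class Samples per class per cancer (default 20).
#' @param effect_size Planted shift in sd units (default 2).
#' @param baseline_hazard Exponential baseline hazard per day (default
#'   1/1000).
#' @param hazard_ratio Hazard ratio per sd of PA score (default 1).
#' @param censoring_rate Expected fraction censored (default 0.3).
#' @param n_drugs Perturbation library size (default 50).
#' @param n_instances Instances per drug (default 3).
#' @param reversal_strength Metric shift of planted genes in reverser
#'   instances, in null-metric sd units (default 2).
#' @param seed Mandatory integer seed.
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 2000L, n_sets = 50L, set_size = c(20L, 80L),
                       n_cancers = 3L, n_per_class = 20L, effect_size = 2,
                       baseline_hazard = 1 / 1000, hazard_ratio = 1,
                       censoring_rate = 0.3, n_drugs = 50L, n_instances = 3L,
                       reversal_strength = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genes > 0, n_sets > 0, all(set_size > 0), n_cancers > 0,
            n_per_class > 0, is.finite(effect_size), baseline_hazard > 0,
            hazard_ratio > 0, censoring_rate >= 0, n_drugs > 0,
            n_instances > 0, is.finite(reversal_strength))
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a gene-set collection over the synthetic gene universe
#'
#' Disjoint sets of sizes drawn uniformly from the configured range, so a
#' planted shift in one set never leaks into another.
#'
#' @param config A [sim_config()].
#' @return A [gene_set_collection()] (names `SET_001`...).
#' @export
simulate_gene_sets <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  sizes <- sample(seq(config$set_size[1], config$set_size[2]),
                  config$n_sets, replace = TRUE)
  if (sum(sizes) > config$n_genes)
    stop("gene universe too small for the requested disjoint sets")
  pool <- sample(genes)
  ends <- cumsum(sizes)
  sets <- Map(function(a, b) sort(pool[a:b]), c(1, utils::head(ends, -1) + 1), ends)
  names(sets) <- sprintf("SET_%03d", seq_along(sets))
  gene_set_collection(sets)
}

#' Simulate a paired tumor/normal cohort with planted pathway shifts
#'
#' Background log2 expression is Gaussian with gene-specific means
#' (uniform on 3..8) and sds (uniform on 0.5..1.5, heteroscedastic so the
#' SAM fudge-factor selection is exercised); values are reported on the
#' linear (2^x) scale, FPKM-like. Genes of `planted_up` sets are shifted
#' +effect_size sd units in cases, `planted_down` sets -effect_size.
#'
#' @param config A [sim_config()].
#' @param sets A [gene_set_collection()] over the config's gene universe
#'   (as from [simulate_gene_sets()]).
#' @param planted_up,planted_down Character vectors of set names.
#' @param seed Seed override (defaults to `config$seed`).
#' @return An [expression_matrix()] (cases then controls).
#' @export
simulate_paired_cohort <- function(config, sets, planted_up = character(),
                                   planted_down = character(), seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(sets, "GeneSetCollection"))
  missing_sets <- setdiff(c(planted_up, planted_down), names(sets))
  if (length(missing_sets))
    stop("planted set not in collection: ", paste(missing_sets, collapse = ", "))
  set.seed(if (is.null(seed)) config$seed else seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  n <- config$n_per_class
  mu <- stats::runif(config$n_genes, 3, 8)
  sd_g <- stats::runif(config$n_genes, 0.5, 1.5)
  X <- matrix(stats::rnorm(config$n_genes * 2 * n, mean = mu, sd = sd_g),
              nrow = config$n_genes)
  shift <- numeric(config$n_genes)
  for (s in planted_up) shift[genes %in% sets[[s]]] <- config$effect_size
  for (s in planted_down) shift[genes %in% sets[[s]]] <- -config$effect_size
  X[, seq_len(n)] <- X[, seq_len(n)] + shift * sd_g
  rownames(X) <- genes
  colnames(X) <- c(sprintf("case_%03d", seq_len(n)),
                   sprintf("ctrl_%03d", seq_len(n)))
  expression_matrix(2^X, rep(c("case", "control"), each = n))
}

#' Simulate survival outcomes tied to pathway activation
#'
#' Exponential event times with per-patient hazard
#' h0 * HR^z(PA), z the standardized PA score; independent exponential
#' censoring with rate set so the expected censored fraction equals
#' `censoring_rate` (competing exponentials). `censoring_rate >= 1` yields
#' an all-censored cohort.
#'
#' @param config A [sim_config()].
#' @param pa_scores Named numeric vector: PA score per patient.
#' @param seed Seed override.
#' @return A [clinical_table()].
#' @export
simulate_survival_cohort <- function(config, pa_scores, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"), !is.null(names(pa_scores)))
  set.seed(if (is.null(seed)) config$seed else seed)
  z <- if (stats::sd(pa_scores) > 0)
    (pa_scores - mean(pa_scores)) / stats::sd(pa_scores) else pa_scores * 0
  h <- config$baseline_hazard * config$hazard_ratio^z
  t_event <- stats::rexp(length(h), rate = h)
  cr <- config$censoring_rate
  if (cr >= 1) {
    return(clinical_table(names(pa_scores), t_event, rep(0L, length(h))))
  }
  if (cr > 0) {
    t_cens <- stats::rexp(length(h), rate = h * cr / (1 - cr))
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, length(h)); time <- t_event
  }
  clinical_table(names(pa_scores), time, event)
}

#' Simulate a perturbation (drug) library with planted reversers
#'
#' Each drug gets `n_instances` instances; an instance's treated-versus-
#' control metric is standard normal noise per gene. Reverser drugs
#' additionally shift the genes of `planted_up` sets down by
#' `reversal_strength` (and `planted_down` genes up), so GSEA of the
#' planted pathway on their rankings is negative (positive). Decoy drugs
#' are pure noise.
#'
#' @param config A [sim_config()].
#' @param sets A [gene_set_collection()] over the config's gene universe.
#' @param reversers Named list: drug id -> list(up = set names whose genes
#'   the drug pushes down, down = set names pushed up). Remaining drugs up
#'   to `config$n_drugs` are decoys (`drug_002`...).
#' @param seed Seed override.
#' @return List of [perturbation_profile()] objects.
#' @export
simulate_perturbation_library <- function(config, sets,
                                          reversers = list(), seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(sets, "GeneSetCollection"))
  set.seed(if (is.null(seed)) config$seed else seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  drug_ids <- sprintf("drug_%03d", seq_len(config$n_drugs))
  names(reversers) <- names(reversers) %||%
    drug_ids[seq_along(reversers)]
  unknown <- setdiff(names(reversers), drug_ids)
  if (length(unknown)) stop("reverser drug ids outside the library: ",
                            paste(unknown, collapse = ", "))
  profiles <- list()
  for (d in drug_ids) {
    shift <- numeric(config$n_genes)
    if (d %in% names(reversers)) {
      spec <- reversers[[d]]
      for (s in spec$up %||% character())
        shift[genes %in% sets[[s]]] <- -config$reversal_strength
      for (s in spec$down %||% character())
        shift[genes %in% sets[[s]]] <- config$reversal_strength
    }
    for (i in seq_len(config$n_instances)) {
      metric <- stats::rnorm(config$n_genes) + shift
      profiles[[length(profiles) + 1L]] <- perturbation_profile(
        d, sprintf("%s_inst%d", d, i), ranked_list(genes, metric))
    }
  }
  profiles
}

`%||%` <- function(a, b) if (is.null(a)) b else a
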