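test_that("signal-to-noise ranking matches hand arithmetic and orders planted genes first", {
  # mean_case 4, mean_control 2, sd exactly 1 per group -> metric 1
  x <- 1 / sqrt(2)
  vals <- rbind(g1 = c(4 - x, 4 + x, 2 - x, 2 + x), g2 = c(5, 5, 5, 5))
  colnames(vals) <- c("a", "b", "c", "d")
  em <- expression_matrix(vals, c("case", "case", "control", "control"))
  rl <- rank_genes(em)
  expect_equal(rl$metric[rl$gene_ids == "g1"], 1)
  expect_equal(rl$metric[rl$gene_ids == "g2"], 0)

  # identical classes: all metrics 0, deterministic tie order by gene id
  em0 <- make_cohort(n_genes = 8, seed = 1)
  em0$values[, 1:5] <- em0$values[, 6:10]
  rl0 <- rank_genes(em0)
  expect_true(all(rl0$metric == 0))
  expect_identical(rl0$gene_ids, sort(rl0$gene_ids))

  # a planted 4-fold gene ranks first
  em4 <- make_cohort(n_genes = 10, seed = 7, shift_genes = "g004", shift = 10)
  expect_identical(rank_genes(em4)$gene_ids[1], "g004")

  # single-sample class: signal-to-noise refuses, log2FC works
  m1 <- matrix(1:6 + 0, 3, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  em1 <- expression_matrix(m1, c("case", "control"))
  expect_error(rank_genes(em1), "log2_fold_change")
  expect_silent(rank_genes(em1, "log2_fold_change"))
})

test_that("enrichment score hits single-gene extremes and stays in [-1, 1]", {
  r <- ranked_list(paste0("g", 1:4), c(4, 3, 2, 1))
  expect_equal(enrichment_score(r, "g1"), 1)
  expect_equal(enrichment_score(r, "g4"), -1)
  expect_error(enrichment_score(r, "absent"), "no measured members")
  expect_error(enrichment_score(r, paste0("g", 1:4)), "entire ranked list")
})

test_that("enrichment score equals the brute-force running-sum oracle", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(10:50, 1)
    ids <- sprintf("g%03d", seq_len(n))
    metric <- round(rnorm(n), 3)
    rl <- ranked_list(ids, metric)
    k <- sample(2:(n - 1), 1)
    set <- sample(ids, k)
    expect_equal(enrichment_score(rl, set),
                 oracle_es(rl$gene_ids, rl$metric, set), tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(3)
  n <- 40
  ids <- sprintf("g%02d", 1:n)
  rl <- ranked_list(ids, rnorm(n))
  for (k in c(3, 8, 15)) {
    set <- sample(ids, k)
    es_fgsea <- fgsea::calcGseaStat(setNames(rl$metric, rl$gene_ids),
                                    which(rl$gene_ids %in% set),
                                    gseaParam = 1)
    expect_equal(enrichment_score(rl, set), es_fgsea, tolerance = 1e-10)
  }
})

test_that("reversing the ranked list negates the enrichment score", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 30
    ids <- sprintf("g%02d", 1:n)
    metric <- rnorm(n)
    metric <- metric[order(-metric)]  # distinct ordering, no ties
    rl <- ranked_list(ids, metric)
    rl_rev <- ranked_list(ids, -metric)
    set <- sample(ids, 6)
    expect_equal(enrichment_score(rl_rev, set),
                 -enrichment_score(rl, set), tolerance = 1e-12)
  }
})

test_that("NES and empirical p are reproducible and handle degenerate nulls", {
  set.seed(2)
  rl <- ranked_list(sprintf("g%02d", 1:30), rnorm(30))
  set <- sprintf("g%02d", 1:5)
  a <- nes_and_significance(rl, set, n_perm = 200, seed = 99)
  b <- nes_and_significance(rl, set, n_perm = 200, seed = 99)
  expect_identical(a, b)
  expect_false(a$flagged)
  expect_gt(a$p_emp, 0)  # +1/+1 correction forbids p = 0

  # degenerate null: every null ES equals the observed -> nes 1, p maximal
  d <- cdprx:::.nes_from_null(0.5, rep(0.5, 100))
  expect_equal(d$nes, 1)
  expect_equal(d$p_emp, 1)
  # no null of matching sign -> flagged, not a silent NaN
  flg <- cdprx:::.nes_from_null(0.5, rep(-0.5, 100))
  expect_true(flg$flagged)
  expect_true(is.na(flg$nes))
})

test_that("planted enrichment is detected with positive NES and small p", {
  hits <- 0L
  for (s in 1:20) {
    em <- make_cohort(n_genes = 100, n_case = 10, n_ctrl = 10, seed = s,
                      shift_genes = sprintf("g%03d", 1:15), shift = 2)
    rl <- rank_genes(em)
    res <- nes_and_significance(rl, sprintf("g%03d", 1:15), n_perm = 200,
                                seed = s)
    if (!res$flagged && res$nes > 0 && res$p_emp <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("CNS assembly recovers planted signs and permutes columns with cohorts", {
  sets <- gene_set_collection(list(UP = sprintf("g%03d", 1:12),
                                   DOWN = sprintf("g%03d", 13:24),
                                   NULLSET = sprintf("g%03d", 25:36)))
  mk <- function(seed) {
    em <- make_cohort(n_genes = 60, n_case = 10, n_ctrl = 10, seed = seed,
                      shift_genes = sprintf("g%03d", 1:12), shift = 2)
    em$values[sprintf("g%03d", 13:24), 1:10] <-
      em$values[sprintf("g%03d", 13:24), 1:10] - 2
    em
  }
  cohorts <- list(A = mk(1), B = mk(2))
  cns <- compute_cns(cohorts, sets, n_perm = 100, seed = 10)
  expect_identical(dim(cns$nes), c(3L, 2L))
  expect_true(all(cns$nes["UP", ] > 0))
  expect_true(all(cns$nes["DOWN", ] < 0))
  expect_true(all(cns$fdr >= cns$p - 1e-12, na.rm = TRUE))

  cns_swap <- compute_cns(list(B = cohorts$B, A = cohorts$A), sets,
                          n_perm = 100, seed = 10)
  expect_identical(colnames(cns_swap$nes), c("B", "A"))
  # column contents depend only on the cohort, not its position
  expect_equal(cns_swap$nes[, "A"], cns$nes[, "A"], tolerance = 1e-12)
})

test_that("small cohorts fall back to gene-set permutation with a warning", {
  sets <- gene_set_collection(list(S = sprintf("g%03d", 1:5)))
  em <- make_cohort(n_genes = 30, n_case = 1, n_ctrl = 3, seed = 4)
  expect_warning(
    cns <- compute_cns(list(tiny = em), sets, metric = "log2_fold_change",
                       scheme = "phenotype", n_perm = 50, seed = 1),
    "gene-set permutation")
  expect_true(is.finite(cns$nes[1, 1]))
})

test_that("ssGSEA score is rank-invariant, monotone in set position, and matches its oracle", {
  set.seed(8)
  v <- setNames(runif(50, 1, 100), sprintf("g%02d", 1:50))
  set <- sample(names(v), 5)
  s1 <- ssgsea_score(v, set)
  expect_equal(ssgsea_score(log(v), set), s1, tolerance = 1e-12)
  expect_equal(ssgsea_score(v * 1000, set), s1, tolerance = 1e-12)

  ord <- names(sort(v, decreasing = TRUE))
  expect_gt(ssgsea_score(v, ord[1:5]), ssgsea_score(v, rev(ord)[1:5]))

  expect_equal(s1, oracle_ssgsea(v, set, 0.25), tolerance = 1e-10)
  expect_equal(ssgsea_score(v, set, alpha = 0.7),
               oracle_ssgsea(v, set, 0.7), tolerance = 1e-10)

  expect_error(ssgsea_score(setNames(rep(1, 10), paste0("g", 1:10)), "g1"),
               "constant")
})

test_that("swapping a set member upward in rank strictly increases the ssGSEA score", {
  v <- setNames(50:1, sprintf("g%02d", 1:50))
  base_set <- c("g30", "g40", "g45")
  better_set <- c("g20", "g40", "g45")  # one member moved up in rank
  expect_gt(ssgsea_score(v, better_set), ssgsea_score(v, base_set))
})
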