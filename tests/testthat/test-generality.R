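test_that("rank matrix assigns ascending NES ranks with stable ties", {
  nes <- rbind(P1 = c(0.1, 0.5, -0.2), P2 = c(1, 1, 1))
  colnames(nes) <- c("c1", "c2", "c3")
  r <- build_rank_matrix(score_matrix(nes))
  expect_identical(r["P1", ], c(c1 = 2L, c2 = 3L, c3 = 1L))
  expect_identical(sort(r["P2", ]), structure(1:3, names = c("c1", "c2", "c3")))
  expect_identical(r["P2", ], c(c1 = 1L, c2 = 2L, c3 = 3L))  # tie by label order

  set.seed(9)
  rnd <- matrix(rnorm(60), 10, dimnames = list(sprintf("P%02d", 1:10),
                                               sprintf("c%d", 1:6)))
  rr <- build_rank_matrix(score_matrix(rnd))
  expect_true(all(rowSums(rr) == 21))
})

test_that("significance weights tally enriched and depleted cancers", {
  nes <- matrix(2, 1, 20, dimnames = list("P", sprintf("c%02d", 1:20)))
  p01 <- matrix(0.01, 1, 20, dimnames = dimnames(nes))
  w <- significance_weights(score_matrix(nes, p01))
  expect_identical(unname(w$w1), 20)
  expect_identical(unname(w$w2), 0)

  w2 <- significance_weights(score_matrix(nes, p01 * 20))
  expect_identical(unname(w2$w1), 0)

  mixed_nes <- matrix(c(1, -2, 3, -4, 0.5), 1,
                      dimnames = list("P", paste0("c", 1:5)))
  mixed_p <- matrix(c(0.01, 0.02, 0.5, 0.001, 0.04), 1,
                    dimnames = dimnames(mixed_nes))
  wm <- significance_weights(score_matrix(mixed_nes, mixed_p))
  expect_identical(unname(wm$w1), 2)  # c1, c5
  expect_identical(unname(wm$w2), 2)  # c2, c4
  expect_error(significance_weights(score_matrix(nes)), "no p layer")
})

test_that("generality score hits its analytic extremes at n = 20", {
  # significant enrichment in all 20 cancers -> sum r/20 = 10.5
  nes <- seq(0.1, 2, length.out = 20)
  cns <- make_single_pathway_cns(nes, rep(0.01, 20))
  g <- generality_score(build_rank_matrix(cns), significance_weights(cns))
  expect_equal(g$s, 10.5)

  # significant depletion everywhere -> -10.5
  cns_d <- make_single_pathway_cns(-nes, rep(0.01, 20))
  g_d <- generality_score(build_rank_matrix(cns_d), significance_weights(cns_d))
  expect_equal(g_d$s, -10.5)

  # 19 of 20 significant, the non-significant cancer at rank 1 -> 10.45
  p19 <- rep(0.01, 20); p19[which.min(nes)] <- 0.5
  cns19 <- make_single_pathway_cns(nes, p19)
  g19 <- generality_score(build_rank_matrix(cns19), significance_weights(cns19))
  expect_equal(g19$s, 10.45)

  # |s| never exceeds (n+1)/2
  expect_lte(abs(g$s), 21 / 2)
})

test_that("balanced enrichment and depletion cancel to zero", {
  # mirror-symmetric configuration: w1 = w2 and |a| = |b|
  nes <- c(1, 2, -1, -2)
  p <- rep(0.01, 4)
  cns <- make_single_pathway_cns(nes, p)
  # ranks ascending: -2 -> 1, -1 -> 2, 1 -> 3, 2 -> 4 (n = 4)
  # a = 1/2 * (3 + 4)/4 = 0.875 ; b = 1/2 * -( (1 - 0/4) + (1 - 1/4) ) = -0.875
  g <- generality_score(build_rank_matrix(cns), significance_weights(cns))
  expect_equal(g$a, 0.875)
  expect_equal(g$b, -0.875)
  expect_equal(g$s, 0)

  # nowhere significant: s = 0 by convention
  cns_ns <- make_single_pathway_cns(nes, rep(0.9, 4))
  g_ns <- generality_score(build_rank_matrix(cns_ns), significance_weights(cns_ns))
  expect_equal(g_ns$s, 0)
})

test_that("generality matches direct formula evaluation on random configurations", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(3:20, 1)
    nes <- rnorm(n)
    p <- runif(n)
    cns <- make_single_pathway_cns(nes, p)
    g <- generality_score(build_rank_matrix(cns), significance_weights(cns))
    o <- oracle_generality(nes, p)
    expect_equal(g$a, o$a, tolerance = 1e-12)
    expect_equal(g$b, o$b, tolerance = 1e-12)
    expect_equal(g$s, o$s, tolerance = 1e-12)
  }
})

test_that("generality is equivariant under cancer relabeling", {
  set.seed(23)
  nes <- rnorm(10)
  p <- runif(10)
  cns <- make_single_pathway_cns(nes, p)
  g <- generality_score(build_rank_matrix(cns), significance_weights(cns))
  perm <- sample(10)
  cns_p <- make_single_pathway_cns(nes[perm], p[perm])
  g_p <- generality_score(build_rank_matrix(cns_p), significance_weights(cns_p))
  expect_equal(g_p$s, g$s, tolerance = 1e-12)
})

test_that("consensus MoA clustering recovers planted LoF/SoF/GoF blocks", {
  mk_cns <- function(seed) {
    set.seed(seed)
    n_ca <- 6
    lof <- matrix(rnorm(5 * n_ca, -2, 0.2), 5)
    sof <- t(sapply(1:5, function(i) sample(c(-2, 2), n_ca, TRUE) + rnorm(n_ca, 0, 0.2)))
    gof <- matrix(rnorm(5 * n_ca, 2, 0.2), 5)
    nes <- rbind(lof, sof, gof)
    dimnames(nes) <- list(sprintf("P%02d", 1:15), sprintf("c%d", 1:n_ca))
    score_matrix(nes)
  }
  perfect <- 0L
  for (s in 1:10) {
    moa <- classify_moa(mk_cns(s), n_resample = 50, seed = s, sd_min = 0)
    ok <- all(moa$cluster[1:5] == "LoF") && all(moa$cluster[11:15] == "GoF")
    if (ok) perfect <- perfect + 1L
  }
  expect_gte(perfect, 9L)
})

test_that("degenerate consensus equals plain hierarchical clustering and is reproducible", {
  set.seed(2)
  nes <- matrix(rnorm(12 * 5, rep(c(-2, 0, 2), each = 4)), 12,
                dimnames = list(sprintf("P%02d", 1:12), paste0("c", 1:5)))
  cns <- score_matrix(nes)
  m1 <- classify_moa(cns, n_resample = 1, subsample = 1, seed = 1, sd_min = 0)
  plain <- stats::cutree(stats::hclust(stats::dist(nes), "average"), k = 3)
  expect_equal(length(unique(paste(m1$cluster, plain))), 3L)  # label-for-label match

  m2 <- classify_moa(cns, n_resample = 100, seed = 42, sd_min = 0)
  m3 <- classify_moa(cns, n_resample = 100, seed = 42, sd_min = 0)
  expect_identical(m2, m3)
  expect_error(classify_moa(cns, k = 50), "exceeds")
})

test_that("generality-based reassignment moves extreme pathways and is idempotent", {
  moa <- data.frame(pathway = c("A", "B", "C", "D"),
                    cluster = c("LoF", "GoF", "LoF", "SoF"),
                    stringsAsFactors = FALSE)
  gen <- data.frame(pathway = c("A", "B", "C", "D"),
                    s = c(7.2, -8, 3, 10))
  out <- reassign_moa(moa, gen)
  expect_identical(out$cluster, c("GoF", "LoF", "LoF", "SoF"))
  expect_identical(out$reassigned, c(TRUE, TRUE, FALSE, FALSE))
  again <- reassign_moa(out, gen)
  expect_identical(again$cluster, out$cluster)
})

test_that("hypergeometric enrichment matches exact enumeration and its edge cases", {
  universe <- sprintf("u%02d", 1:20)
  ann <- universe[1:5]
  # full overlap of a 5-draw with 5 successes: p = 1 / C(20, 5)
  expect_equal(hypergeometric_enrichment(universe[1:5], ann, universe),
               1 / choose(20, 5), tolerance = 1e-12)
  # disjoint query: k = 0 -> p = 1
  expect_equal(hypergeometric_enrichment(universe[6:10], ann, universe), 1)
  # annotation = universe -> p = 1
  expect_equal(hypergeometric_enrichment(universe[1:3], universe, universe), 1)
  expect_error(hypergeometric_enrichment("x", ann, character()), "empty universe")
  expect_error(hypergeometric_enrichment("zz", ann, universe), "outside")

  for (N in c(6, 9, 12)) {
    uni <- sprintf("g%02d", seq_len(N))
    for (K in c(2, N %/% 2)) {
      for (nd in c(2, N - 1)) {
        query <- uni[seq_len(nd)]
        k_obs <- length(intersect(query, uni[seq_len(K)]))
        expect_equal(hypergeometric_enrichment(query, uni[seq_len(K)], uni),
                     oracle_hyper(N, K, nd, k_obs), tolerance = 1e-12)
      }
    }
  }
})

test_that("cancer-side clustering is deterministic and groups correlated cancers", {
  set.seed(31)
  base <- rnorm(30)
  nes <- cbind(c1 = base + rnorm(30, 0, 0.1), c2 = base + rnorm(30, 0, 0.1),
               c3 = -base + rnorm(30, 0, 0.1), c4 = -base + rnorm(30, 0, 0.1))
  rownames(nes) <- sprintf("P%02d", 1:30)
  hc <- cluster_cancers(score_matrix(nes))
  cl <- stats::cutree(hc, 2)
  expect_identical(cl[["c1"]], cl[["c2"]])
  expect_identical(cl[["c3"]], cl[["c4"]])
  expect_false(cl[["c1"]] == cl[["c3"]])
  expect_identical(hc$merge, cluster_cancers(score_matrix(nes))$merge)
})
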