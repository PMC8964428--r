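# Independent oracles used to check the package's implementations.
# These are deliberately written as direct, position-by-position or
# enumeration computations and share no code with the package internals.

# Brute-force weighted-KS running sum: walk every position of the ranked
# list and track the signed maximum deviation.
oracle_es <- function(ranked_ids, metric, set) {
  n <- length(ranked_ids)
  hit <- ranked_ids %in% set
  k <- sum(hit)
  w <- abs(metric)
  sw <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (sw > 0) w[i] / sw else 1 / k
    } else {
      -1 / (n - k)
    }
    if (abs(run) > abs(best) + 1e-9) best <- run  # first extremum wins ties
  }
  best
}

# Brute-force ssGSEA: explicit weighted-ECDF difference summed over
# positions.
oracle_ssgsea <- function(values, set, alpha) {
  o <- order(-values, names(values), method = "radix")
  v <- values[o]
  inset <- names(v) %in% set
  n <- length(v)
  r <- (n:1)^alpha
  num <- denom_in <- sum(r[inset])
  score <- 0
  cum_in <- cum_out <- 0
  n_out <- sum(!inset)
  for (i in seq_len(n)) {
    if (inset[i]) cum_in <- cum_in + r[i] else cum_out <- cum_out + 1
    score <- score + cum_in / denom_in - cum_out / n_out
  }
  score
}

# Exact hypergeometric upper tail by enumerating all C(N, n) draws.
oracle_hyper <- function(N, K, n_draw, k_obs) {
  draws <- utils::combn(N, n_draw)
  succ <- colSums(draws <= K)  # successes are items 1..K
  mean(succ >= k_obs)
}

# Log-rank chi-square from the observed-minus-expected formula, summed
# over distinct event times.
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  O <- E <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at1 <- sum(time >= tt & grp == 1)
    at2 <- sum(time >= tt & grp == 2)
    nt <- at1 + at2
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * at1 / nt
    if (nt > 1) V <- V + d * (at1 / nt) * (at2 / nt) * (nt - d) / (nt - 1)
  }
  (O - E)^2 / V
}

# Direct evaluation of the generality statistics from their definitions,
# independent of build_rank_matrix / generality_score.
oracle_generality <- function(nes, p, alpha = 0.05) {
  n <- length(nes)
  # ascending rank of each cancer by NES, ties by position order
  r <- integer(n)
  r[order(nes, seq_len(n))] <- seq_len(n)
  enr <- which(nes > 0 & p < alpha)
  dep <- which(nes < 0 & p < alpha)
  w1 <- length(enr); w2 <- length(dep)
  if (w1 + w2 == 0) return(list(a = 0, b = 0, s = 0))
  a <- w1 / (w1 + w2) * sum(r[enr] / n)
  b <- w2 / (w1 + w2) * sum((1 - (r[dep] - 1) / n) * (-1))
  s <- if (abs(a) > abs(b)) a else if (abs(a) < abs(b)) b else 0
  list(a = a, b = b, s = s)
}

# small deterministic cohort builder for io/enrichment tests
make_cohort <- function(n_genes = 30, n_case = 5, n_ctrl = 5, seed = 42,
                        shift_genes = character(), shift = 0) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  m <- matrix(rnorm(n_genes * (n_case + n_ctrl), mean = 5),
              nrow = n_genes,
              dimnames = list(genes, c(sprintf("case%d", seq_len(n_case)),
                                       sprintf("ctrl%d", seq_len(n_ctrl)))))
  m[genes %in% shift_genes, seq_len(n_case)] <-
    m[genes %in% shift_genes, seq_len(n_case)] + shift
  expression_matrix(m, rep(c("case", "control"), c(n_case, n_ctrl)))
}

# 20-cancer single-pathway score matrix with chosen NES and p patterns
make_single_pathway_cns <- function(nes, p) {
  nm <- list("PATHWAY", sprintf("cancer%02d", seq_along(nes)))
  score_matrix(matrix(nes, 1, dimnames = nm), matrix(p, 1, dimnames = nm))
}
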