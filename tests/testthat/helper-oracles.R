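# Independent brute-force oracles used across test files. These stay
# deliberately naive (per-record loops, full enumeration) so they share
# no code path with the package implementations they check.

# record-by-record re-evaluation of the signature DMP rule
oracle_select_dmps <- function(tab, p_threshold, delta_threshold) {
  out <- character(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$p[i] < p_threshold && abs(tab$effect[i]) > delta_threshold)
      out <- c(out, tab$cpg[i])
  }
  out
}

# record-by-record re-evaluation of the drug-correction rule
oracle_corrected_dmps <- function(tab, p_threshold, geno_min, drug_min,
                                  residual_max) {
  out <- character(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$p[i] < p_threshold &&
        abs(tab$effect_geno[i]) > geno_min &&
        abs(tab$effect_drug[i]) > drug_min &&
        abs(tab$effect_residual[i]) < residual_max)
      out <- c(out, tab$cpg[i])
  }
  out
}

# record-by-record re-evaluation of the RRBS DMP rule
oracle_rrbs_dmps <- function(tab, q_threshold, diff_threshold) {
  out <- character(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$q[i] < q_threshold && abs(tab$meth_diff[i]) > diff_threshold)
      out <- c(out, tab$cpg[i])
  }
  out
}

# exact two-sided rank-sum p by enumerating every split of the pooled
# values into the two group sizes
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  n <- length(pooled)
  w_obs <- sum(r[seq_len(nx)])
  ew <- nx * (n + 1) / 2
  idx <- utils::combn(n, nx)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-12)
}

# exact Kruskal-Wallis p for two groups by enumerating group splits;
# the H statistic for each split comes from stats::kruskal.test, an
# implementation independent of the package's
oracle_kw2_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  H_obs <- unname(stats::kruskal.test(
    pooled, factor(rep(1:2, c(nx, n - nx))))$statistic)
  idx <- utils::combn(n, nx)
  Hs <- apply(idx, 2, function(i) {
    g <- factor(ifelse(seq_len(n) %in% i, 1, 2))
    unname(stats::kruskal.test(pooled, g)$statistic)
  })
  mean(Hs >= H_obs - 1e-12)
}

# small random beta matrix for IO round trips
random_beta_matrix <- function(n_cpg = 20, n_sample = 5, seed = 42,
                               with_coords = TRUE) {
  set.seed(seed)
  v <- matrix(runif(n_cpg * n_sample), n_cpg,
              dimnames = list(sprintf("cg%03d", seq_len(n_cpg)),
                              sprintf("s%02d", seq_len(n_sample))))
  coords <- NULL
  if (with_coords) {
    chrom <- sample(c("chr1", "chr2", "chrX"), n_cpg, replace = TRUE)
    coords <- data.frame(cpg = rownames(v), chrom = chrom,
                         pos = sample.int(1e6, n_cpg), sex = chrom == "chrX")
  }
  beta_matrix(v, coords)
}

# long-format score block for one suppressor across enhancer conditions;
# `shift` < 0 rescues (mass toward score 0) under every enhancer
simulate_screen_block <- function(supp, shift, seed,
                                  enhancers = c("e1", "e2", "e3"),
                                  n_larvae = 30) {
  shift <- rep_len(shift, length(enhancers))
  out <- lapply(seq_along(enhancers), function(i) {
    sc <- simulate_ordinal_screen(supp, effect_shifts = shift[i],
                                  n_larvae = n_larvae,
                                  seed = seed * 10 + i)
    data.frame(suppressor = supp, enhancer = enhancers[i],
               score = sc$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# minimal meth_counts constructor for hand-built fixtures
make_counts <- function(meth, cov) {
  ids <- sprintf("rr%03d", seq_len(nrow(meth)))
  rownames(meth) <- rownames(cov) <- ids
  structure(list(meth = meth, cov = cov,
                 coords = data.frame(cpg = ids, chrom = "chr1",
                                     pos = seq_len(nrow(meth)) * 100L,
                                     strand = "+")),
            class = "meth_counts")
}
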