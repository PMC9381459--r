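#' Kruskal-Wallis test with Dunn's post test for ordinal scores
#'
#' Rank-based H test with tie correction (essential for 4-level ordinal
#' data), followed by Dunn's pairwise z comparisons on the pooled
#' midranks with the tie-corrected variance and Bonferroni-style
#' multiplicity adjustment. For small pooled samples
#' (`n <= exact_limit`, default 10) the global p-value is computed
#' exactly by full enumeration of group assignments; otherwise the
#' chi-square approximation is used. If every pooled observation is
#' identical the contract is `H = 0`, `p = 1`.
#'
#' @param score numeric/integer scores (or a data.frame with columns
#'   `score` and `condition`/`chemical`).
#' @param condition condition labels, same length as `score`.
#' @param exact_limit pooled-size cutoff for the exact enumeration path.
#' @param p_adjust adjustment for the pairwise p-values (default
#'   `"bonferroni"`; any [stats::p.adjust()] method).
#' @return list with `H`, `df`, `p`, `p_method`, `mean_ranks`, and
#'   `pairwise` (data.frame: group1, group2, z, p, p_adj).
#' @export
kruskal_wallis_dunn <- function(score, condition = NULL, exact_limit = 10,
                                p_adjust = "bonferroni") {
  if (is.data.frame(score)) {
    df <- score
    cond_col <- intersect(c("condition", "chemical"), names(df))[1]
    if (is.na(cond_col)) stop("data.frame needs a condition/chemical column")
    condition <- df[[cond_col]]
    score <- df$score
  }
  condition <- as.factor(as.character(condition))
  if (nlevels(condition) < 2) stop("need at least two conditions")
  if (any(table(condition) < 2)) stop("each condition needs >= 2 observations")
  n <- length(score)
  r <- rank(score)
  mean_ranks <- tapply(r, condition, mean)
  if (stats::sd(score) == 0) {           # all-identical contract
    H <- 0; p <- 1; p_method <- "degenerate"
  } else if (n <= exact_limit) {
    H <- kw_stat(score, condition)
    p <- kw_exact_p(score, condition, H)
    p_method <- "exact"
  } else {
    kt <- stats::kruskal.test(score, condition)
    H <- unname(kt$statistic); p <- kt$p.value
    p_method <- "asymptotic"
  }
  # Dunn pairwise z with tie correction
  tie <- table(score)
  tie_term <- sum(tie^3 - tie) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12
  lev <- levels(condition)
  ns <- table(condition)
  pairs <- utils::combn(lev, 2)
  zs <- vapply(seq_len(ncol(pairs)), function(i) {
    gg <- pairs[, i]
    se <- sqrt((v0 - tie_term) * (1 / ns[[gg[1]]] + 1 / ns[[gg[2]]]))
    if (se > 0) (mean_ranks[[gg[1]]] - mean_ranks[[gg[2]]]) / se else 0
  }, 0)
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = zs, p = 2 * stats::pnorm(-abs(zs)),
                         stringsAsFactors = FALSE)
  pairwise$p_adj <- pmin(stats::p.adjust(pairwise$p, method = p_adjust), 1)
  list(H = H, df = nlevels(condition) - 1, p = p, p_method = p_method,
       mean_ranks = mean_ranks, pairwise = pairwise)
}

# tie-corrected Kruskal-Wallis H
kw_stat <- function(score, condition) {
  n <- length(score)
  r <- rank(score)
  ns <- tapply(r, condition, length)
  rs <- tapply(r, condition, sum)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  tie <- table(score)
  corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  if (corr > 0) H / corr else 0
}

# exact permutation p by enumerating all distinct assignments of the
# pooled scores to the group sizes; p = P(H >= observed)
kw_exact_p <- function(score, condition, H_obs) {
  ns <- table(condition)
  k <- length(ns)
  n <- length(score)
  idx_all <- seq_len(n)
  count <- 0; total <- 0
  rec <- function(remaining, gi, assign) {
    if (gi == k) {
      assign[remaining] <- k
      g <- factor(assign, levels = seq_len(k))
      H <- kw_stat(score, g)
      total <<- total + 1
      if (H >= H_obs - 1e-12) count <<- count + 1
      return(invisible())
    }
    cmb <- utils::combn(remaining, ns[gi])
    for (c_i in seq_len(ncol(cmb))) {
      a2 <- assign
      a2[cmb[, c_i]] <- gi
      rec(setdiff(remaining, cmb[, c_i]), gi + 1, a2)
    }
  }
  rec(idx_all, 1, integer(n))
  count / total
}

#' Build a suppressor-by-enhancer chemical fingerprint matrix
#'
#' For each enhancer block, ranks all scores across suppressor
#' conditions jointly (midranks), takes the mean rank per suppressor and
#' divides by the vehicle's mean rank within the same block, so the
#' vehicle entry is exactly 1 and values below 1 indicate rescue. The
#' normalised matrix is then transformed column-wise for clustering:
#' `"zscore"` (default; removes per-enhancer severity so clustering
#' reflects the rescue pattern), `"log2"`, or `"none"`. Combinations
#' with no scores become explicit `NA` entries, pairwise-deleted in
#' downstream distances.
#'
#' @param scores long data.frame with columns `suppressor`, `enhancer`,
#'   `score`.
#' @param vehicle suppressor label of the vehicle (default `"DMSO"`).
#' @param transform column transformation for the clustering matrix.
#' @return object of class `fingerprint_matrix`: list with `ratio`
#'   (suppressor x enhancer mean-rank ratios) and `transformed`.
#' @export
build_fingerprint <- function(scores, vehicle = "DMSO",
                              transform = c("zscore", "log2", "none")) {
  transform <- match.arg(transform)
  need <- c("suppressor", "enhancer", "score")
  if (!all(need %in% names(scores)))
    stop("scores needs columns suppressor, enhancer, score")
  if (!vehicle %in% scores$suppressor)
    stop("vehicle label '", vehicle, "' not present")
  sups <- sort(unique(as.character(scores$suppressor)))
  enhs <- sort(unique(as.character(scores$enhancer)))
  ratio <- matrix(NA_real_, length(sups), length(enhs),
                  dimnames = list(sups, enhs))
  for (e in enhs) {
    blk <- scores[scores$enhancer == e, ]
    if (!vehicle %in% blk$suppressor)
      stop("vehicle missing in enhancer block '", e, "'")
    r <- rank(blk$score)
    mr <- tapply(r, as.character(blk$suppressor), mean)
    ratio[names(mr), e] <- mr / mr[[vehicle]]
  }
  tr <- switch(transform,
               zscore = apply(ratio, 2, function(col) {
                 s <- stats::sd(col, na.rm = TRUE)
                 if (is.na(s) || s == 0) col - mean(col, na.rm = TRUE)
                 else (col - mean(col, na.rm = TRUE)) / s
               }),
               log2 = log2(ratio),
               none = ratio)
  if (is.null(dim(tr))) tr <- matrix(tr, nrow = length(sups),
                                     dimnames = dimnames(ratio))
  structure(list(ratio = ratio, transformed = tr, vehicle = vehicle,
                 transform = transform),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix: %d suppressors x %d enhancers (%s transform)\n",
              nrow(x$ratio), ncol(x$ratio), x$transform))
  print(round(x$ratio, 3), ...)
  invisible(x)
}

#' Hierarchically cluster fingerprint rows
#'
#' Centered-correlation distance (1 - Pearson correlation of rows,
#' pairwise-complete) with average linkage, the classic
#' expression-clustering convention. Pairs where the correlation is
#' undefined (a constant row) fall back to the Euclidean distance of the
#' two rows (documented fallback). Leaf order is deterministic.
#'
#' @param x a `fingerprint_matrix` or numeric matrix (rows clustered).
#' @param k number of flat clusters from the cut (default 2).
#' @return list with `hclust`, `clusters` (named integer), `newick`.
#' @export
cluster_fingerprint <- function(x, k = 2) {
  m <- if (inherits(x, "fingerprint_matrix")) x$transformed else as.matrix(x)
  if (nrow(m) < 2) stop("need at least two rows")
  m <- m[order(rownames(m)), , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  d <- 1 - cc
  if (any(!is.finite(d))) {
    de <- as.matrix(stats::dist(m))
    d[!is.finite(d)] <- de[!is.finite(d)]
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, k = min(k, nrow(m)))
  list(hclust = hc, clusters = cl,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Chemical-genetic interaction contrast with bootstrap CI
#'
#' The interaction contrast quantifies an unexpected change in the
#' WT-mutant difference after treatment:
#' `(mean_mut_treated - mean_WT_treated) -
#'  (mean_mut_vehicle - mean_WT_vehicle)`.
#' A percentile bootstrap confidence interval is built by resampling
#' observations within each design cell. A cell with a single
#' observation flags the interval as unstable.
#'
#' @param value numeric response (e.g. swim speed).
#' @param genotype two-level factor, reference (WT) first.
#' @param treatment two-level factor, reference (vehicle) first.
#' @param n_boot bootstrap replicates (default 10000).
#' @param conf confidence level.
#' @param seed optional integer seed for the resampling.
#' @return list with `contrast`, `ci` (length 2), `conf`, `unstable`,
#'   `cell_means`.
#' @export
interaction_contrast <- function(value, genotype, treatment,
                                 n_boot = 10000, conf = 0.95, seed = NULL) {
  genotype <- as.factor(genotype); treatment <- as.factor(treatment)
  if (nlevels(genotype) != 2 || nlevels(treatment) != 2)
    stop("genotype and treatment must each have two levels")
  cells <- split(value, list(genotype, treatment), drop = FALSE)
  if (any(lengths(cells) == 0)) stop("empty design cell")
  if (!is.null(seed)) set.seed(seed)
  wt <- levels(genotype)[1]; veh <- levels(treatment)[1]
  mu <- vapply(cells, mean, 0)
  nm <- function(g, t) paste(g, t, sep = ".")
  contrast <- (mu[nm(levels(genotype)[2], levels(treatment)[2])] -
                 mu[nm(wt, levels(treatment)[2])]) -
              (mu[nm(levels(genotype)[2], veh)] - mu[nm(wt, veh)])
  boot_means <- vapply(cells, function(xx) {
    n <- length(xx)
    colMeans(matrix(xx[sample.int(n, n * n_boot, replace = TRUE)], n, n_boot))
  }, numeric(n_boot))
  bc <- (boot_means[, nm(levels(genotype)[2], levels(treatment)[2])] -
           boot_means[, nm(wt, levels(treatment)[2])]) -
        (boot_means[, nm(levels(genotype)[2], veh)] -
           boot_means[, nm(wt, veh)])
  alpha <- (1 - conf) / 2
  list(contrast = unname(contrast),
       ci = unname(stats::quantile(bc, c(alpha, 1 - alpha))),
       conf = conf, unstable = any(lengths(cells) == 1),
       cell_means = mu)
}

#' ChIP-qPCR percent-input quantification
#'
#' Expresses immunoprecipitated signal as a percentage of input
#' chromatin: the input Ct is first adjusted for its dilution by
#' `log2(1/input_fraction)` cycles, then
#' `percent = 100 * 2^(adjusted_input_ct - ct_ip)`.
#'
#' @param ct_ip Ct of the IP sample.
#' @param ct_input Ct of the (diluted) input sample.
#' @param input_fraction fraction of chromatin used as input, in (0,1].
#' @return percent input (vectorised).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.1) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0,1]")
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_input)))
    stop("Ct values must be finite")
  100 * 2^((ct_input - log2(1 / input_fraction)) - ct_ip)
}

#' Methylation potential index (SAM:SAH ratio)
#'
#' The ratio of S-adenosylmethionine to S-adenosylhomocysteine, an index
#' of cellular methylation potential. Vectorised.
#'
#' @param sam,sah metabolite concentrations; `sah` must be positive.
#' @export
methylation_potential <- function(sam, sah) {
  if (any(sah <= 0)) stop("sah must be positive")
  sam / sah
}
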