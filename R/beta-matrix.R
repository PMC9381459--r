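#' Methylation beta-value matrix
#'
#' Container for a CpG-by-sample matrix of methylation beta values
#' (fraction methylated, in \[0,1\]) with optional per-CpG genomic
#' coordinates. Rows are CpGs, columns are samples; missing values are
#' allowed and excluded pairwise by downstream summaries.
#'
#' @param values numeric matrix, CpGs in rows (rownames = CpG ids),
#'   samples in columns (colnames = sample ids); values in \[0,1\] or `NA`.
#' @param coords optional `data.frame` with columns `cpg`, `chrom`,
#'   `pos` (1-based) and logical `sex` flagging sex-chromosome probes;
#'   rows must cover every CpG id in `values`.
#' @return an object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, coords = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("`values` must have CpG ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate CpG ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:3],
               collapse = ", "))
  if (is.null(colnames(values)))
    stop("`values` must have sample ids as colnames")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at CpG '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    need <- c("cpg", "chrom", "pos")
    if (!all(need %in% names(coords)))
      stop("coords must have columns cpg, chrom, pos")
    if (!"sex" %in% names(coords))
      coords$sex <- coords$chrom %in% c("chrX", "chrY", "X", "Y")
    missing_cpg <- setdiff(rownames(values), coords$cpg)
    if (length(missing_cpg) > 0)
      stop("coords missing for ", length(missing_cpg), " CpGs")
    coords <- coords[match(rownames(values), coords$cpg),
                     c("cpg", "chrom", "pos", "sex")]
    rownames(coords) <- NULL
  }
  structure(list(values = values, coords = coords), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$coords))
    cat(sprintf("  coordinates: %d chromosomes, %d sex-chromosome CpGs\n",
                length(unique(x$coords$chrom)), sum(x$coords$sex)))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  missing values: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

# accept either a beta_matrix or a plain matrix
beta_values <- function(x) {
  if (inherits(x, "beta_matrix")) x$values else as.matrix(x)
}

#' Read / write a beta matrix as TSV
#'
#' The on-disk format is tab-separated with a header: first column `cpg`,
#' optional `chrom`/`pos`/`sex` coordinate columns, then one column per
#' sample. Coordinates are 1-based. Missing betas are empty fields.
#'
#' @param path file path.
#' @return `read_beta_matrix` returns a [beta_matrix];
#'   `write_beta_matrix` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"cpg" %in% names(df)) stop("first column must be 'cpg'")
  coord_cols <- intersect(c("chrom", "pos", "sex"), names(df))
  sample_cols <- setdiff(names(df), c("cpg", coord_cols))
  if (length(sample_cols) == 0) stop("no sample columns found")
  vals <- as.matrix(df[sample_cols])
  if (!is.numeric(vals)) stop("non-numeric beta values in file")
  rownames(vals) <- df$cpg
  coords <- NULL
  if (all(c("chrom", "pos") %in% coord_cols))
    coords <- df[c("cpg", coord_cols)]
  beta_matrix(vals, coords)
}

#' @rdname read_beta_matrix
#' @param x a [beta_matrix].
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(cpg = rownames(x$values), stringsAsFactors = FALSE)
  if (!is.null(x$coords))
    df <- cbind(df, x$coords[c("chrom", "pos", "sex")])
  df <- cbind(df, as.data.frame(x$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# methylation beta matrix; coordinates 1-based", con)
  utils::write.table(format(df, digits = 15, trim = TRUE, nsmall = 0),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write a sample sheet as CSV
#'
#' Per-sample covariates and design labels: `sample_id` plus any of
#' `cohort`, `group`, `age`, `genotype`, `treatment`, `batch`.
#'
#' @param path file path.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample sheet needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sample sheet")
  df
}

#' @rdname read_sample_sheet
#' @param x sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Beta / M-value conversion
#'
#' `beta_to_m` maps beta values to M-values, `m = log2(beta/(1-beta))`,
#' the variance-stabilised scale for linear modelling; betas are clipped
#' to `[eps, 1-eps]` first so the transform stays finite. `m_to_beta`
#' inverts it (recovering the clipped beta).
#'
#' @param beta numeric vector/matrix of betas.
#' @param eps clipping bound in (0, 0.5); default 0.001.
#' @export
beta_to_m <- function(beta, eps = 0.001) {
  stopifnot(eps > 0, eps < 0.5)
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m numeric vector/matrix of M-values.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Filter probes by missingness, variability and sex chromosomes
#'
#' Removes CpGs whose missing fraction exceeds `max_missing_frac` or whose
#' standard deviation (pairwise-complete) is below `min_sd`. Sex-chromosome
#' probes are kept by default, the appropriate choice for a single-sex
#' cohort; set `drop_sex = TRUE` to remove them.
#'
#' @param x a [beta_matrix].
#' @param max_missing_frac maximum tolerated fraction of missing values
#'   per CpG, in \[0,1\].
#' @param min_sd minimum per-CpG standard deviation.
#' @param drop_sex drop CpGs flagged as sex-chromosome probes?
#' @return filtered [beta_matrix]; errors if nothing survives.
#' @export
filter_probes <- function(x, max_missing_frac = 1, min_sd = 0,
                          drop_sex = FALSE) {
  stopifnot(inherits(x, "beta_matrix"),
            max_missing_frac >= 0, max_missing_frac <= 1, min_sd >= 0)
  v <- x$values
  miss <- rowMeans(is.na(v))
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  keep <- miss <= max_missing_frac & sds >= min_sd
  if (min_sd > 0) keep <- keep & sds > 0  # constants go when variability is required
  if (drop_sex && !is.null(x$coords)) keep <- keep & !x$coords$sex
  if (!any(keep)) stop("no CpGs survive filtering")
  beta_matrix(v[keep, , drop = FALSE],
              if (is.null(x$coords)) NULL else x$coords[keep, , drop = FALSE])
}

#' Row-wise mean centering (optionally scaling) of a beta matrix
#'
#' Centers each CpG row to mean zero, as used for signature heatmaps and
#' principal-component plots; with `scale = TRUE` rows are also divided by
#' their standard deviation ("scaled and mean centered"). Rows with zero
#' variance are left centered but unscaled.
#'
#' @param x a [beta_matrix] or numeric matrix.
#' @param scale divide rows by their sd after centering?
#' @return numeric matrix of centered values.
#' @export
mean_center <- function(x, scale = FALSE) {
  v <- beta_values(x)
  ctr <- v - rowMeans(v, na.rm = TRUE)
  if (scale) {
    s <- apply(ctr, 1, stats::sd, na.rm = TRUE)
    s[is.na(s) | s == 0] <- 1
    ctr <- ctr / s
  }
  ctr
}

#' Compare global methylation between two groups
#'
#' Computes per-CpG group mean betas, then tests the two distributions of
#' CpG means against each other with a two-sided Wilcoxon rank-sum test.
#' For pooled n (2 x CpG count) at most `exact_limit` the p-value is
#' computed by full enumeration of group assignments (handles ties
#' exactly); above it, the normal approximation with tie correction is
#' used. Also returns a shared-breaks histogram summary of the per-group
#' mean-beta densities.
#'
#' @param x a [beta_matrix] or matrix.
#' @param groups factor/character of length `ncol(x)` with exactly two
#'   levels; the first level is the reference (direction `hyper` means the
#'   second level is more methylated).
#' @param exact_limit pooled-size cutoff for the exact enumeration path.
#' @param breaks number of histogram bins for the density summary.
#' @return list with `statistic` (rank sum of the non-reference group),
#'   `p`, `direction`, `group_means` and `histogram`.
#' @export
global_methylation_compare <- function(x, groups, exact_limit = 20,
                                       breaks = 40) {
  v <- beta_values(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) == 0)) stop("a group has zero samples")
  ref <- levels(groups)[1]; alt <- levels(groups)[2]
  mx <- rowMeans(v[, groups == ref, drop = FALSE], na.rm = TRUE)
  my <- rowMeans(v[, groups == alt, drop = FALSE], na.rm = TRUE)
  n <- length(mx) + length(my)
  if (n <= exact_limit) {
    res <- wilcox_exact(my, mx)
    W <- res$statistic; p <- res$p
  } else {
    wt <- stats::wilcox.test(my, mx, exact = FALSE, correct = TRUE)
    W <- unname(wt$statistic); p <- wt$p.value
  }
  direction <- if (mean(my) > mean(mx)) "hyper"
               else if (mean(my) < mean(mx)) "hypo" else "none"
  brk <- seq(0, 1, length.out = breaks + 1)
  hist_ref <- graphics::hist(mx, breaks = brk, plot = FALSE)
  hist_alt <- graphics::hist(my, breaks = brk, plot = FALSE)
  list(statistic = W, p = p, direction = direction,
       group_means = stats::setNames(c(mean(mx), mean(my)), c(ref, alt)),
       histogram = data.frame(mid = hist_ref$mids,
                              density_ref = hist_ref$density,
                              density_alt = hist_alt$density))
}

# Exact two-sided rank-sum test by full enumeration of the C(n, n_y)
# group assignments of the pooled ranks; ties handled through midranks.
# Two-sided p = P(|W - E W| >= |w_obs - E W|). Returns the Mann-Whitney
# style statistic of `y` (rank sum minus its minimum).
wilcox_exact <- function(y, x) {
  pooled <- c(y, x)
  r <- rank(pooled)
  ny <- length(y); n <- length(pooled)
  w_obs <- sum(r[seq_len(ny)])
  ew <- ny * (n + 1) / 2
  idx <- utils::combn(n, ny)
  ws <- colSums(matrix(r[idx], nrow = ny))
  p <- mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-12)
  list(statistic = w_obs - ny * (ny + 1) / 2, p = p)
}
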