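#' Reference-based cell-type deconvolution by constrained projection
#'
#' Estimates cell-type proportions per sample by projecting observed
#' betas onto cell-type reference profiles under a nonnegativity
#' constraint (Lawson-Hanson nonnegative least squares), the
#' constrained-projection approach used for blood cell composition on
#' methylation arrays. Only CpGs shared between the sample matrix and the
#' reference are used; missing sample values are dropped pairwise.
#'
#' The raw NNLS fractions are returned together with their sum-to-one
#' renormalisation; the residual norm stays interpretable on the raw
#' solution. When the unconstrained least-squares solution is already
#' nonnegative, the constrained solution equals it exactly.
#'
#' @param x a [beta_matrix] or matrix (CpG x sample).
#' @param reference a `cell_reference` (see [simulate_cell_reference()])
#'   or a CpG x cell-type matrix.
#' @param normalize if `TRUE` the `proportions` field holds the
#'   sum-to-one fractions (the raw solution is kept in `raw`).
#' @return object of class `cell_proportions`: list with `proportions`
#'   (sample x cell type), `raw`, `normalized`, `residual` (per-sample
#'   residual norm).
#' @export
estimate_proportions <- function(x, reference, normalize = FALSE) {
  v <- beta_values(x)
  prof <- if (inherits(reference, "cell_reference")) reference$profiles
          else as.matrix(reference)
  common <- intersect(rownames(v), rownames(prof))
  if (length(common) == 0) stop("no CpGs shared with the reference")
  if (length(common) < ncol(prof))
    stop("fewer shared CpGs than cell types")
  A_full <- prof[common, , drop = FALSE]
  if (qr(A_full)$rank < ncol(A_full))
    stop("rank-deficient cell reference")
  v <- v[common, , drop = FALSE]
  k <- ncol(prof)
  n <- ncol(v)
  raw <- matrix(NA_real_, n, k,
                dimnames = list(colnames(v), colnames(prof)))
  resid <- numeric(n)
  for (j in seq_len(n)) {
    ok <- !is.na(v[, j])
    fit <- pracma::lsqnonneg(A_full[ok, , drop = FALSE], v[ok, j])
    raw[j, ] <- fit$x
    resid[j] <- sqrt(fit$resid.norm)
  }
  norm <- raw / pmax(rowSums(raw), .Machine$double.eps)
  structure(list(proportions = if (normalize) norm else raw,
                 raw = raw, normalized = norm,
                 residual = stats::setNames(resid, colnames(v))),
            class = "cell_proportions")
}

#' @export
print.cell_proportions <- function(x, ...) {
  cat(sprintf("cell_proportions: %d samples x %d cell types\n",
              nrow(x$proportions), ncol(x$proportions)))
  cat("  mean fractions:",
      paste(sprintf("%s=%.3f", colnames(x$normalized),
                    colMeans(x$normalized)), collapse = ", "), "\n")
  invisible(x)
}

#' Select cell-type-discriminating CpGs from a reference
#'
#' For each cell type, ranks CpGs by the difference between that type's
#' beta and the mean beta of all other types, and keeps the `k_per_type`
#' most extreme — half hypermethylated, half hypomethylated where
#' available. The union over types is returned; these CpGs condition the
#' deconvolution design far better than a random subset.
#'
#' @param reference a `cell_reference` or CpG x cell-type matrix.
#' @param k_per_type CpGs kept per cell type (>= 1).
#' @return character vector of CpG ids.
#' @export
select_discriminating_cpgs <- function(reference, k_per_type = 100) {
  stopifnot(k_per_type >= 1)
  prof <- if (inherits(reference, "cell_reference")) reference$profiles
          else as.matrix(reference)
  if (max(apply(prof, 1, function(r) diff(range(r)))) < 1e-12)
    stop("reference profiles identical across cell types; no discriminating CpGs")
  if (k_per_type > nrow(prof)) stop("k_per_type exceeds available CpGs")
  k <- ncol(prof)
  chosen <- character(0)
  any_signal <- FALSE
  for (j in seq_len(k)) {
    d <- prof[, j] - rowMeans(prof[, -j, drop = FALSE])
    if (all(abs(d) < 1e-12)) next
    any_signal <- TRUE
    n_up <- min(ceiling(k_per_type / 2), sum(d > 0))
    n_dn <- min(k_per_type - n_up, sum(d < 0))
    up <- names(sort(d, decreasing = TRUE))[seq_len(n_up)]
    dn <- if (n_dn > 0) names(sort(d))[seq_len(n_dn)] else character(0)
    chosen <- c(chosen, up, dn)
  }
  if (!any_signal)
    stop("reference profiles identical across cell types; no discriminating CpGs")
  unique(chosen)
}
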