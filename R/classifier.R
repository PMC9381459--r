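#' Principal-component projection of samples on signature CpGs
#'
#' Restricts the matrix to the signature CpGs, mean-centers per CpG
#' (unscaled), and computes the top principal components over all
#' supplied samples jointly (discovery + test together, the joint
#' projection used for visual validation). Component signs are fixed so
#' the largest-magnitude loading of each component is positive, making
#' the decomposition deterministic.
#'
#' @param x a [beta_matrix] or matrix.
#' @param signature a `signature_set`, or character vector of CpG ids;
#'   `NULL` uses all rows.
#' @param n_comp number of components returned (default 3).
#' @return list with `coordinates` (sample x component), `variance_frac`
#'   (fraction of total variance per component), `loadings`.
#' @export
pca_project <- function(x, signature = NULL, n_comp = 3) {
  v <- beta_values(x)
  if (!is.null(signature)) {
    ids <- if (is.data.frame(signature)) signature$cpg else signature
    miss <- setdiff(ids, rownames(v))
    if (length(miss) == length(ids)) stop("no signature CpGs in matrix")
    v <- v[intersect(ids, rownames(v)), , drop = FALSE]
  }
  if (nrow(v) < 1) stop("need at least one CpG")
  if (ncol(v) < 3) stop("need at least three samples")
  ctr <- mean_center(v)
  pc <- stats::prcomp(t(ctr), center = FALSE, scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$x))
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  load <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(n_comp)) {       # deterministic sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = scores, variance_frac = vf[seq_len(n_comp)],
       loadings = load)
}

#' Hierarchical clustering of samples on signature CpGs with a 2-cut
#'
#' Agglomerative clustering of samples with Euclidean distance on
#' per-CpG scaled and mean-centered values (the heatmap convention),
#' average linkage by default, cut into two clusters. The cluster
#' holding the majority of the supplied known cases is labelled
#' `case-like`, the other `control-like`; an exact tie goes to cluster 1
#' (documented tie-break). Sample and CpG order do not affect the
#' result.
#'
#' @param x a [beta_matrix] or matrix (all samples to cluster).
#' @param signature `signature_set` or CpG ids; `NULL` uses all rows.
#' @param case_ids sample ids of known (discovery) cases anchoring the
#'   case-like label.
#' @param scale scale rows to unit sd before clustering (default TRUE).
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `labels` (named character, `case-like` /
#'   `control-like`), `cluster` (1/2 from the cut), `hclust`, `newick`
#'   (dendrogram as a Newick string).
#' @export
hierarchical_cluster <- function(x, signature = NULL, case_ids = character(0),
                                 scale = TRUE, linkage = "average") {
  v <- beta_values(x)
  if (!is.null(signature)) {
    ids <- if (is.data.frame(signature)) signature$cpg else signature
    v <- v[intersect(ids, rownames(v)), , drop = FALSE]
  }
  if (ncol(v) < 2) stop("need at least two samples")
  # order-invariance: sort rows and columns by id before computing
  v <- v[order(rownames(v)), order(colnames(v)), drop = FALSE]
  ctr <- mean_center(v, scale = scale)
  d <- stats::dist(t(ctr), method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = 2)
  case_in_1 <- sum(names(cl)[cl == 1] %in% case_ids)
  case_in_2 <- sum(names(cl)[cl == 2] %in% case_ids)
  case_cluster <- if (case_in_2 > case_in_1) 2 else 1
  labels <- ifelse(cl == case_cluster, "case-like", "control-like")
  names(labels) <- names(cl)
  phy <- ape::as.phylo(hc)
  list(labels = labels, cluster = cl, hclust = hc,
       newick = ape::write.tree(phy))
}

#' Nearest-centroid classification against discovery centroids
#'
#' Computes case and control centroids from the discovery samples over
#' the signature CpGs and labels each query sample by the nearer
#' centroid in Euclidean distance; the margin is the control distance
#' minus the case distance (positive = case-like). Missing CpGs in a
#' query are deleted pairwise (distances renormalised by the CpG count
#' used) provided coverage of the signature is at least
#' `min_coverage`; CpGs missing from one sample never affect another.
#'
#' @param x query samples: [beta_matrix] or matrix (may be a single
#'   column).
#' @param discovery discovery [beta_matrix] or matrix.
#' @param groups two-level factor over discovery samples; level order
#'   (control, case) or pass explicit `case_level`.
#' @param signature `signature_set` or CpG ids.
#' @param case_level which level of `groups` marks cases (default the
#'   second level).
#' @param min_coverage minimum fraction of signature CpGs a query must
#'   cover (default 0.9).
#' @return data.frame (sample, label, margin, dist_case, dist_control);
#'   `label` is `ambiguous` at an exact tie.
#' @export
classify_nearest_centroid <- function(x, discovery, groups, signature,
                                      case_level = NULL,
                                      min_coverage = 0.9) {
  q <- beta_values(x)
  dv <- beta_values(discovery)
  ids <- if (is.data.frame(signature)) signature$cpg else signature
  ids <- intersect(ids, rownames(dv))
  if (length(ids) == 0) stop("no signature CpGs in discovery matrix")
  groups <- as.factor(groups)
  if (is.null(case_level)) case_level <- levels(groups)[2]
  cen_case <- rowMeans(dv[ids, groups == case_level, drop = FALSE],
                       na.rm = TRUE)
  cen_ctrl <- rowMeans(dv[ids, groups != case_level, drop = FALSE],
                       na.rm = TRUE)
  out <- lapply(colnames(q), function(s) {
    y <- q[match(ids, rownames(q)), s]
    ok <- !is.na(y)
    cov <- mean(ok)
    if (cov < min_coverage)
      stop(sprintf("sample '%s' covers %.0f%% of signature CpGs (< %.0f%%)",
                   s, 100 * cov, 100 * min_coverage))
    dc <- sqrt(sum((y[ok] - cen_case[ok])^2) / sum(ok))
    d0 <- sqrt(sum((y[ok] - cen_ctrl[ok])^2) / sum(ok))
    margin <- d0 - dc
    if (abs(margin) < 1e-12) margin <- 0     # numerical tie
    label <- if (margin > 0) "case-like"
             else if (margin < 0) "control-like" else "ambiguous"
    data.frame(sample = s, label = label, margin = margin,
               dist_case = dc, dist_control = d0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score a classification against known labels
#'
#' Confusion counts and rates for case-like/control-like assignments
#' against truth labels.
#'
#' @param labels named character of predicted labels (`case-like` /
#'   `control-like`), names = sample ids.
#' @param truth named character/logical of true status; `TRUE`/"case"
#'   means case.
#' @return list with `sensitivity`, `specificity`, `accuracy`,
#'   `confusion` (2x2 table), `misassigned` (sample ids).
#' @export
evaluate_signature <- function(labels, truth) {
  common <- intersect(names(labels), names(truth))
  if (length(common) == 0) stop("no overlapping sample ids")
  lab <- labels[common]
  tr <- truth[common]
  if (is.logical(tr)) tr <- ifelse(tr, "case", "control")
  tr <- ifelse(tr %in% c("case", "case-like", "TRUE"), "case", "control")
  pred <- ifelse(lab == "case-like", "case", "control")
  tp <- sum(pred == "case" & tr == "case")
  tn <- sum(pred == "control" & tr == "control")
  fp <- sum(pred == "case" & tr == "control")
  fn <- sum(pred == "control" & tr == "case")
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(common),
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(predicted = c("case", "control"),
                                          truth = c("case", "control"))),
       misassigned = common[pred != tr])
}
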