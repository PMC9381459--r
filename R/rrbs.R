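#' Overdispersion-corrected differential methylation from counts
#'
#' Per-CpG two-group comparison of methylated/coverage counts. The group
#' test statistic is the score (Pearson) chi-square of the pooled 2x2
#' table (methylated/unmethylated by group), equivalent to the score
#' test of the group coefficient in a binomial logistic regression of
#' methylated/coverage on group. Extra-binomial variation is estimated
#' per CpG as `phi_hat = Pearson X^2 / (N - 2)` from the per-sample
#' residuals of the two-proportion (alternative) model; the statistic is
#' divided by the implied variance inflation (floored at 1) and referred
#' to chi-square with 1 df, so for `phi_hat <= 1` the corrected and
#' uncorrected statistics are identical. Because the pooled statistic
#' weights reads while `phi_hat` averages samples, the dispersion is
#' converted to an intraclass correlation and re-weighted by the
#' read-weighted mean coverage of each group before dividing; with equal
#' coverage this reduces to dividing by `max(phi_hat, 1)`.
#'
#' With only a few samples per group a per-CpG dispersion estimate is
#' very noisy; by default the per-CpG estimates are squeezed across CpGs
#' by the same log-moment empirical-Bayes fit used for variance
#' moderation (`shrink_dispersion = TRUE`), which stabilises the
#' chi-square reference while leaving truly binomial data uncorrected.
#' Set it to `FALSE` for the raw per-CpG estimate.
#'
#' The effect size `meth_diff` is the pooled (count-weighted) methylated
#' proportion of the non-reference group minus the reference group.
#' CpGs with any sample below `min_coverage` are skipped and listed in
#' the `skipped` attribute.
#'
#' @param counts a `meth_counts` object (see [simulate_rrbs()] /
#'   [read_meth_counts()]).
#' @param groups two-level factor over samples; first level = reference.
#' @param min_coverage minimum per-sample coverage for a CpG to be
#'   tested (default 10).
#' @param shrink_dispersion squeeze per-CpG dispersions across CpGs?
#' @param correct apply the overdispersion correction? `FALSE` gives the
#'   naive binomial test (for comparison only).
#' @return data.frame (cpg, meth_diff, phi, phi_eff, stat, p, q) with
#'   attribute `skipped` (CpG ids not tested) and `phi_prior`.
#' @export
test_cpg_counts <- function(counts, groups, min_coverage = 10,
                            shrink_dispersion = TRUE, correct = TRUE) {
  stopifnot(inherits(counts, "meth_counts"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  meth <- counts$meth; cov <- counts$cov
  if (ncol(meth) != length(groups)) stop("groups must match samples")
  N <- ncol(meth)
  ok <- rowSums(cov < min_coverage) == 0
  skipped <- rownames(meth)[!ok]
  meth <- meth[ok, , drop = FALSE]; cov <- cov[ok, , drop = FALSE]
  g2 <- groups == levels(groups)[2]
  m1 <- rowSums(meth[, !g2, drop = FALSE]); c1 <- rowSums(cov[, !g2, drop = FALSE])
  m2 <- rowSums(meth[, g2, drop = FALSE]);  c2 <- rowSums(cov[, g2, drop = FALSE])
  if (any(c1 == 0) || any(c2 == 0)) stop("group with zero total coverage")
  p1 <- m1 / c1; p2 <- m2 / c2
  p0 <- (m1 + m2) / (c1 + c2)
  # score chi-square of the pooled 2x2 table
  num <- (c1 + c2) * (m1 * (c2 - m2) - m2 * (c1 - m1))^2
  den <- (m1 + m2) * (c1 + c2 - m1 - m2) * c1 * c2
  stat0 <- ifelse(den > 0, num / den, 0)
  # per-sample Pearson residuals under the fitted two-proportion model
  p_hat <- matrix(ifelse(rep(g2, each = nrow(meth)), p2, p1),
                  nrow = nrow(meth))
  vv <- cov * p_hat * (1 - p_hat)
  r2 <- ifelse(vv > 0, (meth - cov * p_hat)^2 / vv, 0)
  phi_raw <- rowSums(r2) / max(N - 2, 1)
  phi <- phi_raw
  phi_prior <- NULL
  if (shrink_dispersion && N > 2 && sum(phi_raw > 0) >= 10) {
    prior <- fit_f_dist(phi_raw[phi_raw > 0], rep(N - 2, sum(phi_raw > 0)))
    d0 <- prior$df_prior
    phi <- if (is.infinite(d0)) rep(prior$s2_prior, length(phi_raw))
           else (d0 * prior$s2_prior + (N - 2) * phi_raw) / (d0 + N - 2)
    phi_prior <- prior
  }
  # The pooled-proportion statistic weights reads, so its variance
  # inflation is 1 + rho * (ctilde - 1) with the read-weighted mean
  # coverage ctilde = sum(c^2)/sum(c) per group, not the per-sample
  # average that phi_hat reflects. Convert phi_hat to an intraclass
  # correlation and apply the coverage-weighted inflation.
  cbar <- rowMeans(cov)
  rho <- pmax(phi - 1, 0) / pmax(cbar - 1, 1e-8)
  ct1 <- rowSums(cov[, !g2, drop = FALSE]^2) / c1
  ct2 <- rowSums(cov[, g2, drop = FALSE]^2) / c2
  phi_eff <- ((1 + rho * (ct1 - 1)) / c1 + (1 + rho * (ct2 - 1)) / c2) /
    (1 / c1 + 1 / c2)
  stat <- if (correct) stat0 / pmax(phi_eff, 1) else stat0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out <- data.frame(cpg = rownames(meth), meth_diff = p2 - p1,
                    phi = phi, phi_eff = phi_eff, stat = stat, p = p,
                    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  attr(out, "skipped") <- skipped
  attr(out, "phi_prior") <- phi_prior
  out
}

#' Call RRBS DMPs by q-value and methylation difference
#'
#' `q < q_threshold` and `|meth_diff| > diff_threshold` (defaults 0.05
#' and 0.10 — the higher effect cutoff compensates for effect-size
#' inflation at low read depth); direction reported as hyper/hypo.
#'
#' @param x result of [test_cpg_counts()].
#' @param q_threshold FDR q cutoff.
#' @param diff_threshold absolute pooled-proportion difference cutoff.
#' @return data.frame (cpg, meth_diff, q, direction).
#' @export
call_rrbs_dmps <- function(x, q_threshold = 0.05, diff_threshold = 0.10) {
  stopifnot(q_threshold > 0, diff_threshold > 0)
  keep <- x$q < q_threshold & abs(x$meth_diff) > diff_threshold
  out <- x[keep, c("cpg", "meth_diff", "p", "q")]
  out$direction <- ifelse(out$meth_diff > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Gene annotation for CpG feature assignment
#'
#' Builds an annotation object from a BED-like data.frame with columns
#' `chrom`, `start`, `end` (1-based, closed), `gene`, `strand`
#' (`+`/`-`) and `feature` (one of `transcript`, `exon`, `5UTR`,
#' `3UTR`). Each gene needs exactly one `transcript` row (the gene
#' body); the TSS is its `start` on `+` and `end` on `-` strands.
#'
#' @param df annotation data.frame (or TSV path for
#'   `read_gene_annotation`).
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  df <- as.data.frame(df)
  need <- c("chrom", "start", "end", "gene", "strand", "feature")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (!all(df$feature %in% c("transcript", "exon", "5UTR", "3UTR")))
    stop("feature must be transcript/exon/5UTR/3UTR")
  if (any(df$end < df$start)) stop("interval end before start")
  tx <- df[df$feature == "transcript", ]
  if (anyDuplicated(tx$gene)) stop("a gene has multiple transcript rows")
  if (!all(unique(df$gene) %in% tx$gene))
    stop("every gene needs a transcript row")
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  structure(list(features = df, transcripts = tx), class = "gene_annotation")
}

#' @rdname gene_annotation
#' @param path TSV file path.
#' @export
read_gene_annotation <- function(path) {
  gene_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

feature_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         gene = df$gene)
}

#' Assign a genomic feature label to each CpG
#'
#' Each CpG receives exactly one label by precedence
#' Promoter > 5UTR > 3UTR > Exon > Intron > Downstream > Distal
#' Intergenic. Promoter is TSS +/- `tss_window` bp (strand-aware TSS);
#' Intron is inside the gene body but in no exon/UTR; Downstream is
#' within `downstream_window` bp past the gene end (strand-aware). The
#' gene id is attached for all non-intergenic labels. CpGs on
#' chromosomes absent from the annotation get Distal Intergenic with a
#' warning.
#'
#' @param positions data.frame with `cpg`, `chrom`, `pos` (1-based).
#' @param annotation a [gene_annotation()].
#' @param tss_window promoter half-window around the TSS (bp).
#' @param downstream_window window past the gene end (bp).
#' @return data.frame (cpg, chrom, pos, feature, gene).
#' @export
annotate_cpgs <- function(positions, annotation, tss_window = 3000,
                          downstream_window = 3000) {
  stopifnot(inherits(annotation, "gene_annotation"))
  pos <- as.data.frame(positions)
  if (!all(c("cpg", "chrom", "pos") %in% names(pos)))
    stop("positions need columns cpg, chrom, pos")
  unknown <- !pos$chrom %in% unique(annotation$features$chrom)
  if (any(unknown))
    warning(sum(unknown), " CpGs on chromosomes absent from annotation; ",
            "labelled Distal Intergenic")
  cg <- GenomicRanges::GRanges(pos$chrom, IRanges::IRanges(pos$pos, pos$pos))
  tx <- annotation$transcripts
  fts <- annotation$features
  prom <- data.frame(chrom = tx$chrom, start = pmax(tx$tss - tss_window, 1),
                     end = tx$tss + tss_window, gene = tx$gene)
  down <- data.frame(chrom = tx$chrom,
                     start = ifelse(tx$strand == "+", tx$end + 1,
                                    pmax(tx$start - downstream_window, 1)),
                     end = ifelse(tx$strand == "+",
                                  tx$end + downstream_window,
                                  pmax(tx$start - 1, 1)),
                     gene = tx$gene)
  layers <- list(
    Promoter = prom,
    `5UTR` = fts[fts$feature == "5UTR", c("chrom", "start", "end", "gene")],
    `3UTR` = fts[fts$feature == "3UTR", c("chrom", "start", "end", "gene")],
    Exon = fts[fts$feature == "exon", c("chrom", "start", "end", "gene")],
    Intron = tx[, c("chrom", "start", "end", "gene")],
    Downstream = down)
  feature <- rep("Distal Intergenic", nrow(pos))
  gene <- rep(NA_character_, nrow(pos))
  unassigned <- rep(TRUE, nrow(pos))
  for (nm in names(layers)) {
    lay <- layers[[nm]]
    if (nrow(lay) == 0) next
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(cg, feature_granges(lay),
                                  select = "first"))
    take <- unassigned & !is.na(hits)
    feature[take] <- nm
    gene[take] <- lay$gene[hits[take]]
    unassigned <- unassigned & is.na(hits)
  }
  data.frame(cpg = pos$cpg, chrom = pos$chrom, pos = pos$pos,
             feature = feature, gene = gene, stringsAsFactors = FALSE)
}

#' Overlap differentially methylated genes with a DEG list
#'
#' From annotated DMPs, takes the unique genes with at least one
#' proximal (non-intergenic) differentially methylated CpG, and
#' intersects them with a differential-expression gene list.
#'
#' @param annotated result of [annotate_cpgs()] restricted to DMPs.
#' @param degs character vector of differentially expressed gene ids.
#' @return list with `genes` (unique DM genes), `overlap`, and counts
#'   `n_dmps`, `n_mapped`, `n_genes`, `n_overlap`.
#' @export
overlap_dm_degs <- function(annotated, degs) {
  if (nrow(annotated) == 0) stop("empty annotation")
  mapped <- annotated[annotated$feature != "Distal Intergenic" &
                        !is.na(annotated$gene), ]
  genes <- sort(unique(mapped$gene))
  ov <- intersect(genes, degs)
  list(genes = genes, overlap = ov,
       n_dmps = nrow(annotated), n_mapped = nrow(mapped),
       n_genes = length(genes), n_overlap = length(ov))
}

#' Two-set Venn partition of gene lists
#'
#' Shared and list-unique counts for two gene lists, with each unique
#' percentage computed against its own list's total and rounded to the
#' nearest integer.
#'
#' @param a,b character vectors of gene ids (de-duplicated internally).
#' @return list with `shared`, `unique_a`, `unique_b`, `pct_unique_a`,
#'   `pct_unique_b`, `size_a`, `size_b`, `union`.
#' @export
venn_partition <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- length(intersect(a, b))
  ua <- length(a) - shared
  ub <- length(b) - shared
  list(shared = shared, unique_a = ua, unique_b = ub,
       pct_unique_a = if (length(a)) round(100 * ua / length(a)) else NA,
       pct_unique_b = if (length(b)) round(100 * ub / length(b)) else NA,
       size_a = length(a), size_b = length(b),
       union = length(union(a, b)))
}
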