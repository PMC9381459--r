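#' Pipeline configuration with layered defaults
#'
#' Returns the full parameter set for the end-to-end runs, every
#' threshold at its conventional default; pass overrides as named
#' arguments. Defaults: discovery DMP selection p < 0.005 and
#' methylation difference > 5%; age screen FDR < 0.05; mouse corrected
#' caller p < 0.01 with 5% genotype/drug minima and 5% residual
#' tolerance; RRBS q < 0.05, difference > 10%, minimum coverage 10x;
#' modelling scale beta.
#'
#' @param ... named overrides of any default.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    scale = "m",
    age_fdr = 0.05,
    dmp_p = 0.005, dmp_delta = 0.05,
    deconv_k_per_type = 100,
    covariate_cells = c("Neutrophil", "Monocyte"),
    interaction_p = 0.01, interaction_delta_min = 0.05,
    interaction_residual_max = 0.05,
    rrbs_q = 0.05, rrbs_diff = 0.10, rrbs_min_coverage = 10,
    screen_alpha = 0.05,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_manifest <- function(out_dir, stage, params, files) {
  manifest <- list(stage = stage, params = params,
                   files = lapply(files, function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the discovery episignature workflow end to end
#'
#' Deconvolve cell proportions, screen out age-associated CpGs, fit the
#' covariate-adjusted per-CpG model with variance moderation, select
#' signature DMPs, and validate on any test samples by joint PCA,
#' hierarchical clustering and nearest-centroid scoring. Artifacts
#' (DMP table, signature set, classification, run manifest with file
#' hashes) are written when `out_dir` is given.
#'
#' @param beta discovery+test [beta_matrix] (columns = all samples).
#' @param sheet sample sheet with `sample_id`, `cohort`
#'   (discovery/test), `group` (case/control/disease_control), `age`.
#' @param reference cell-type reference for deconvolution
#'   ([simulate_cell_reference()] format or matrix).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `proportions`, `age_cpgs`, `dmp_table`,
#'   `signature`, `pca`, `clustering`, `classification`.
#' @export
run_discovery <- function(beta, sheet, reference,
                          config = pipeline_config(), out_dir = NULL) {
  for (col in c("sample_id", "cohort", "group", "age"))
    if (!col %in% names(sheet))
      stop("sample sheet is missing required column '", col, "'")
  if (!all(colnames(beta$values) %in% sheet$sample_id))
    stop("matrix columns missing from sample sheet")
  sheet <- sheet[match(colnames(beta$values), sheet$sample_id), ]
  disc <- sheet$cohort == "discovery"
  message(sprintf("discovery: %d samples (%d discovery, %d test), %d CpGs",
                  nrow(sheet), sum(disc), sum(!disc), nrow(beta$values)))

  props <- estimate_proportions(beta, reference)
  covs <- props$normalized[, intersect(config$covariate_cells,
                                       colnames(props$normalized)),
                           drop = FALSE]
  dsheet <- cbind(sheet, covs[sheet$sample_id, , drop = FALSE])

  dv <- beta$values[, disc, drop = FALSE]
  dsub <- dsheet[disc, ]
  age_cpgs <- age_cpg_screen(dv, dsub$age, fdr_threshold = config$age_fdr,
                             scale = config$scale)
  keep <- setdiff(rownames(dv), age_cpgs)
  message(sprintf("age screen: %d CpGs removed, %d retained",
                  length(age_cpgs), length(keep)))

  dsub$group <- factor(dsub$group, levels = c("control", "case"))
  X <- build_design(dsub, main = "group",
                    covariates = c("age", colnames(covs)))
  fit <- fit_cpg_models(dv[keep, , drop = FALSE], X, scale = config$scale,
                        groups = dsub$group)
  dmp <- ebayes_moderate(fit, coef = "groupcase")
  sig <- select_dmps(dmp, p_threshold = config$dmp_p,
                     delta_threshold = config$dmp_delta)
  message(sprintf("signature: %d DMPs selected", nrow(sig)))
  if (nrow(sig) == 0) stop("discovery stage produced an empty signature")

  pca <- pca_project(beta, sig)
  case_ids <- sheet$sample_id[disc & sheet$group == "case"]
  clus <- hierarchical_cluster(beta, sig, case_ids = case_ids)
  test_ids <- sheet$sample_id[!disc]
  cls <- NULL
  if (length(test_ids) > 0)
    cls <- classify_nearest_centroid(beta$values[, test_ids, drop = FALSE],
                                     dv, dsub$group, sig,
                                     case_level = "case")
  res <- list(proportions = props, age_cpgs = age_cpgs, dmp_table = dmp,
              signature = sig, pca = pca, clustering = clus,
              classification = cls)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      dmp = write_dmp_table(dmp, file.path(out_dir, "dmp_table.tsv")),
      signature = write_dmp_table(sig, file.path(out_dir, "signature.tsv")))
    utils::write.csv(data.frame(sample = names(clus$labels),
                                cluster = clus$cluster,
                                label = clus$labels,
                                pca$coordinates[names(clus$labels), ]),
                     file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(out_dir, "classification.csv"))
    writeLines(clus$newick, file.path(out_dir, "dendrogram.nwk"))
    files <- c(files, file.path(out_dir, "dendrogram.nwk"))
    write_manifest(out_dir, "discovery", config, files)
  }
  res
}

#' Run the mouse genotype-by-drug correction workflow
#'
#' @param beta mouse [beta_matrix].
#' @param sheet sample sheet with `sample_id`, `genotype`, `treatment`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `interaction` (per-CpG results) and `corrected`
#'   (called CpG ids).
#' @export
run_mouse <- function(beta, sheet, config = pipeline_config(),
                      out_dir = NULL) {
  for (col in c("sample_id", "genotype", "treatment"))
    if (!col %in% names(sheet))
      stop("sample sheet is missing required column '", col, "'")
  sheet <- sheet[match(colnames(beta$values), sheet$sample_id), ]
  res <- fit_interaction(beta, sheet$genotype, sheet$treatment,
                         scale = config$scale)
  corrected <- call_corrected_dmps(
    res, p_threshold = config$interaction_p,
    geno_min = config$interaction_delta_min,
    drug_min = config$interaction_delta_min,
    residual_max = config$interaction_residual_max)
  message(sprintf("mouse: %d CpGs tested, %d corrected DMPs called",
                  nrow(res), length(corrected)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "interaction.tsv")
    utils::write.table(as.data.frame(res), f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- file.path(out_dir, "corrected_dmps.tsv")
    utils::write.table(data.frame(cpg = corrected), f2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "mouse", config, c(f1, f2))
  }
  list(interaction = res, corrected = corrected)
}

#' Run the count-based (RRBS) differential methylation workflow
#'
#' @param counts a `meth_counts` object.
#' @param groups two-level factor over samples.
#' @param annotation optional [gene_annotation()] for feature labels.
#' @param degs optional DEG id vector for the expression overlap.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `results`, `dmps`, and (when inputs allow)
#'   `annotated`, `overlap`.
#' @export
run_rrbs <- function(counts, groups, annotation = NULL, degs = NULL,
                     config = pipeline_config(), out_dir = NULL) {
  res <- test_cpg_counts(counts, groups,
                         min_coverage = config$rrbs_min_coverage)
  dmps <- call_rrbs_dmps(res, q_threshold = config$rrbs_q,
                         diff_threshold = config$rrbs_diff)
  message(sprintf("rrbs: %d CpGs tested (%d skipped), %d DMPs called",
                  nrow(res), length(attr(res, "skipped")), nrow(dmps)))
  out <- list(results = res, dmps = dmps)
  if (!is.null(annotation) && nrow(dmps) > 0) {
    pos <- counts$coords[match(dmps$cpg, counts$coords$cpg),
                         c("cpg", "chrom", "pos")]
    out$annotated <- annotate_cpgs(pos, annotation)
    if (!is.null(degs))
      out$overlap <- overlap_dm_degs(out$annotated, degs)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "rrbs_results.tsv")
    utils::write.table(res, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out_dir, "rrbs_dmps.tsv")
    utils::write.table(dmps, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "rrbs", config, c(f1, f2))
  }
  out
}

#' Run the ordinal-screen statistics workflow
#'
#' Global Kruskal-Wallis with Dunn's post test against the vehicle;
#' chemicals whose vehicle comparison passes `screen_alpha` after
#' adjustment are flagged, with direction from the mean-rank difference
#' (suppressor = lower mean rank than vehicle).
#'
#' @param scores long data.frame (larva, chemical, score).
#' @param vehicle vehicle condition label.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `test` (the [kruskal_wallis_dunn()] result) and
#'   `hits` (data.frame chemical, z, p_adj, direction).
#' @export
run_screen <- function(scores, vehicle = "DMSO",
                       config = pipeline_config(), out_dir = NULL) {
  kw <- kruskal_wallis_dunn(scores)
  pw <- kw$pairwise
  vs_veh <- pw[pw$group1 == vehicle | pw$group2 == vehicle, ]
  other <- ifelse(vs_veh$group1 == vehicle, vs_veh$group2, vs_veh$group1)
  dir_sign <- ifelse(vs_veh$group1 == vehicle, -vs_veh$z, vs_veh$z)
  hits <- data.frame(chemical = other, z = dir_sign, p_adj = vs_veh$p_adj,
                     direction = ifelse(dir_sign < 0, "suppressor",
                                        "enhancer"),
                     stringsAsFactors = FALSE)
  hits <- hits[hits$p_adj < config$screen_alpha, ]
  message(sprintf("screen: H = %.2f (p = %.3g), %d chemicals flagged",
                  kw$H, kw$p, nrow(hits)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(out_dir, "screen_hits.csv")
    utils::write.csv(hits, f, row.names = FALSE)
    write_manifest(out_dir, "screen", config, f)
  }
  list(test = kw, hits = hits)
}
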