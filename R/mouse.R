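#' Genotype-by-treatment interaction model per CpG
#'
#' Fits a two-factor linear model with interaction
#' (`~ genotype * treatment`) to every CpG and computes the three
#' group-mean effects used by the drug-correction caller, all on the
#' beta scale:
#' \describe{
#'   \item{effect_geno}{mean(KO-vehicle) - mean(WT-vehicle), the
#'     genotype effect under vehicle;}
#'   \item{effect_drug}{mean(KO-vehicle) - mean(KO-drug), the drug
#'     effect within KO;}
#'   \item{effect_residual}{mean(KO-drug) - mean(WT-vehicle), how far
#'     the treated KO remains from the WT baseline.}
#' }
#' By construction `effect_geno - effect_drug = effect_residual`
#' exactly. The interaction-term p-value comes from the empirical-Bayes
#' moderated t ([ebayes_moderate()]).
#'
#' @param x a [beta_matrix] or matrix.
#' @param genotype factor/character, reference level first (WT);
#'   two levels.
#' @param treatment factor/character, reference level first (vehicle);
#'   two levels.
#' @param scale modelling scale for the interaction test
#'   (`"beta"`/`"m"`); effects are always beta-scale group means.
#' @return object of class `interaction_result`: data.frame (cpg,
#'   effect_geno, effect_drug, effect_residual, t, p, q) with prior
#'   hyperparameters as attributes.
#' @export
fit_interaction <- function(x, genotype, treatment,
                            scale = c("m", "beta")) {
  scale <- match.arg(scale)
  v <- beta_values(x)
  genotype <- stats::relevel(as.factor(genotype),
                             ref = intersect(c("WT", levels(as.factor(genotype))),
                                             as.character(genotype))[1])
  treatment <- stats::relevel(as.factor(treatment),
                              ref = intersect(c("vehicle",
                                                levels(as.factor(treatment))),
                                              as.character(treatment))[1])
  if (nlevels(genotype) != 2 || nlevels(treatment) != 2)
    stop("genotype and treatment must each have two levels")
  cells <- table(genotype, treatment)
  if (any(cells < 2)) stop("every design cell needs at least 2 samples")
  X <- stats::model.matrix(~ genotype * treatment)
  fit <- fit_cpg_models(v, X, scale = scale)
  tab <- ebayes_moderate(fit, coef = ncol(X))  # interaction term
  ko <- levels(genotype)[2]; drug <- levels(treatment)[2]
  wt_veh <- rowMeans(v[, genotype != ko & treatment != drug, drop = FALSE])
  ko_veh <- rowMeans(v[, genotype == ko & treatment != drug, drop = FALSE])
  ko_drug <- rowMeans(v[, genotype == ko & treatment == drug, drop = FALSE])
  eff <- data.frame(cpg = rownames(v),
                    effect_geno = ko_veh - wt_veh,
                    effect_drug = ko_veh - ko_drug,
                    effect_residual = ko_drug - wt_veh,
                    stringsAsFactors = FALSE)
  out <- merge(eff, as.data.frame(tab)[c("cpg", "t", "p", "q")],
               by = "cpg", sort = TRUE)
  attr(out, "df_prior") <- attr(tab, "df_prior")
  attr(out, "s2_prior") <- attr(tab, "s2_prior")
  class(out) <- c("interaction_result", "data.frame")
  out
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction_result: %d CpGs (prior df %.2f)\n",
              nrow(x), attr(x, "df_prior")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Call drug-corrected DMPs by the triple effect-size criterion
#'
#' Reports a CpG as drug-corrected iff all of:
#' interaction `p < p_threshold`; `|effect_geno| > geno_min` (a genotype
#' effect exists under vehicle); `|effect_drug| > drug_min` (the drug
#' moved methylation within KO); and `|effect_residual| < residual_max`
#' (the treated KO has returned to within the residual tolerance of the
#' WT baseline). Defaults: p < 0.01 and 5% for all three effect bounds.
#' Pure threshold logic, reproducible by brute-force enumeration.
#'
#' @param x an `interaction_result`.
#' @param p_threshold interaction p cutoff (default 0.01; 0.05 is the
#'   laxer conventional alternative).
#' @param geno_min,drug_min minimum absolute genotype / drug effects.
#' @param residual_max maximum absolute residual effect; must not
#'   exceed `min(geno_min, drug_min)`.
#' @param sign_consistent additionally require the drug effect to share
#'   the genotype effect's sign (off by default; the residual criterion
#'   already enforces return-toward-baseline).
#' @return character vector of corrected CpG ids.
#' @export
call_corrected_dmps <- function(x, p_threshold = 0.01, geno_min = 0.05,
                                drug_min = 0.05, residual_max = 0.05,
                                sign_consistent = FALSE) {
  stopifnot(p_threshold > 0, geno_min > 0, drug_min > 0, residual_max > 0)
  if (residual_max > min(geno_min, drug_min))
    stop("residual_max must not exceed min(geno_min, drug_min)")
  keep <- x$p < p_threshold &
    abs(x$effect_geno) > geno_min &
    abs(x$effect_drug) > drug_min &
    abs(x$effect_residual) < residual_max
  if (sign_consistent)
    keep <- keep & sign(x$effect_drug) == sign(x$effect_geno)
  x$cpg[keep]
}
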