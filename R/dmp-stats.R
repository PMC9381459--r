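#' Build a design matrix from a sample sheet
#'
#' Intercept + main effect (case status or genotype) + any numeric
#' covariates, checked for full column rank and row alignment with the
#' methylation matrix columns.
#'
#' @param sheet sample sheet data.frame with `sample_id`.
#' @param main name of the main-effect column (two-level factor; the
#'   first level is the reference).
#' @param covariates character vector of covariate column names.
#' @return numeric design matrix with rownames = sample ids.
#' @export
build_design <- function(sheet, main = "group", covariates = character(0)) {
  stopifnot(main %in% names(sheet), all(covariates %in% names(sheet)))
  f <- stats::as.formula(paste("~", paste(c(main, covariates),
                                          collapse = " + ")))
  X <- stats::model.matrix(f, data = sheet)
  rownames(X) <- sheet$sample_id
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

#' Per-CpG ordinary least squares over a common design
#'
#' Fits the same linear model to every CpG row by a single QR
#' decomposition of the design. `scale = "m"` fits on M-values
#' (log2 beta odds); regardless of the modelling scale, the reported
#' effect size is the difference in group mean *beta* between the two
#' levels of `groups` ("methylation difference", fraction units).
#'
#' Zero-variance CpGs get `sigma = 0` and are flagged so the moderation
#' step can exclude them from hyperparameter estimation.
#'
#' @param x a [beta_matrix] or CpG x sample matrix of betas.
#' @param design numeric design matrix (samples x predictors), full
#'   column rank, rows aligned with columns of `x`.
#' @param scale `"m"` (default; exact Gaussian error model for
#'   logit-scale noise) or `"beta"`.
#' @param groups optional two-level factor giving the case/control (or
#'   KO/WT) split used for the beta-scale effect size; the effect is
#'   level 2 minus level 1.
#' @param eps clipping bound for the M transform.
#' @return object of class `cpg_fit`: list with `coefficients` (CpG x
#'   predictor), `sigma`, `df_residual`, `stdev_unscaled`, `effect`,
#'   `zero_variance`, `scale`, `cpg`, plus `coords` when available.
#' @export
fit_cpg_models <- function(x, design, scale = c("m", "beta"),
                           groups = NULL, eps = 0.001) {
  scale <- match.arg(scale)
  v <- beta_values(x)
  design <- as.matrix(design)
  n <- ncol(v)
  if (nrow(design) != n) stop("design rows must match matrix columns")
  p <- ncol(design)
  if (n <= p) stop("need more samples than predictors")
  qrX <- qr(design)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  y <- if (scale == "m") beta_to_m(v, eps) else v
  coef <- t(qr.coef(qrX, t(y)))
  fitted <- coef %*% t(design)
  res <- y - fitted
  d_g <- n - p
  s2 <- rowSums(res^2) / d_g
  sigma <- sqrt(pmax(s2, 0))
  zero_var <- sigma < 1e-12
  XtX_inv <- chol2inv(qr.R(qrX))
  stdev_unscaled <- sqrt(diag(XtX_inv))
  names(stdev_unscaled) <- colnames(design)
  effect <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2) stop("groups must have two levels")
    effect <- rowMeans(v[, groups == levels(groups)[2], drop = FALSE],
                       na.rm = TRUE) -
      rowMeans(v[, groups == levels(groups)[1], drop = FALSE], na.rm = TRUE)
  }
  structure(list(coefficients = coef, sigma = sigma,
                 df_residual = rep(d_g, nrow(v)),
                 stdev_unscaled = stdev_unscaled,
                 effect = effect, zero_variance = zero_var,
                 scale = scale, cpg = rownames(v),
                 coords = if (inherits(x, "beta_matrix")) x$coords else NULL),
            class = "cpg_fit")
}

#' @export
print.cpg_fit <- function(x, ...) {
  cat(sprintf("cpg_fit: %d CpGs, %d coefficients, %d residual df, %s scale\n",
              length(x$cpg), ncol(x$coefficients), x$df_residual[1],
              x$scale))
  invisible(x)
}

# Newton solve of trigamma(y) = x; monotone decreasing, convex in 1/y.
# Same iteration idea as the classic moment-matching estimator.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Moment-matching fit of the scaled-F prior predictive to log s^2:
# log s_g^2 - digamma(d_g/2) + log(d_g/2) has mean log s0^2 +
# digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2) beyond
# trigamma(d_g/2). Solving the trigamma equation by monotone
# root-finding gives d0; no finite root (sample variance below the
# chi-square noise floor) means d0 = Inf and s0^2 = the geometric-mean
# variance.
fit_f_dist <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 10)
    stop("need at least 10 positive variances for moderation")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in log s^2 beyond chi-square sampling noise:
    # infinite prior df. With genuinely varying s^2 the consistent scale
    # estimate is the digamma-corrected exp(mean(e)); if the variances
    # are exactly equal (degenerate input) that correction would move
    # them, so return the common value unchanged.
    d0 <- Inf
    s0_2 <- if (stats::var(z) < 1e-15) exp(mean(z)) else exp(emean)
  }
  list(df_prior = d0, s2_prior = s0_2)
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Shrinks per-CpG residual variances toward a common prior estimated
#' from all CpGs, then tests one coefficient with the moderated t on
#' augmented degrees of freedom. The posterior variance is
#' `s2_post = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` with the prior
#' `(d0, s0^2)` fitted by matching the first two moments of `log s_g^2`
#' to the scaled-F prior predictive (digamma/trigamma moment equations,
#' monotone Newton root-finding). When the trigamma equation has no
#' finite solution, `d0 = Inf` and every posterior variance equals
#' `s0^2`. Zero-variance CpGs are excluded from the prior fit but still
#' receive a (prior-driven) statistic.
#'
#' @param fit a [fit_cpg_models()] result.
#' @param coef name or index of the tested coefficient (default 2, the
#'   main effect).
#' @return a `dmp_table` data.frame: cpg (+ chrom/pos when available),
#'   effect, coefficient, sigma, df, s2_post, t, p, q (BH), direction;
#'   attributes `df_prior`, `s2_prior`, `coef`.
#' @export
ebayes_moderate <- function(fit, coef = 2) {
  stopifnot(inherits(fit, "cpg_fit"))
  if (all(fit$zero_variance)) stop("all CpG variances are zero")
  j <- if (is.character(coef)) match(coef, colnames(fit$coefficients)) else coef
  if (is.na(j) || j < 1 || j > ncol(fit$coefficients))
    stop("unknown coefficient")
  s2 <- fit$sigma^2
  d <- fit$df_residual
  prior <- fit_f_dist(s2[!fit$zero_variance], d[!fit$zero_variance])
  d0 <- prior$df_prior; s0_2 <- prior$s2_prior
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + d * s2) / (d0 + d)
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  b <- fit$coefficients[, j]
  tstat <- b / (sqrt(s2_post) * fit$stdev_unscaled[j])
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  effect <- if (!is.null(fit$effect)) fit$effect else b
  tab <- data.frame(cpg = fit$cpg, effect = effect, coefficient = b,
                    sigma = fit$sigma, df = d, s2_post = s2_post,
                    t = tstat, p = p, stringsAsFactors = FALSE)
  if (!is.null(fit$coords)) {
    tab$chrom <- fit$coords$chrom[match(tab$cpg, fit$coords$cpg)]
    tab$pos <- fit$coords$pos[match(tab$cpg, fit$coords$cpg)]
  }
  # stable order on cpg id for reproducible BH ties
  tab <- tab[order(tab$cpg), ]
  tab$q <- bh_fdr(tab$p)
  tab$direction <- ifelse(tab$effect > 0, "hyper",
                          ifelse(tab$effect < 0, "hypo", "none"))
  rownames(tab) <- NULL
  attr(tab, "df_prior") <- d0
  attr(tab, "s2_prior") <- s0_2
  attr(tab, "coef") <- colnames(fit$coefficients)[j]
  class(tab) <- c("dmp_table", "data.frame")
  tab
}

#' @export
print.dmp_table <- function(x, ...) {
  cat(sprintf("dmp_table: %d CpGs (coef '%s'; prior df %.2f, prior s0 %.4f)\n",
              nrow(x), attr(x, "coef"), attr(x, "df_prior"),
              sqrt(attr(x, "s2_prior"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values with enforced monotonicity, order-preserving
#' (q returned in the input order). A validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p numeric p-values in \[0,1\].
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen for age-associated CpGs
#'
#' Per-CpG simple regression on age with empirical-Bayes moderation and
#' BH correction; CpGs with `q < fdr_threshold` are returned for removal
#' before the case/control model is fit, so age-driven variation cannot
#' masquerade as disease signal.
#'
#' @param x a [beta_matrix] or matrix.
#' @param ages numeric ages (years), one per sample; must vary.
#' @param fdr_threshold BH threshold in (0,1); default 0.05.
#' @param scale modelling scale, see [fit_cpg_models()].
#' @return character vector of removable CpG ids.
#' @export
age_cpg_screen <- function(x, ages, fdr_threshold = 0.05,
                           scale = c("m", "beta")) {
  scale <- match.arg(scale)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  ages <- as.numeric(ages)
  if (stats::sd(ages) == 0) stop("ages are constant; cannot screen on age")
  X <- cbind(`(Intercept)` = 1, age = ages)
  fit <- fit_cpg_models(x, X, scale = scale)
  tab <- ebayes_moderate(fit, coef = "age")
  tab$cpg[tab$q < fdr_threshold]
}

#' Select signature DMPs by nominal p and methylation difference
#'
#' Keeps CpGs with `p < p_threshold` and `|effect| > delta_threshold`
#' (both strict), the dual effect-size/significance rule used for
#' episignature discovery; defaults 0.005 and 0.05 (5% methylation
#' difference).
#'
#' @param dmp a `dmp_table` from [ebayes_moderate()].
#' @param p_threshold nominal p cutoff.
#' @param delta_threshold absolute methylation-difference cutoff
#'   (fraction units).
#' @return object of class `signature_set`: data.frame (cpg, effect, p,
#'   q, direction) with threshold provenance attributes.
#' @export
select_dmps <- function(dmp, p_threshold = 0.005, delta_threshold = 0.05) {
  stopifnot(p_threshold > 0, delta_threshold > 0)
  if (nrow(dmp) == 0) stop("empty DMP table")
  keep <- dmp$p < p_threshold & abs(dmp$effect) > delta_threshold
  out <- as.data.frame(dmp)[keep, intersect(
    c("cpg", "chrom", "pos", "effect", "t", "p", "q", "direction"),
    names(dmp)), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_threshold
  attr(out, "delta_threshold") <- delta_threshold
  class(out) <- c("signature_set", "data.frame")
  out
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(
    "signature_set: %d DMPs (%d hyper, %d hypo) at p < %g, |diff| > %g\n",
    nrow(x), sum(x$direction == "hyper"), sum(x$direction == "hypo"),
    attr(x, "p_threshold"), attr(x, "delta_threshold")))
  invisible(x)
}

#' Write a DMP table or signature set as TSV
#' @param x `dmp_table` or `signature_set`.
#' @param path file path.
#' @export
write_dmp_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
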