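#' Synthetic blood cell-type methylation reference
#'
#' Builds a cell-type reference panel of beta profiles for use with
#' [estimate_proportions()]. Most CpGs share a common baseline across cell
#' types; each type additionally receives `n_markers_per_type`
#' discriminating CpGs, half hypermethylated and half hypomethylated in
#' that type relative to the others, emulating the structure a sorted-cell
#' reference provides for constrained-projection deconvolution.
#'
#' @param n_cpg number of CpGs in the panel.
#' @param cell_types character vector (>= 2 unique names); default the
#'   six-type blood panel (CD8T, CD4T, B, NK, Neutrophil, Monocyte).
#' @param n_markers_per_type discriminating CpGs planted per type.
#' @param marker_delta beta offset of a marker CpG in its own type.
#' @param seed integer seed.
#' @return object of class `cell_reference`: list with `profiles`
#'   (CpG x cell-type matrix in \[0,1\]), `cell_types`, and `markers`
#'   (data.frame cpg, cell_type, direction).
#' @export
simulate_cell_reference <- function(n_cpg = 2000,
                                    cell_types = c("CD8T", "CD4T", "B", "NK",
                                                   "Neutrophil", "Monocyte"),
                                    n_markers_per_type = 100,
                                    marker_delta = 0.4, seed = 1) {
  stopifnot(length(unique(cell_types)) >= 2,
            n_markers_per_type * length(cell_types) <= n_cpg)
  set.seed(seed)
  k <- length(cell_types)
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpg))
  # bimodal array-like baseline
  base <- ifelse(stats::runif(n_cpg) < 0.5,
                 stats::rbeta(n_cpg, 2, 8), stats::rbeta(n_cpg, 8, 2))
  base <- pmin(pmax(base, 0.05), 0.95)
  prof <- matrix(rep(base, k), ncol = k,
                 dimnames = list(cpg_ids, cell_types))
  marker_idx <- matrix(sample.int(n_cpg, n_markers_per_type * k),
                       ncol = k)
  markers <- NULL
  for (j in seq_len(k)) {
    idx <- marker_idx[, j]
    if (length(idx) == 0) next
    half <- length(idx) %/% 2
    up <- idx[seq_len(half)]
    dn <- idx[-seq_len(half)]
    prof[up, j] <- pmin(prof[up, j] + marker_delta, 0.98)
    prof[dn, j] <- pmax(prof[dn, j] - marker_delta, 0.02)
    markers <- rbind(markers,
                     data.frame(cpg = cpg_ids[c(up, dn)],
                                cell_type = cell_types[j],
                                direction = rep(c("hyper", "hypo"),
                                                c(length(up), length(dn)))))
  }
  structure(list(profiles = prof, cell_types = cell_types,
                 markers = markers),
            class = "cell_reference")
}

#' @export
print.cell_reference <- function(x, ...) {
  cat(sprintf("cell_reference: %d CpGs x %d cell types (%s)\n",
              nrow(x$profiles), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

clamp_beta <- function(b, lo = 0.001, hi = 0.999) pmin(pmax(b, lo), hi)

# logit-normal noise: Gaussian on the logit scale, back-transformed —
# keeps betas in (0,1) and reproduces the mean-dependent variance of
# array replicates.
add_logit_noise <- function(beta, sd) {
  if (sd == 0) return(clamp_beta(beta))
  stats::plogis(stats::qlogis(clamp_beta(beta)) +
                stats::rnorm(length(beta), 0, sd))
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Blood-like mixing: the neutrophil fraction dominates between-sample
# variation (Beta draw); the remainder is split among the other types by
# a tightly concentrated Dirichlet, so minor-type fractions co-vary
# (inversely) with neutrophils as they do in whole blood — the property
# that lets a neutrophil covariate stand in for the lymphocyte subsets.
rblood_mix <- function(n, cell_types, neutrophil_mean = 0.55,
                       neutrophil_conc = 40, remainder_conc = 150) {
  k <- length(cell_types)
  neu <- match("Neutrophil", cell_types)
  if (is.na(neu))   # no neutrophil column: plain symmetric Dirichlet
    return(rdirichlet(n, rep(5, k)))
  p_n <- stats::rbeta(n, neutrophil_mean * neutrophil_conc,
                      (1 - neutrophil_mean) * neutrophil_conc)
  comp <- c(CD8T = 0.12, CD4T = 0.25, B = 0.12, NK = 0.10,
            Monocyte = 0.16)
  others <- setdiff(seq_len(k), neu)
  w <- comp[cell_types[others]]
  w[is.na(w)] <- mean(comp)
  w <- w / sum(w)
  rest <- rdirichlet(n, remainder_conc * w)
  out <- matrix(NA_real_, n, k)
  out[, neu] <- p_n
  out[, others] <- rest * (1 - p_n)
  colnames(out) <- cell_types
  out
}

#' Simulate a case/control methylation cohort with planted episignature
#'
#' Generates a beta matrix whose per-sample expectation is a mixture of
#' cell-type reference profiles (Dirichlet-drawn proportions), plus an
#' age-associated slope at a subset of CpGs, plus a planted signed
#' delta-beta at the signature CpGs for case samples; logit-normal noise
#' is then applied and values clamped to \[0.001, 0.999\]. Defaults mirror
#' a rare-disease discovery design of 12 cases vs 21 controls. Planted
#' signature magnitudes are drawn uniformly in `[delta, 2*delta]` with
#' random sign (flipped toward the interior where a shift would leave
#' (0,1)).
#'
#' Passing `truth` from a previous call re-uses its planted signature and
#' age effects, producing an independent test cohort that carries the same
#' episignature; `n_disease` adds disease-control samples that carry a
#' perturbation of their own at non-signature CpGs but not the signature.
#'
#' @param n_case,n_control,n_disease group sizes.
#' @param n_cpg total CpGs (ignored when `truth` is supplied).
#' @param n_signature planted signature CpGs.
#' @param delta minimum absolute planted delta-beta, in (0, 0.5).
#' @param cell_reference a [simulate_cell_reference()] panel; one is
#'   generated (seeded from `seed`) when `NULL`.
#' @param age_range ages drawn uniformly in this range (years).
#' @param age_frac fraction of CpGs given an age slope.
#' @param age_slope beta change per year at age CpGs.
#' @param noise_sd sd of the logit-scale noise.
#' @param neutrophil_mean,neutrophil_conc Beta parameters of the
#'   neutrophil fraction (mean and concentration); the remaining types
#'   split the residual fraction by a concentrated Dirichlet, so their
#'   fractions co-vary inversely with neutrophils as in whole blood.
#' @param case_neutrophil_mean optional case-specific neutrophil mean
#'   (confound stressor, e.g. elevated neutrophils in cases).
#' @param cohort cohort label written to the sample sheet.
#' @param truth optional truth manifest from a previous call.
#' @param seed integer seed; outputs are reproducible from it.
#' @return list with `beta` ([beta_matrix]), `sheet` (sample sheet
#'   data.frame) and `truth` (list: `signature` data.frame(cpg, delta),
#'   `age` data.frame(cpg, slope), `proportions`, `noise_sd`, `seed`).
#' @export
simulate_cohort <- function(n_case = 12, n_control = 21, n_disease = 0,
                            n_cpg = 20000, n_signature = 416, delta = 0.05,
                            cell_reference = NULL, age_range = c(0, 60),
                            age_frac = 0.03, age_slope = 0.004,
                            noise_sd = 0.1, neutrophil_mean = 0.55,
                            neutrophil_conc = 40,
                            case_neutrophil_mean = NULL,
                            cohort = "discovery", truth = NULL, seed = 1) {
  stopifnot(n_case >= 1, n_control >= 1, delta >= 0, delta < 0.5,
            n_signature <= n_cpg)
  set.seed(seed)
  if (is.null(cell_reference) && is.null(truth))
    cell_reference <- simulate_cell_reference(n_cpg = n_cpg, seed = seed + 1)
  if (!is.null(truth)) {
    cell_reference <- truth$cell_reference
    n_cpg <- nrow(cell_reference$profiles)
  }
  prof <- cell_reference$profiles
  if (nrow(prof) != n_cpg) {
    # extend the panel with non-discriminating CpGs up to n_cpg
    extra <- n_cpg - nrow(prof)
    if (extra < 0) stop("cell reference has more CpGs than n_cpg")
    if (extra > 0) {
      base <- ifelse(stats::runif(extra) < 0.5,
                     stats::rbeta(extra, 2, 8), stats::rbeta(extra, 8, 2))
      base <- pmin(pmax(base, 0.05), 0.95)
      add <- matrix(rep(base, ncol(prof)), ncol = ncol(prof))
      rownames(add) <- sprintf("cg%07d", nrow(prof) + seq_len(extra))
      colnames(add) <- colnames(prof)
      prof <- rbind(prof, add)
      cell_reference$profiles <- prof
    }
  }
  cpg_ids <- rownames(prof)
  k <- ncol(prof)

  n <- n_case + n_control + n_disease
  group <- rep(c("case", "control", "disease_control"),
               c(n_case, n_control, n_disease))
  sample_id <- sprintf("%s_%s%02d", cohort, c("case", "ctrl", "dis")[
    match(group, c("case", "control", "disease_control"))],
    stats::ave(seq_len(n), group, FUN = seq_along))
  age <- stats::runif(n, age_range[1], age_range[2])

  props <- matrix(NA_real_, n, k, dimnames = list(sample_id, colnames(prof)))
  is_case <- group == "case"
  mu_case <- if (is.null(case_neutrophil_mean)) neutrophil_mean
             else case_neutrophil_mean
  props[!is_case, ] <- rblood_mix(sum(!is_case), colnames(prof),
                                  neutrophil_mean, neutrophil_conc)
  if (any(is_case))
    props[is_case, ] <- rblood_mix(sum(is_case), colnames(prof),
                                   mu_case, neutrophil_conc)

  if (is.null(truth)) {
    sig_idx <- sample.int(n_cpg, n_signature)
    sig_delta <- stats::runif(n_signature, delta, 2 * delta) *
      sample(c(-1, 1), n_signature, replace = TRUE)
    if (delta == 0) sig_delta <- rep(0, n_signature)
    base_mean <- rowMeans(prof)[sig_idx]
    # flip planted sign where the shift would push the expectation out of (0,1)
    flip <- (base_mean + sig_delta > 0.98) | (base_mean + sig_delta < 0.02)
    sig_delta[flip] <- -sig_delta[flip]
    out <- (base_mean + sig_delta > 0.99) | (base_mean + sig_delta < 0.01)
    if (any(out)) stop("planted delta forces expected beta outside (0,1)")
    n_age <- round(age_frac * n_cpg)
    age_idx <- sample(setdiff(seq_len(n_cpg), sig_idx), n_age)
    age_sl <- age_slope * sample(c(-1, 1), n_age, replace = TRUE)
    # keep age trajectory inside (0,1) across the age range
    span <- age_sl * diff(age_range)
    bm <- rowMeans(prof)[age_idx]
    flip <- (bm + span > 0.95) | (bm + span < 0.05)
    age_sl[flip] <- -age_sl[flip]
    signature <- data.frame(cpg = cpg_ids[sig_idx], delta = sig_delta)
    age_tab <- data.frame(cpg = cpg_ids[age_idx], slope = age_sl)
  } else {
    signature <- truth$signature
    age_tab <- truth$age
    sig_idx <- match(signature$cpg, cpg_ids)
    age_idx <- match(age_tab$cpg, cpg_ids)
  }

  expected <- prof %*% t(props)            # n_cpg x n
  expected[age_idx, ] <- expected[age_idx, ] +
    outer(age_tab$slope, age - mean(age_range))
  if (any(is_case))
    expected[sig_idx, is_case] <- expected[sig_idx, is_case] + signature$delta
  if (n_disease > 0) {
    # disease controls carry their own perturbation at other CpGs
    is_dis <- group == "disease_control"
    free <- setdiff(seq_len(n_cpg), c(sig_idx, age_idx))
    dis_idx <- sample(free, min(length(free), length(sig_idx)))
    dis_delta <- stats::runif(length(dis_idx), delta, 2 * delta) *
      sample(c(-1, 1), length(dis_idx), replace = TRUE)
    expected[dis_idx, is_dis] <- clamp_beta(
      expected[dis_idx, is_dis] + dis_delta, 0.01, 0.99)
  }
  expected <- clamp_beta(expected, 0.001, 0.999)
  vals <- matrix(add_logit_noise(expected, noise_sd), nrow = n_cpg,
                 dimnames = list(cpg_ids, sample_id))
  vals <- clamp_beta(vals)

  chrom <- sample(paste0("chr", c(1:19, "X")), n_cpg, replace = TRUE)
  coords <- data.frame(cpg = cpg_ids, chrom = chrom,
                       pos = sample.int(2e8, n_cpg, replace = TRUE),
                       sex = chrom == "chrX")
  if (!is.null(truth)) coords <- truth$coords

  sheet <- data.frame(sample_id = sample_id, cohort = cohort, group = group,
                      age = age, genotype = NA_character_,
                      treatment = "none", stringsAsFactors = FALSE)
  truth_out <- list(signature = signature, age = age_tab,
                    proportions = props, noise_sd = noise_sd, seed = seed,
                    cell_reference = cell_reference, coords = coords)
  list(beta = beta_matrix(vals, coords), sheet = sheet, truth = truth_out)
}

#' Simulate a 2x2 genotype-by-drug methylation array experiment
#'
#' Four groups (WT/KO crossed with vehicle/drug). `n_geno_dmps` CpGs get a
#' genotype shift of `delta` in KO samples; a `frac_corrected` subset has
#' the KO-drug group returned to the WT baseline (drug-corrected sites)
#' while the rest persist under drug. Noise is logit-normal as in
#' [simulate_cohort()].
#'
#' @param n_per_group samples per design cell (>= 2).
#' @param n_cpg total CpGs.
#' @param n_geno_dmps planted genotype DMPs.
#' @param frac_corrected fraction of planted DMPs normalised by drug.
#' @param delta genotype shift in beta units.
#' @param noise_sd logit-scale noise sd.
#' @param seed integer seed.
#' @return list with `beta`, `sheet` (columns sample_id, genotype,
#'   treatment) and `truth` (`geno_dmps` data.frame(cpg, delta,
#'   corrected)).
#' @export
simulate_mouse_array <- function(n_per_group = 4, n_cpg = 20000,
                                 n_geno_dmps = 160, frac_corrected = 0.5,
                                 delta = 0.08, noise_sd = 0.05, seed = 1) {
  stopifnot(n_per_group >= 2, frac_corrected >= 0, frac_corrected <= 1,
            n_geno_dmps <= n_cpg)
  set.seed(seed)
  cpg_ids <- sprintf("mm%07d", seq_len(n_cpg))
  base <- ifelse(stats::runif(n_cpg) < 0.5,
                 stats::rbeta(n_cpg, 2, 8), stats::rbeta(n_cpg, 8, 2))
  base <- pmin(pmax(base, 0.1), 0.9)
  genotype <- rep(c("WT", "WT", "KO", "KO"), each = n_per_group)
  treatment <- rep(c("vehicle", "drug"), each = n_per_group, times = 2)
  sample_id <- paste0(genotype, "_", treatment, "_",
                      rep(seq_len(n_per_group), 4))
  dmp_idx <- sample.int(n_cpg, n_geno_dmps)
  sgn <- sample(c(-1, 1), n_geno_dmps, replace = TRUE)
  sgn[base[dmp_idx] + sgn * delta > 0.95] <- -1
  sgn[base[dmp_idx] + sgn * delta < 0.05] <- 1
  d <- sgn * delta
  n_corr <- round(frac_corrected * n_geno_dmps)
  corrected <- rep(FALSE, n_geno_dmps)
  if (n_corr > 0) corrected[sample.int(n_geno_dmps, n_corr)] <- TRUE

  expected <- matrix(rep(base, length(sample_id)), ncol = length(sample_id),
                     dimnames = list(cpg_ids, sample_id))
  is_ko <- genotype == "KO"
  is_ko_drug <- is_ko & treatment == "drug"
  expected[dmp_idx, is_ko] <- expected[dmp_idx, is_ko] + d
  # corrected sites: KO-drug returns to WT baseline
  expected[dmp_idx[corrected], is_ko_drug] <-
    expected[dmp_idx[corrected], is_ko_drug] - d[corrected]
  vals <- matrix(add_logit_noise(clamp_beta(expected), noise_sd),
                 nrow = n_cpg, dimnames = dimnames(expected))
  sheet <- data.frame(sample_id = sample_id, genotype = genotype,
                      treatment = treatment, stringsAsFactors = FALSE)
  truth <- list(geno_dmps = data.frame(cpg = cpg_ids[dmp_idx], delta = d,
                                       corrected = corrected),
                noise_sd = noise_sd, seed = seed)
  list(beta = beta_matrix(vals,
                          data.frame(cpg = cpg_ids, chrom = "chr1",
                                     pos = seq_len(n_cpg) * 1000L,
                                     sex = FALSE)),
       sheet = sheet, truth = truth)
}

#' Simulate RRBS-style methylation counts with overdispersion
#'
#' Coverage per CpG/sample is `1 + NegBin(mu = mean_coverage - 1, size =
#' coverage_size)` (mean exactly `mean_coverage`, support >= 1).
#' Methylated counts are beta-binomial: a per-observation success
#' probability is drawn from a Beta with the CpG/group mean and intraclass
#' correlation `rho = (phi - 1)/(mean_coverage - 1)`, so the dispersion
#' factor at the mean coverage equals `phi`; `phi = 1` gives exact
#' binomial counts. `n_dmps` CpGs have the second-group proportion shifted
#' by `delta`.
#'
#' @param n_per_group samples per group (two groups).
#' @param n_cpg number of CpGs.
#' @param mean_coverage mean read coverage (>= 1).
#' @param phi overdispersion factor (>= 1).
#' @param n_dmps planted differentially methylated CpGs.
#' @param delta planted proportion difference.
#' @param coverage_size negative-binomial size of the coverage draw.
#' @param seed integer seed.
#' @return list with `counts` (class `meth_counts`: `meth` and `cov`
#'   integer matrices CpG x sample, `coords`), `groups` factor, and
#'   `truth` (`dmps` data.frame(cpg, delta), `phi`, `seed`).
#' @export
simulate_rrbs <- function(n_per_group = 3, n_cpg = 2000, mean_coverage = 30,
                          phi = 3, n_dmps = 100, delta = 0.15,
                          coverage_size = 5, seed = 1) {
  stopifnot(mean_coverage >= 1, phi >= 1, n_dmps <= n_cpg)
  set.seed(seed)
  cpg_ids <- sprintf("rr%07d", seq_len(n_cpg))
  n <- 2 * n_per_group
  groups <- factor(rep(c("WT", "KO"), each = n_per_group),
                   levels = c("WT", "KO"))
  sample_id <- paste0(groups, "_", rep(seq_len(n_per_group), 2))
  base_p <- pmin(pmax(stats::rbeta(n_cpg, 0.8, 0.8), 0.05), 0.95)
  dmp_idx <- sample.int(n_cpg, n_dmps)
  base_p[dmp_idx] <- pmin(pmax(base_p[dmp_idx], 0.1), 0.9 - delta)
  sgn <- rep(1, n_dmps)
  d <- sgn * delta
  p_mat <- matrix(rep(base_p, n), ncol = n,
                  dimnames = list(cpg_ids, sample_id))
  p_mat[dmp_idx, groups == "KO"] <- p_mat[dmp_idx, groups == "KO"] + d

  cov <- matrix(1L + stats::rnbinom(n_cpg * n, mu = mean_coverage - 1,
                                    size = coverage_size),
                nrow = n_cpg, dimnames = list(cpg_ids, sample_id))
  rho <- if (mean_coverage > 1) (phi - 1) / (mean_coverage - 1) else 0
  if (rho > 0) {
    s <- (1 - rho) / rho
    pp <- matrix(stats::rbeta(n_cpg * n, p_mat * s, (1 - p_mat) * s),
                 nrow = n_cpg)
  } else pp <- p_mat
  meth <- matrix(stats::rbinom(n_cpg * n, as.vector(cov), as.vector(pp)),
                 nrow = n_cpg, dimnames = dimnames(cov))
  counts <- structure(list(meth = meth, cov = cov,
                           coords = data.frame(cpg = cpg_ids, chrom = "chr1",
                                               pos = seq_len(n_cpg) * 500L,
                                               strand = "+")),
                      class = "meth_counts")
  list(counts = counts, groups = groups,
       truth = list(dmps = data.frame(cpg = cpg_ids[dmp_idx], delta = d),
                    base_p = stats::setNames(base_p, cpg_ids),
                    phi = phi, seed = seed))
}

#' @export
print.meth_counts <- function(x, ...) {
  cat(sprintf("meth_counts: %d CpGs x %d samples, mean coverage %.1f\n",
              nrow(x$meth), ncol(x$meth), mean(x$cov)))
  invisible(x)
}

#' Simulate an ordinal phenotype screen
#'
#' Draws per-larva scores on the 4-point ordinal severity scale
#' {0 = WT-like, 1 = mild, 2 = moderate, 3 = severe} from per-chemical
#' categorical distributions. Chemical effects are proportional-odds
#' shifts of the baseline distribution: negative `effect_shifts` move mass
#' toward 0 (suppressors), positive toward 3 (enhancers), 0 reproduces the
#' baseline exactly.
#'
#' @param chemicals character vector of condition names.
#' @param effect_shifts numeric, recycled to `length(chemicals)`;
#'   log-odds shift per chemical.
#' @param n_larvae larvae per chemical.
#' @param base_prob baseline probabilities over scores 0..3 (must sum
#'   to 1); default severity-skewed as in an untreated mutant clutch.
#' @param seed integer seed.
#' @return long-format data.frame (larva, chemical, score).
#' @export
simulate_ordinal_screen <- function(chemicals, effect_shifts = 0,
                                    n_larvae = 100,
                                    base_prob = c(0.1, 0.15, 0.25, 0.5),
                                    seed = 1) {
  if (abs(sum(base_prob) - 1) > 1e-8)
    stop("base_prob must sum to 1")
  stopifnot(length(base_prob) == 4, all(base_prob >= 0))
  set.seed(seed)
  shifts <- rep_len(effect_shifts, length(chemicals))
  out <- vector("list", length(chemicals))
  for (i in seq_along(chemicals)) {
    cum <- cumsum(base_prob)[1:3]
    cum <- pmin(pmax(cum, 1e-9), 1 - 1e-9)
    cum_shift <- stats::plogis(stats::qlogis(cum) - shifts[i])
    p <- diff(c(0, sort(cum_shift), 1))
    score <- sample(0:3, n_larvae, replace = TRUE, prob = p)
    out[[i]] <- data.frame(larva = paste0(chemicals[i], "_", seq_len(n_larvae)),
                           chemical = chemicals[i], score = score,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate two gene lists with an exact overlap
#'
#' Draws two gene-id sets of the requested sizes sharing exactly
#' `n_shared` ids, from a universe of `n_universe` genes; a fixture
#' generator for Venn partitioning of differential-expression lists.
#'
#' @param n_universe universe size.
#' @param size_a,size_b list sizes.
#' @param n_shared shared genes, `<= min(size_a, size_b)`.
#' @param seed integer seed.
#' @return list with character vectors `a` and `b`.
#' @export
simulate_deg_lists <- function(n_universe, size_a, size_b, n_shared,
                               seed = 1) {
  if (n_shared > min(size_a, size_b))
    stop("n_shared exceeds a list size")
  if (size_a + size_b - n_shared > n_universe)
    stop("universe too small for requested sizes")
  set.seed(seed)
  genes <- sprintf("gene%06d", seq_len(n_universe))
  picked <- sample(genes, size_a + size_b - n_shared)
  shared <- picked[seq_len(n_shared)]
  only_a <- picked[n_shared + seq_len(size_a - n_shared)]
  only_b <- picked[size_a + seq_len(size_b - n_shared)]
  list(a = sample(c(shared, only_a)), b = sample(c(shared, only_b)))
}

#' Write RRBS-style counts as TSV
#'
#' Paired columns `<sample>_meth`, `<sample>_cov` after the coordinate
#' columns.
#'
#' @param x a `meth_counts` object.
#' @param path file path.
#' @export
write_meth_counts <- function(x, path) {
  stopifnot(inherits(x, "meth_counts"))
  samples <- colnames(x$meth)
  df <- x$coords
  for (s in samples) {
    df[[paste0(s, "_meth")]] <- x$meth[, s]
    df[[paste0(s, "_cov")]] <- x$cov[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_counts
#' @export
read_meth_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meth_cols <- grep("_meth$", names(df), value = TRUE)
  samples <- sub("_meth$", "", meth_cols)
  meth <- as.matrix(df[paste0(samples, "_meth")])
  cov <- as.matrix(df[paste0(samples, "_cov")])
  colnames(meth) <- colnames(cov) <- samples
  rownames(meth) <- rownames(cov) <- df$cpg
  if (any(meth > cov | meth < 0)) stop("methylated counts exceed coverage")
  structure(list(meth = meth, cov = cov,
                 coords = df[intersect(c("cpg", "chrom", "pos", "strand"),
                                       names(df))]),
            class = "meth_counts")
}
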