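test_that("two-group OLS coefficient equals the difference of group means", {
  set.seed(1)
  v <- matrix(runif(60, 0.2, 0.8), 10,
              dimnames = list(paste0("cg", 1:10), paste0("s", 1:6)))
  grp <- factor(rep(c("control", "case"), each = 3),
                levels = c("control", "case"))
  X <- cbind(1, case = as.numeric(grp == "case"))
  fit <- fit_cpg_models(v, X, scale = "beta", groups = grp)
  diff <- rowMeans(v[, 4:6]) - rowMeans(v[, 1:3])
  expect_equal(unname(fit$coefficients[, "case"]), unname(diff),
               tolerance = 1e-12)
  expect_equal(unname(fit$effect), unname(diff), tolerance = 1e-12)
  expect_equal(fit$df_residual[1], 4)
})

test_that("per-CpG OLS matches the closed-form solution with a covariate", {
  # 4-sample toy with an added indicator covariate, checked against the
  # normal equations solved independently
  v <- matrix(c(0.30, 0.42, 0.55, 0.61,
                0.20, 0.25, 0.70, 0.72), 2, byrow = TRUE,
              dimnames = list(c("cgA", "cgB"), paste0("s", 1:4)))
  X <- cbind(1, grp = c(0, 0, 1, 1), cov = c(0, 1, 0, 1))
  fit <- fit_cpg_models(v, X, scale = "beta")
  for (g in 1:2) {
    b_hat <- solve(t(X) %*% X, t(X) %*% v[g, ])
    expect_equal(unname(fit$coefficients[g, ]), as.vector(b_hat),
                 tolerance = 1e-12)
    res <- v[g, ] - as.vector(X %*% b_hat)
    expect_equal(unname(fit$sigma[g]), sqrt(sum(res^2) / 1),
                 tolerance = 1e-12)
  }
  expect_equal(unname(fit$stdev_unscaled),
               unname(sqrt(diag(solve(t(X) %*% X)))), tolerance = 1e-12)
})

test_that("zero-variance CpGs are flagged and excluded from the prior fit", {
  set.seed(2)
  v <- matrix(runif(120, 0.3, 0.7), 20)
  v[1, ] <- 0.5
  dimnames(v) <- list(paste0("cg", 1:20), paste0("s", 1:6))
  X <- cbind(1, grp = rep(0:1, each = 3))
  fit <- fit_cpg_models(v, X, scale = "beta")
  expect_true(fit$zero_variance[1])
  expect_equal(unname(fit$sigma[1]), 0)
  tab <- ebayes_moderate(fit, 2)
  expect_true(all(is.finite(tab$t)))
})

test_that("equal variances collapse the prior: moderated t equals ordinary t", {
  set.seed(3)
  n <- 8
  X <- cbind(1, grp = rep(0:1, each = n / 2))
  # construct rows with exactly equal residual variance by scaling
  v <- matrix(rnorm(30 * n), 30)
  res <- v - v %*% X %*% solve(crossprod(X)) %*% t(X)
  v <- v / sqrt(rowSums(res^2) / (n - 2))   # unit residual variance rows
  dimnames(v) <- list(paste0("g", 1:30), paste0("s", 1:n))
  fit <- fit_cpg_models(v, X, scale = "beta")
  expect_lt(diff(range(fit$sigma)), 1e-10)
  tab <- ebayes_moderate(fit, 2)
  t_ord <- fit$coefficients[, 2] / (fit$sigma * fit$stdev_unscaled[2])
  expect_equal(unname(tab$t[match(names(t_ord), tab$cpg)]), unname(t_ord),
               tolerance = 1e-8)
  expect_true(is.infinite(attr(tab, "df_prior")))
  # the d0 = Inf limit pools every posterior variance at s0^2
  expect_lt(diff(range(tab$s2_post)), 1e-12)
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(4)
  G <- 300; n <- 12
  X <- cbind(1, grp = rep(0:1, each = n / 2), cov = rnorm(n))
  sigma2 <- 1 / rgamma(G, shape = 3, rate = 3)    # heterogeneous variances
  v <- matrix(rnorm(G * n, sd = sqrt(rep(sigma2, n))), G)
  dimnames(v) <- list(paste0("g", 1:G), paste0("s", 1:n))
  fit <- fit_cpg_models(v, X, scale = "beta")
  tab <- ebayes_moderate(fit, "grp")
  lf <- limma::eBayes(limma::lmFit(v, X))
  ord <- match(tab$cpg, rownames(v))
  expect_equal(attr(tab, "df_prior"), lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "s2_prior"), lf$s2.prior, tolerance = 1e-6)
  expect_equal(tab$s2_post, unname(lf$s2.post[ord]), tolerance = 1e-6)
  expect_equal(tab$t, unname(lf$t[ord, "grp"]), tolerance = 1e-6)
  expect_equal(tab$p, unname(lf$p.value[ord, "grp"]), tolerance = 1e-6)
})

test_that("prior hyperparameters are recovered from model-simulated variances", {
  set.seed(5)
  G <- 5000; d0 <- 4; s0 <- 1; d_g <- 10
  sigma2 <- s0^2 * d0 / rchisq(G, df = d0)        # scaled inverse chi-square
  s2 <- sigma2 * rchisq(G, df = d_g) / d_g
  est <- episig:::fit_f_dist(s2, rep(d_g, G))
  expect_lt(abs(est$df_prior - d0) / d0, 0.25)
  expect_lt(abs(sqrt(est$s2_prior) - s0) / s0, 0.05)
})

test_that("BH correction reproduces the step-up enumeration and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.04, 0.001, 0.9, 0.02)
  q <- bh_fdr(p)
  expect_equal(order(q), order(p))          # order-preserving
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("age screening removes planted age CpGs and spares nulls", {
  set.seed(6)
  n <- 40; g <- 2000; n_age <- 200
  ages <- runif(n, 0, 60)
  base <- matrix(0.5, g, n)
  base[1:n_age, ] <- 0.4 + outer(rep(0.004, n_age), ages - 30)
  v <- pmin(pmax(base + matrix(rnorm(g * n, 0, 0.02), g), 0.001), 0.999)
  dimnames(v) <- list(paste0("cg", 1:g), paste0("s", 1:n))
  removed <- age_cpg_screen(v, ages, fdr_threshold = 0.05, scale = "beta")
  expect_gte(mean(paste0("cg", 1:n_age) %in% removed), 0.95)
  # false removals controlled by BH
  expect_lt(mean(paste0("cg", (n_age + 1):g) %in% removed), 0.02)
  expect_error(age_cpg_screen(v, rep(5, n)), "constant")
})

test_that("under a global null the age screen removes almost nothing", {
  set.seed(7)
  n <- 30; g <- 10000
  v <- matrix(runif(g * n, 0.3, 0.7), g,
              dimnames = list(paste0("cg", 1:g), paste0("s", 1:n)))
  removed <- age_cpg_screen(v, runif(n, 0, 60))
  expect_lt(length(removed) / g, 0.002)
})

test_that("signature selection applies both thresholds strictly", {
  tab <- data.frame(cpg = c("a", "b", "c", "d"),
                    effect = c(0.06, 0.04, 0.06, -0.07),
                    p = c(0.004, 0.004, 0.006, 0.001),
                    q = c(0.02, 0.02, 0.03, 0.01),
                    direction = c("hyper", "hyper", "hyper", "hypo"))
  sel <- select_dmps(tab, p_threshold = 0.005, delta_threshold = 0.05)
  expect_setequal(sel$cpg, c("a", "d"))     # b fails effect, c fails p
  expect_equal(sel$direction[sel$cpg == "a"], "hyper")
  expect_equal(sel$direction[sel$cpg == "d"], "hypo")
  expect_error(select_dmps(tab[0, ]), "empty")
})

test_that("selection is invariant to CpG order and flips sign with labels", {
  set.seed(8)
  v <- matrix(runif(600, 0.2, 0.8), 100,
              dimnames = list(sprintf("cg%03d", 1:100), paste0("s", 1:6)))
  grp <- factor(rep(c("control", "case"), each = 3),
                levels = c("control", "case"))
  X <- cbind(1, case = as.numeric(grp == "case"))
  tab <- ebayes_moderate(fit_cpg_models(v, X, groups = grp), 2)
  sel <- select_dmps(tab, 0.5, 0.01)
  # permuted CpG order
  perm <- sample(nrow(v))
  tab_p <- ebayes_moderate(fit_cpg_models(v[perm, ], X, groups = grp), 2)
  sel_p <- select_dmps(tab_p, 0.5, 0.01)
  expect_setequal(sel$cpg, sel_p$cpg)
  # swapped group labels: same CpGs, opposite directions
  grp2 <- factor(rep(c("case", "control"), each = 3),
                 levels = c("control", "case"))
  X2 <- cbind(1, case = as.numeric(grp2 == "case"))
  tab_s <- ebayes_moderate(fit_cpg_models(v, X2, groups = grp2), 2)
  sel_s <- select_dmps(tab_s, 0.5, 0.01)
  expect_setequal(sel$cpg, sel_s$cpg)
  m <- match(sel$cpg, sel_s$cpg)
  expect_equal(sel$effect, -sel_s$effect[m], tolerance = 1e-12)
})

test_that("design construction validates rank and content", {
  sheet <- data.frame(sample_id = paste0("s", 1:6),
                      group = rep(c("control", "case"), 3),
                      age = c(1, 2, 3, 4, 5, 6), dup = c(1, 2, 3, 4, 5, 6))
  X <- build_design(sheet, covariates = "age")
  expect_equal(colnames(X), c("(Intercept)", "groupcontrol", "age"))
  expect_error(build_design(sheet, covariates = c("age", "dup")),
               "rank deficient")
  expect_error(build_design(sheet, main = "missing_col"))
})
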