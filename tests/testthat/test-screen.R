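test_that("identical score multisets give H = 0 and p = 1", {
  df <- data.frame(score = c(0, 1, 3, 0, 1, 3),
                   condition = rep(c("a", "b"), each = 3))
  r <- kruskal_wallis_dunn(df$score, df$condition)
  expect_equal(r$H, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  # all-identical pooled data: degenerate contract
  r0 <- kruskal_wallis_dunn(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(r0$H, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$p_method, "degenerate")
})

test_that("small-sample exact p agrees with full enumeration (with ties)", {
  x <- c(0, 0, 1); y <- c(2, 3, 3)
  r <- kruskal_wallis_dunn(c(x, y), rep(c("a", "b"), each = 3))
  expect_equal(r$p_method, "exact")
  # H must match the tie-corrected statistic from the base implementation
  expect_equal(r$H,
               unname(kruskal.test(c(x, y),
                                   factor(rep(1:2, each = 3)))$statistic),
               tolerance = 1e-10)
  expect_equal(r$p, oracle_kw2_p(x, y))
  # a second configuration, unequal sizes
  x2 <- c(1, 1, 2, 3); y2 <- c(0, 2, 2)
  r2 <- kruskal_wallis_dunn(c(x2, y2), rep(c("a", "b"), c(4, 3)))
  expect_equal(r2$p, oracle_kw2_p(x2, y2))
})

test_that("Dunn post test ranks conditions and adjusts p-values", {
  set.seed(1)
  sc <- simulate_ordinal_screen(c("DMSO", "supp", "enh"),
                                effect_shifts = c(0, -2.5, 2), n_larvae = 60,
                                seed = 2)
  r <- kruskal_wallis_dunn(sc$score, sc$chemical)
  expect_lt(r$p, 1e-6)
  pw <- r$pairwise
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p))
  expect_true(all(pw$p_adj <= 1))
  i <- which(pw$group1 == "DMSO" & pw$group2 == "supp")
  expect_gt(pw$z[i], 0)                # suppressor has lower mean rank
  expect_lt(pw$p_adj[i], 0.01)
  expect_lt(r$mean_ranks[["supp"]], r$mean_ranks[["DMSO"]])
  expect_error(kruskal_wallis_dunn(1:4, rep("a", 4)), "two conditions")
})

test_that("fingerprint normalisation anchors the vehicle at 1", {
  set.seed(3)
  scores <- expand.grid(suppressor = c("DMSO", "s1", "s2"),
                        enhancer = c("e1", "e2"), rep = 1:20)
  scores$score <- sample(0:3, nrow(scores), replace = TRUE)
  # s1 rescues completely under every enhancer
  scores$score[scores$suppressor == "s1"] <- 0
  fp <- build_fingerprint(scores, vehicle = "DMSO", transform = "none")
  expect_equal(unname(fp$ratio["DMSO", ]), c(1, 1))
  expect_true(all(fp$ratio["s1", ] < fp$ratio["DMSO", ]))
  # a missing combination becomes an explicit NA entry
  sc2 <- scores[!(scores$suppressor == "s2" & scores$enhancer == "e2"), ]
  fp2 <- build_fingerprint(sc2, vehicle = "DMSO")
  expect_true(is.na(fp2$ratio["s2", "e2"]))
  expect_error(build_fingerprint(scores, vehicle = "nope"), "not present")
})

test_that("fingerprint is invariant to row order within conditions", {
  set.seed(4)
  scores <- expand.grid(suppressor = c("DMSO", "s1"), enhancer = c("e1", "e2"),
                        rep = 1:15)
  scores$score <- sample(0:3, nrow(scores), replace = TRUE)
  fp1 <- build_fingerprint(scores)
  fp2 <- build_fingerprint(scores[sample(nrow(scores)), ])
  expect_equal(fp1$ratio, fp2$ratio)
})

test_that("suppressors sharing a rescue pattern are closer than unrelated pairs", {
  near <- 0
  for (i in 1:100) {
    sc <- rbind(
      simulate_screen_block("DMSO", 0, i),
      simulate_screen_block("hdaci_1", -2, i + 300),
      simulate_screen_block("hdaci_2", -2, i + 600),
      simulate_screen_block("inert", 0, i + 900))
    fp <- build_fingerprint(sc, vehicle = "DMSO")
    d <- as.matrix(dist(fp$transformed))
    if (d["hdaci_1", "hdaci_2"] < d["hdaci_1", "inert"]) near <- near + 1
  }
  expect_gte(near, 95)
})

test_that("fingerprint clustering groups rescue patterns and tolerates constants", {
  # HDACi-like compounds share a graded rescue pattern across six
  # enhancers; the control compounds share a mild opposite pattern, so
  # centered-correlation clustering sees two coherent row groups
  ee <- paste0("e", 1:6)
  # two suppressor families with opposite enhancer specificity: HDACi-like
  # rescue e1/e2 strongly, the other family rescues e5/e6
  hdaci_pat <- c(-3, -3, -1, -1, 0, 0)
  other_pat <- c(0, 0, -1, -1, -3, -3)
  sc <- rbind(
    simulate_screen_block("DMSO", 0, 1, enhancers = ee, n_larvae = 60),
    simulate_screen_block("hdaci_1", hdaci_pat, 2, enhancers = ee, n_larvae = 60),
    simulate_screen_block("hdaci_2", hdaci_pat, 3, enhancers = ee, n_larvae = 60),
    simulate_screen_block("other_1", other_pat, 4, enhancers = ee, n_larvae = 60),
    simulate_screen_block("other_2", other_pat, 5, enhancers = ee, n_larvae = 60))
  fp <- build_fingerprint(sc, vehicle = "DMSO")
  cl <- cluster_fingerprint(fp, k = 2)
  expect_equal(cl$clusters[["hdaci_1"]], cl$clusters[["hdaci_2"]])
  expect_equal(cl$clusters[["other_1"]], cl$clusters[["other_2"]])
  expect_false(cl$clusters[["hdaci_1"]] == cl$clusters[["other_1"]])
  # duplicated row sits at distance zero from its twin
  m <- fp$transformed
  m <- rbind(m, dup = m["hdaci_1", ])
  cl2 <- cluster_fingerprint(m, k = 2)
  expect_equal(cl2$clusters[["dup"]], cl2$clusters[["hdaci_1"]])
  # constant rows fall back to Euclidean distance without error
  m2 <- rbind(m, flat = rep(0, ncol(m)))
  expect_no_error(cluster_fingerprint(m2))
  # row permutation leaves the tree topology unchanged
  cl3 <- cluster_fingerprint(m[sample(nrow(m)), ], k = 2)
  expect_equal(cl3$clusters[sort(names(cl3$clusters))],
               cl2$clusters[sort(names(cl2$clusters))])
})

test_that("interaction contrast reproduces its defining arithmetic", {
  # means WT_veh 10, mut_veh 4, WT_trt 10, mut_trt 8 -> contrast +4
  value <- c(9, 11, 3, 5, 9.5, 10.5, 7, 9)
  genotype <- factor(rep(c("WT", "mut", "WT", "mut"), each = 2),
                     levels = c("WT", "mut"))
  treatment <- factor(rep(c("vehicle", "treated"), each = 4),
                      levels = c("vehicle", "treated"))
  r <- interaction_contrast(value, genotype, treatment, n_boot = 200,
                            seed = 1)
  expect_equal(r$contrast, 4, tolerance = 1e-12)
  expect_false(r$unstable)
  # an equal shift in both genotypes cancels
  v2 <- c(1, 3, 2, 4, 6, 8, 7, 9)
  r2 <- interaction_contrast(v2, genotype, treatment, n_boot = 200, seed = 1)
  expect_equal(r2$contrast, 0, tolerance = 1e-12)
  # single-observation cell flags instability
  r3 <- interaction_contrast(c(1, 2, 3, 4, 5, 6, 7),
                             factor(c("WT", "WT", "mut", "mut", "WT", "mut", "WT"),
                                    levels = c("WT", "mut")),
                             factor(c("v", "v", "v", "v", "t", "t", "t"),
                                    levels = c("v", "t")),
                             n_boot = 100, seed = 2)
  expect_true(r3$unstable)
})

test_that("bootstrap intervals cover the null contrast at the nominal rate", {
  set.seed(5)
  cover <- 0
  n_sim <- 200
  for (i in 1:n_sim) {
    value <- rnorm(24, mean = 10)
    genotype <- factor(rep(c("WT", "mut"), each = 12), levels = c("WT", "mut"))
    treatment <- factor(rep(rep(c("vehicle", "treated"), each = 6), 2),
                        levels = c("vehicle", "treated"))
    r <- interaction_contrast(value, genotype, treatment, n_boot = 400)
    if (r$ci[1] <= 0 && 0 <= r$ci[2]) cover <- cover + 1
  }
  expect_gte(cover / n_sim, 0.88)
  expect_lte(cover / n_sim, 0.99)
})

test_that("percent input follows the dilution-adjusted formula", {
  expect_equal(percent_input(25, 25, input_fraction = 1), 100)
  expect_equal(percent_input(28, 25, input_fraction = 0.1), 1.25,
               tolerance = 0.01)
  # one extra IP cycle halves the recovered percentage
  expect_equal(percent_input(29, 25, 0.1) / percent_input(28, 25, 0.1), 0.5,
               tolerance = 1e-12)
  expect_error(percent_input(25, 25, 0), "input_fraction")
  expect_error(percent_input(Inf, 25, 0.1), "finite")
})

test_that("methylation potential is the elementwise SAM:SAH ratio", {
  expect_equal(methylation_potential(5, 5), 1)
  expect_equal(methylation_potential(10, 2), 5)
  expect_equal(methylation_potential(c(10, 6), c(2, 3)), c(5, 2))
  expect_error(methylation_potential(1, 0), "positive")
})
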