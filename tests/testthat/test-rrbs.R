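test_that("the pooled 2x2 worked example gives the closed-form chi-square", {
  # [80 meth / 100 cov] vs [50/100]: n(ad-bc)^2/(row x col products) = 19.78
  counts <- make_counts(matrix(c(50, 80), 1), matrix(c(100, 100), 1))
  res <- test_cpg_counts(counts, factor(c("WT", "KO"), levels = c("WT", "KO")))
  expect_equal(res$meth_diff, 0.30, tolerance = 1e-12)
  expect_equal(res$stat, 19.78, tolerance = 0.01)
  expect_equal(res$phi_eff, 1)            # single sample per group: phi = 1
  # independent oracle: stats::prop.test without continuity correction
  oracle <- prop.test(c(80, 50), c(100, 100), correct = FALSE)
  expect_equal(res$stat, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
})

test_that("identical groups give zero difference and p near 1", {
  counts <- make_counts(matrix(c(40, 40, 40, 40), 1),
                        matrix(c(100, 100, 100, 100), 1))
  res <- test_cpg_counts(counts, factor(rep(c("a", "b"), each = 2)))
  expect_equal(res$meth_diff, 0)
  expect_gt(res$p, 0.99)
})

test_that("correction leaves the statistic untouched wherever phi <= 1", {
  r <- simulate_rrbs(n_per_group = 3, n_cpg = 800, phi = 1, n_dmps = 0,
                     seed = 1)
  corr <- test_cpg_counts(r$counts, r$groups)
  naive <- test_cpg_counts(r$counts, r$groups, correct = FALSE)
  at_floor <- corr$phi_eff <= 1
  expect_gt(mean(at_floor), 0.2)
  expect_equal(corr$stat[at_floor], naive$stat[at_floor], tolerance = 1e-12)
  # corrected never exceeds the naive statistic
  expect_true(all(corr$stat <= naive$stat + 1e-12))
  # at phi = 1 the two tests are near-identical overall
  expect_gt(cor(corr$stat, naive$stat), 0.999)
})

test_that("min-coverage filtering skips CpGs and reports them", {
  meth <- matrix(c(5, 10, 3, 8), 2, byrow = TRUE)
  cov <- matrix(c(20, 30, 5, 25), 2, byrow = TRUE)  # second CpG has 5x
  counts <- make_counts(meth, cov)
  res <- test_cpg_counts(counts, factor(c("a", "b")), min_coverage = 10)
  expect_equal(nrow(res), 1)
  expect_equal(attr(res, "skipped"), "rr002")
})

test_that("RRBS DMP calling applies q and difference thresholds", {
  tab <- data.frame(cpg = c("called", "small_diff", "high_q"),
                    meth_diff = c(0.12, 0.08, 0.20),
                    p = c(0.001, 0.001, 0.01),
                    q = c(0.01, 0.01, 0.06))
  out <- call_rrbs_dmps(tab, q_threshold = 0.05, diff_threshold = 0.10)
  expect_identical(out$cpg, "called")
  expect_identical(out$direction, "hyper")
})

test_that("overdispersion-corrected test is calibrated where the naive test is not", {
  r <- simulate_rrbs(n_per_group = 3, n_cpg = 2500, mean_coverage = 30,
                     phi = 3, n_dmps = 0, seed = 2)
  corr <- test_cpg_counts(r$counts, r$groups)
  naive <- test_cpg_counts(r$counts, r$groups, correct = FALSE)
  expect_gte(nrow(corr), 2000)
  t1_corr <- mean(corr$p < 0.05)
  t1_naive <- mean(naive$p < 0.05)
  expect_gte(t1_corr, 0.03)
  expect_lte(t1_corr, 0.07)
  expect_gt(t1_naive, 0.10)
})

toy_annotation <- function() {
  gene_annotation(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10000, 10000, 10400, 15000, 19500, 50000),
    end = c(20000, 10399, 10800, 16000, 20000, 60000),
    gene = c("GeneA", "GeneA", "GeneA", "GeneA", "GeneA", "GeneB"),
    strand = c("+", "+", "+", "+", "+", "-"),
    feature = c("transcript", "5UTR", "exon", "exon", "3UTR", "transcript")))
}

test_that("CpG annotation follows the precedence and the promoter window", {
  ann <- toy_annotation()
  pos <- data.frame(
    cpg = paste0("c", 1:8),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr1", "chr2"),
    pos = c(9000,      # 1 kb upstream of + TSS -> Promoter
            15500,     # exon 5.5 kb from TSS -> Exon (outside promoter)
            14000,     # gene body, no exon -> Intron
            21000,     # 1 kb past + gene end -> Downstream
            500000,    # far away -> Distal Intergenic
            61000,     # 1 kb past - strand TSS at end=60000 -> Promoter
            19600,     # inside 3UTR (outside promoter window) -> 3UTR
            48000))    # 2 kb downstream of - strand gene (start side)
  got <- annotate_cpgs(pos, ann)
  expect_equal(got$feature,
               c("Promoter", "Exon", "Intron", "Downstream",
                 "Distal Intergenic", "Promoter", "3UTR", "Downstream"))
  expect_equal(got$gene[1], "GeneA")
  expect_true(is.na(got$gene[5]))
  # 5UTR outranks Exon where both overlap; Promoter outranks both
  pos2 <- data.frame(cpg = "u1", chrom = "chr1", pos = 10200)
  expect_equal(annotate_cpgs(pos2, ann)$feature, "Promoter")
  pos3 <- data.frame(cpg = "u2", chrom = "chr1", pos = 10200)
  got3 <- annotate_cpgs(pos3, ann, tss_window = 100)
  expect_equal(got3$feature, "5UTR")
  # unknown chromosome warns and falls back to intergenic
  expect_warning(got4 <- annotate_cpgs(
    data.frame(cpg = "zz", chrom = "chr9", pos = 100), ann), "absent")
  expect_equal(got4$feature, "Distal Intergenic")
})

test_that("annotation is invariant to gene order and single-label per CpG", {
  df <- data.frame(
    chrom = "chr1",
    start = c(1000, 30000, 1000, 30500),
    end = c(5000, 40000, 1500, 31000),
    gene = c("G1", "G2", "G1", "G2"),
    strand = c("+", "+", "+", "+"),
    feature = c("transcript", "transcript", "exon", "exon"))
  set.seed(3)
  pos <- data.frame(cpg = paste0("c", 1:50), chrom = "chr1",
                    pos = sample.int(50000, 50))
  a1 <- annotate_cpgs(pos, gene_annotation(df))
  a2 <- annotate_cpgs(pos, gene_annotation(df[sample(nrow(df)), ]))
  expect_equal(a1$feature, a2$feature)
  expect_equal(nrow(a1), 50)              # exactly one label each
})

test_that("DM-gene / DEG overlap does set arithmetic and handles edge cases", {
  annotated <- data.frame(cpg = c("c1", "c2", "c3"),
                          chrom = "chr1", pos = 1:3,
                          feature = c("Promoter", "Exon", "Promoter"),
                          gene = c("A", "A", "B"))
  ov <- overlap_dm_degs(annotated, c("B", "C"))
  expect_setequal(ov$genes, c("A", "B"))
  expect_identical(ov$overlap, "B")
  expect_equal(ov$n_overlap, 1)
  expect_equal(ov$n_mapped, 3)
  # no proximal DMPs: empty overlap
  far <- data.frame(cpg = "c9", chrom = "chr1", pos = 9,
                    feature = "Distal Intergenic", gene = NA)
  ov2 <- overlap_dm_degs(far, c("A"))
  expect_equal(ov2$n_overlap, 0)
  expect_error(overlap_dm_degs(annotated[0, ], "A"), "empty")
})

test_that("promoter DMPs at DE genes are fully recovered in the noiseless case", {
  ann <- toy_annotation()
  # DMPs planted in GeneA's promoter; GeneA is a DEG
  dmp_pos <- data.frame(cpg = c("d1", "d2"), chrom = "chr1",
                        pos = c(9500, 11000))
  annotated <- annotate_cpgs(dmp_pos, ann)
  ov <- overlap_dm_degs(annotated, c("GeneA", "GeneX"))
  expect_identical(ov$overlap, "GeneA")
  expect_equal(ov$n_overlap / length(unique(annotated$gene[
    annotated$feature != "Distal Intergenic"])), 1)
})

test_that("Venn partition counts and percentages are exact", {
  l <- simulate_deg_lists(20000, 3530, 2558, 1971, seed = 4)
  vp <- venn_partition(l$a, l$b)
  expect_equal(vp$shared, 1971)
  expect_equal(vp$unique_a, 1559)
  expect_equal(vp$unique_b, 587)
  expect_equal(vp$pct_unique_a, 44)
  expect_equal(vp$pct_unique_b, 23)
  # identity and disjoint cases
  expect_equal(venn_partition(l$a, l$a)$unique_a, 0)
  expect_equal(venn_partition(letters[1:3], letters[4:6])$shared, 0)
  # property: unique_a + shared = |A| on random inputs
  set.seed(5)
  for (i in 1:20) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    vp <- venn_partition(a, b)
    expect_equal(vp$unique_a + vp$shared, length(unique(a)))
    expect_equal(vp$unique_b + vp$shared, length(unique(b)))
    expect_equal(vp$union, vp$unique_a + vp$unique_b + vp$shared)
  }
})
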