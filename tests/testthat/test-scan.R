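make_groups <- function(hetero, homo) {
  structure(list(marker = "M", hetero = hetero, homo = homo,
                 excluded = data.frame(cross = character(0),
                                       reason = character(0)),
                 split_homo = FALSE),
            class = "genotype_groups")
}

test_that("marker test equals closed-form one-way ANOVA", {
  gr <- make_groups(list("1/2" = c("c1", "c2", "c3")), c("c4", "c5", "c6"))
  y <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), paste0("c", 1:6))
  r <- glm_marker_test(y, gr)
  expect_equal(r$F, 13.5)
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # null identity: identical values in all groups
  y0 <- setNames(rep(0.2, 6), paste0("c", 1:6))
  r0 <- suppressWarnings(glm_marker_test(y0, gr))
  expect_equal(r0$F, 0); expect_equal(r0$p, 1)
  # single eligible group is skipped
  gr1 <- make_groups(list(), c("c1", "c2", "c3"))
  expect_true(glm_marker_test(y, gr1)$skipped)
})

test_that("marker test matches the SS oracle on random datasets", {
  set.seed(101)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(3:6, k, replace = TRUE)
    keys <- paste0("x", seq_len(sum(n)))
    g <- rep(seq_len(k), n)
    y <- setNames(rnorm(sum(n)), keys)
    hetero <- split(keys[g < k], paste0(g[g < k], "/", g[g < k] + 10))
    gr <- make_groups(hetero, keys[g == k])
    r <- glm_marker_test(y, gr)
    o <- anova_oracle(y, g)
    expect_equal(r$F, o$F, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("fast projection-based F equals the lm route", {
  set.seed(202)
  sim <- simulate_founders(sim_config(n_founders = 10, n_markers = 8,
                                      seed = 5))
  d <- half_diallel(rownames(sim$geno$calls))
  pr <- project_hybrid_genotypes(sim$geno, d)
  y <- setNames(rnorm(nrow(pr$a1)), rownames(pr$a1))
  comb <- setNames(
    cluster_combination(pr$crosses$female, pr$crosses$male, sim$clusters),
    pr$crosses$key)
  for (m in colnames(pr$a1)) {
    gr <- partition_by_locus(pr, m, min_group = 3)
    des <- htlmap:::marker_design(y, gr)
    if (is.null(des)) next
    mf <- htlmap:::marker_F(des, matrix(y, ncol = 1))
    r <- glm_marker_test(y, gr)
    expect_equal(unname(mf$F), r$F, tolerance = 1e-9)
    expect_equal(unname(mf$p), r$p, tolerance = 1e-9)
    # and the cofactor variant against sequential lm anova
    des2 <- htlmap:::marker_design(y, gr, comb = comb)
    if (is.null(des2)) next
    mf2 <- htlmap:::marker_F(des2, matrix(y, ncol = 1))
    r2 <- glm_with_cofactor(y, gr, comb)
    if (!r2$skipped) {
      expect_equal(unname(mf2$F), r2$F, tolerance = 1e-9)
      expect_equal(unname(mf2$p), r2$p, tolerance = 1e-9)
    }
  }
})

test_that("KS statistic matches exhaustive ECDF enumeration", {
  # spec-style example
  r <- ks_hetero_vs_homo(c(0.5, 0.6), c(0.0, 0.55, 0.7))
  expect_equal(r$D, 1 / 3)
  # disjoint supports
  r2 <- ks_hetero_vs_homo(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$D, 1)
  # identical samples
  r3 <- ks_hetero_vs_homo(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$D, 0); expect_equal(r3$p, 1); expect_false(r3$advantage)
  set.seed(303)
  for (rep in 1:200) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    # ties included: integer-valued samples
    het <- sample(1:6, n1, replace = TRUE)
    hom <- sample(1:6, n2, replace = TRUE)
    o <- ks_oracle(het, hom)
    g <- ks_hetero_vs_homo(het, hom, sided = "greater")
    t2 <- ks_hetero_vs_homo(het, hom, sided = "two.sided")
    expect_equal(g$D, max(o$d_adv, 0))
    expect_equal(t2$D, o$d_two)
  }
})

test_that("two-sided KS agrees with stats::ks.test", {
  set.seed(404)
  for (rep in 1:50) {
    het <- rnorm(sample(5:30, 1))
    hom <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    r <- ks_hetero_vs_homo(het, hom, sided = "two.sided")
    ref <- suppressWarnings(stats::ks.test(het, hom, exact = FALSE))
    expect_equal(r$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-3)
  }
})

test_that("one-sided KS direction points at hetero advantage", {
  set.seed(505)
  for (rep in 1:50) {
    het <- rnorm(sample(5:20, 1), mean = runif(1, -1, 1))
    hom <- rnorm(sample(5:20, 1))
    r <- ks_hetero_vs_homo(het, hom, sided = "greater")
    # ks.test 'greater': CDF of x lies above that of y; hetero advantage
    # means the homozygote CDF lies above the hetero CDF
    ref <- suppressWarnings(stats::ks.test(hom, het,
                                           alternative = "greater",
                                           exact = FALSE))
    expect_equal(r$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-6)
  }
})

test_that("permutation threshold is the alpha-quantile of min-p", {
  sim <- simulate_founders(sim_config(n_founders = 10, n_markers = 6,
                                      seed = 9))
  d <- half_diallel(rownames(sim$geno$calls))
  pr <- project_hybrid_genotypes(sim$geno, d)
  y <- setNames(rnorm(nrow(pr$a1)), rownames(pr$a1))
  gl <- lapply(colnames(pr$a1), function(m) partition_by_locus(pr, m, 3))
  cfg <- scan_config(n_perm = 100, seed = 77)
  pt <- permutation_threshold(y, gl, cfg)
  expect_equal(pt$threshold, sort(pt$min_p)[5])
  expect_length(pt$min_p, 100)
  # determinism under the seed
  pt2 <- permutation_threshold(y, gl, cfg)
  expect_identical(pt$min_p, pt2$min_p)
  pt3 <- permutation_threshold(y, gl, scan_config(n_perm = 100, seed = 78))
  expect_false(identical(pt$min_p, pt3$min_p))
})

test_that("single-marker threshold approximates the comparison-wise level", {
  # with one marker the experiment-wise threshold is just the alpha
  # quantile of that marker's permutation p distribution
  sim <- simulate_founders(sim_config(n_founders = 10, n_markers = 1,
                                      seed = 10))
  d <- half_diallel(rownames(sim$geno$calls))
  pr <- project_hybrid_genotypes(sim$geno, d)
  set.seed(1); y <- setNames(rnorm(nrow(pr$a1)), rownames(pr$a1))
  gl <- list(partition_by_locus(pr, colnames(pr$a1)[1], 3))
  pt <- permutation_threshold(y, gl, scan_config(n_perm = 1000, seed = 3))
  expect_gt(pt$threshold, 0.02)
  expect_lt(pt$threshold, 0.09)
})

test_that("structure adjustment centers combinations and keeps the mean", {
  v <- c(rep(0.2, 10), rep(0.4, 10))
  comb <- rep(c("A:A", "A:B"), each = 10)
  adj <- adjust_for_structure(v, comb)
  expect_equal(unique(adj), 0.3)
  expect_equal(mean(adj), mean(v))
  # weighted example: means 0.1 (n=1) and 0.4 (n=3) -> grand 0.325
  v2 <- c(0.1, 0.4, 0.4, 0.4)
  comb2 <- c("A:A", "A:B", "A:B", "A:B")
  adj2 <- adjust_for_structure(v2, comb2)
  expect_equal(adj2, c(0.1 + 0.225, 0.4 - 0.075, 0.4 - 0.075, 0.4 - 0.075))
  expect_equal(mean(adj2), 0.325)
  # single combination: identity
  expect_equal(adjust_for_structure(v2, rep("A:A", 4)), v2)
  # between-combination variance is removed
  set.seed(6)
  v3 <- rnorm(30); c3 <- sample(c("A:A", "A:B", "B:B"), 30, replace = TRUE)
  a3 <- adjust_for_structure(v3, c3)
  expect_equal(as.numeric(tapply(a3, c3, mean)),
               rep(mean(v3), 3), tolerance = 1e-12)
})

test_that("unlabeled founders are reported by name", {
  expect_error(cluster_combination("A", "B", c(A = "c1")), "B")
})

test_that("cofactor model reduces to the one-way test for one level", {
  gr <- make_groups(list("1/2" = c("c1", "c2", "c3")), c("c4", "c5", "c6"))
  y <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), paste0("c", 1:6))
  comb <- setNames(rep("A:A", 6), paste0("c", 1:6))
  r <- glm_with_cofactor(y, gr, comb)
  r0 <- glm_marker_test(y, gr)
  expect_equal(r$F, r0$F); expect_equal(r$p, r0$p)
  # aliasing: genotype groups nested in cofactor levels
  comb2 <- setNames(c(rep("A:B", 3), rep("A:A", 3)), paste0("c", 1:6))
  r2 <- glm_with_cofactor(y, gr, comb2)
  expect_true(r2$skipped)
  expect_match(r2$reason, "aliased")
})

test_that("scan gates step 2 on step 1 and is reproducible", {
  cfg <- sim_config(n_founders = 12, n_markers = 15,
                    planted_htls = data.frame(marker = NA, d = 0.8),
                    reps_hybrid = 4, reps_parent = 10, seed = 21)
  sim <- simulate_diallel(cfg)
  sc_cfg <- scan_config(n_perm = 200, seed = 31)
  sc <- htl_scan(sim$geno, sim$design, "DPW", sc_cfg, pheno = sim$pheno)
  for (yr in names(sc$per_year)) {
    res <- sc$per_year[[yr]]
    passed <- res$markers$marker[res$markers$passed]
    expect_true(all(res$ks$marker %in% passed))
    expect_true(all(res$ks$D >= 0 & res$ks$D <= 1))
  }
  sc2 <- htl_scan(sim$geno, sim$design, "DPW", sc_cfg, pheno = sim$pheno)
  expect_identical(sc$calls, sc2$calls)
  expect_identical(sc$per_year[["1"]]$markers, sc2$per_year[["1"]]$markers)
})

test_that("a strongly planted pair is called and named by chromosome", {
  cfg <- sim_config(n_founders = 14, n_markers = 20,
                    planted_htls = data.frame(marker = NA, d = 0.9),
                    reps_hybrid = 4, reps_parent = 10, seed = 33)
  sim <- simulate_diallel(cfg)
  sc <- htl_scan(sim$geno, sim$design, "DPW",
                 scan_config(n_perm = 500, seed = 41), pheno = sim$pheno)
  expect_true(sim$truth$planted$marker %in% sc$calls$marker)
  called <- sc$calls[sc$calls$marker == sim$truth$planted$marker, ]
  expect_true(sim$truth$planted$pair %in% called$pair)
  chrom <- sim$geno$map$chromosome[sim$geno$map$marker == called$marker[1]]
  expect_match(called$name[1], paste0("^hDPW", chrom, "\\."))
})

test_that("single-year scan with require_both_years off reports that year", {
  cfg <- sim_config(n_founders = 12, n_markers = 10, years = 1,
                    planted_htls = data.frame(marker = NA, d = 0.9),
                    reps_hybrid = 5, reps_parent = 10, seed = 55)
  sim <- simulate_diallel(cfg)
  sc <- htl_scan(sim$geno, sim$design, "DPW",
                 scan_config(n_perm = 200, seed = 5,
                             require_both_years = FALSE),
                 pheno = sim$pheno)
  adv <- sc$per_year[["1"]]$ks
  adv <- unique(paste(adv$marker[adv$advantage], adv$pair[adv$advantage]))
  expect_setequal(paste(sc$calls$marker, sc$calls$pair), adv)
})

test_that("different pairs in different years do not intersect into a call", {
  ks1 <- data.frame(marker = "M1", pair = "1/2", n_het = 5L, n_hom = 9L,
                    D = 0.9, p = 0.001, advantage = TRUE)
  ks2 <- ks1; ks2$pair <- "1/3"
  py <- list(`1` = list(ks = ks1), `2` = list(ks = ks2))
  expect_equal(nrow(call_htls(py, trait = "DPW")$calls), 0L)
  py2 <- list(`1` = list(ks = ks1), `2` = list(ks = ks1))
  expect_equal(nrow(call_htls(py2, trait = "DPW")$calls), 1L)
  # lenient mode unions the years
  expect_equal(nrow(call_htls(py, trait = "DPW",
                              require_both_years = FALSE)$calls), 2L)
})
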