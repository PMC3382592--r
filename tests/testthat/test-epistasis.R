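test_that("P/N recoding marks carriers of the advantaged pair", {
  g <- founder_geno(rbind(P1 = c(M = 154L), P2 = c(M = 162L),
                          P3 = c(M = 154L), P4 = c(M = NA)))
  pr <- project_hybrid_genotypes(g, half_diallel(c("P1", "P2", "P3", "P4")))
  f <- pn_recode(pr, "M", "154/162")
  expect_equal(unname(f["P1:P2"]), factor("P", levels = c("P", "N")))
  expect_equal(as.character(f["P1:P3"]), "N")       # homozygous 154/154
  expect_false("P1:P4" %in% names(f))               # missing call dropped
  # consistent allele relabeling leaves the factor unchanged
  g2 <- g; g2$calls[g2$calls == 154] <- 900L; g2$calls[g2$calls == 162] <- 910L
  pr2 <- project_hybrid_genotypes(g2, half_diallel(c("P1", "P2", "P3", "P4")))
  f2 <- pn_recode(pr2, "M", "900/910")
  expect_identical(as.character(f), as.character(f2))
})

test_that("two-way ANOVA decomposition sums to the total", {
  set.seed(61)
  n <- 120
  A <- factor(sample(c("P", "N"), n, replace = TRUE))
  B <- factor(sample(c("P", "N"), n, replace = TRUE))
  yr <- factor(rep(1:2, length.out = n))
  y <- 0.3 * (A == "P") + 0.2 * (B == "P") + rnorm(n, 0, 0.3)
  r <- two_way_anova(y, yr, A, B)
  sst <- sum((y - mean(y))^2)
  expect_equal(sum(r$table$ss) + r$residual_ss, sst, tolerance = 1e-9)
  expect_equal(r$accum$cum_r2[nrow(r$accum)], r$r2, tolerance = 1e-12)
  expect_true(all(diff(r$accum$cum_r2) >= -1e-12))
})

test_that("a pure crossover interaction loads on the interaction term", {
  # cell means +d, -d, -d, +d with tiny noise: mains ~ 0, interaction big
  set.seed(62)
  cells <- expand.grid(A = c("P", "N"), B = c("P", "N"),
                       rep = 1:10, yr = 1:2)
  d <- 1
  mu <- with(cells, ifelse((A == "P") == (B == "P"), d, -d))
  y <- mu + rnorm(nrow(cells), 0, 0.05)
  r <- two_way_anova(y, cells$yr, cells$A, cells$B)
  tab <- r$table
  expect_lt(tab$p[tab$term == "A:B"], 1e-6)
  expect_gt(tab$ss[tab$term == "A:B"],
            100 * sum(tab$ss[tab$term %in% c("A", "B")]))
})

test_that("additively simulated data show a null interaction", {
  set.seed(63)
  ps <- replicate(40, {
    n <- 100
    A <- factor(sample(c("P", "N"), n, replace = TRUE))
    B <- factor(sample(c("P", "N"), n, replace = TRUE))
    y <- 0.5 * (A == "P") + 0.3 * (B == "P") + rnorm(n)
    r <- two_way_anova(y, rep(1, n), A, B)
    r$table$p[r$table$term == "A:B"]
  })
  # interaction p-values behave like a null sample
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(mean(ps), 0.3)
})

test_that("single-year data reduce to the fixed two-way model", {
  set.seed(64)
  n <- 60
  A <- factor(sample(c("P", "N"), n, replace = TRUE))
  B <- factor(sample(c("P", "N"), n, replace = TRUE))
  y <- rnorm(n)
  r <- two_way_anova(y, rep(1, n), A, B)
  expect_false("year" %in% r$table$term)
  ref <- anova(lm(y ~ A + B + A:B))
  expect_equal(r$table$F, ref[1:3, "F value"], tolerance = 1e-12)
})

test_that("empty interaction cells are flagged, mains still reported", {
  A <- factor(c("P", "P", "N", "N", "P", "N"))
  B <- factor(c("P", "P", "P", "P", "P", "P"))
  B[A == "N"] <- "P"   # no (N, N) cell will exist once B has two levels
  B <- factor(c("P", "N", "P", "P", "N", "P"))
  A <- factor(c("P", "P", "N", "N", "P", "N"))
  # construct explicit empty cell: no A=N with B=N
  keep <- !(A == "N" & B == "N")
  r <- two_way_anova(rnorm(sum(keep)), rep(1, sum(keep)), A[keep], B[keep])
  expect_match(r$note, "untestable")
  expect_true(all(c("A", "B") %in% r$table$term))
})

test_that("three-way model orders factors by marginal contribution", {
  sim <- simulate_epistasis(fractions = c(0.04, 0.07, 0.12), n = 2000,
                            seed = 65)
  r <- three_way_model(sim$data$y, sim$data$year, sim$data$A, sim$data$B,
                       sim$data$C)
  mains <- r$table[r$table$term %in% c("A", "B", "C"), ]
  # C planted largest: enters first with the largest single-factor share
  expect_equal(mains$term[1], "C")
  expect_equal(mains$ss, sort(mains$ss, decreasing = TRUE))
  expect_true(all(diff(r$accum$cum_r2) >= -1e-12))
})

test_that("planted variance fractions are recovered by sequential R2", {
  fr <- c(0.12, 0.07, 0.04)
  est <- sapply(1:12, function(s) {
    sim <- simulate_epistasis(fractions = fr, n = 280, seed = s + 400)
    r <- three_way_model(sim$data$y, sim$data$year, sim$data$A, sim$data$B,
                         sim$data$C)
    tab <- r$table
    c(A = tab$r2[tab$term == "A"], B = tab$r2[tab$term == "B"],
      C = tab$r2[tab$term == "C"])
  })
  med <- apply(est, 1, median)
  expect_lt(max(abs(unname(med[c("A", "B", "C")]) - fr)), 0.04)
})

test_that("null data give near-zero R2", {
  set.seed(66)
  n <- 300
  A <- factor(sample(c("P", "N"), n, replace = TRUE))
  B <- factor(sample(c("P", "N"), n, replace = TRUE))
  C <- factor(sample(c("P", "N"), n, replace = TRUE))
  r <- three_way_model(rnorm(n), rep(1:2, length.out = n), A, B, C)
  expect_lt(r$r2, 0.1)
})

test_that("variance_explained returns the monotone accumulation", {
  set.seed(67)
  n <- 100
  A <- factor(sample(c("P", "N"), n, replace = TRUE))
  B <- factor(sample(c("P", "N"), n, replace = TRUE))
  y <- (A == "P") + rnorm(n)
  r <- two_way_anova(y, rep(1, n), A, B)
  ve <- variance_explained(r)
  expect_identical(ve, r$accum)
  expect_equal(ve$cum_r2[nrow(ve)], r$r2)
})
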