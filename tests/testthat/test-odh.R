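test_that("per-replicate ODH follows the three-branch definition", {
  expect_equal(odh_replicate(12, 5, 10), 0.2)
  expect_equal(odh_replicate(7, 5, 10), 0)
  expect_equal(odh_replicate(4, 5, 10), -0.2)
  # boundary: both branches agree at the parent bounds
  expect_equal(odh_replicate(10, 5, 10), 0)
  expect_equal(odh_replicate(5, 5, 10), 0)
  # equal parent means: any deviation counts
  expect_equal(odh_replicate(9, 8, 8), 0.125)
  expect_warning(out <- odh_replicate(5, -1, 10), "non-positive")
  expect_true(is.na(out))
})

test_that("ODH agrees with the brute-force oracle on random inputs", {
  set.seed(42)
  for (rep in 1:50) {
    p <- sort(runif(2, 1, 20))
    f1 <- runif(10, 0, 30)
    expect_equal(odh_replicate(f1, p[1], p[2]), odh_oracle(f1, p[1], p[2]))
  }
})

test_that("ODH, MPH and BPH are scale invariant", {
  set.seed(7)
  for (rep in 1:20) {
    p <- sort(runif(2, 1, 20))
    f1 <- runif(5, 0, 30)
    c_ <- runif(1, 0.1, 10)
    expect_equal(odh_replicate(c_ * f1, c_ * p[1], c_ * p[2]),
                 odh_replicate(f1, p[1], p[2]))
  }
  ph1 <- toy_pheno(); ph2 <- ph1; ph2$DPW <- 3.7 * ph2$DPW
  d <- toy_cross_design()
  o1 <- odh_table(ph1, d, "DPW"); o2 <- odh_table(ph2, d, "DPW")
  expect_equal(o1[c("ODH", "MPH", "BPH")], o2[c("ODH", "MPH", "BPH")])
})

test_that("mean ODH of a cross averages the replicates", {
  d <- toy_cross_design()
  # replicates 12, 7, 4 against P1=5, P2=10: mean(0.2, 0, -0.2) = 0
  o <- odh_table(toy_pheno(), d, "DPW")
  expect_equal(o$ODH, 0)
  expect_equal(o$R, 3L)
  o2 <- odh_table(toy_pheno(hybrid = c(11, 12)), d, "DPW")
  expect_equal(o2$ODH, 0.15)
  o3 <- odh_table(toy_pheno(hybrid = c(10, 10)), d, "DPW")
  expect_equal(o3$ODH, 0)
})

test_that("mean ODH sign reflects excursions beyond the parental range", {
  set.seed(13)
  d <- toy_cross_design()
  for (rep in 1:20) {
    hyb <- runif(6, 0.5, 20)
    o <- odh_table(toy_pheno(hybrid = hyb), d, "DPW")
    if (all(hyb >= 5 & hyb <= 10)) expect_equal(o$ODH, 0)
    if (o$ODH > 0) expect_true(any(hyb > 10))
    if (o$ODH < 0) expect_true(any(hyb < 5))
  }
})

test_that("single-cross ODH agrees with the table route", {
  ph <- toy_pheno(hybrid = c(11, 12, 3))
  d <- toy_cross_design()
  oc <- odh_cross(ph, d, "B", "A", "DPW", "1")   # order-free parents
  tab <- odh_table(ph, d, "DPW")
  expect_true(oc$ok)
  expect_equal(oc$ODH, tab$ODH)
  expect_equal(oc$R, tab$R)
  expect_false(odh_cross(ph, d, "A", "Z", "DPW", "1")$ok)
})

test_that("parent bounds order the parental means", {
  ph <- toy_pheno()
  b <- parent_bounds(ph, "A", "B", "DPW", "1")
  expect_equal(b$P1, 5); expect_equal(b$P2, 10); expect_true(b$ok)
  b2 <- parent_bounds(ph, "B", "A", "DPW", "1")
  expect_equal(b2$P1, 5)  # order-free
  b3 <- parent_bounds(ph, "A", "Z", "DPW", "1")
  expect_false(b3$ok)
})

test_that("MPH and BPH match their definitions", {
  d <- toy_cross_design()
  r <- mph_bph(toy_pheno(hybrid = c(12, 12)), d, "A", "B", "DPW", "1")
  expect_equal(r$MPH, 0.6)   # (12 - 7.5)/7.5
  expect_equal(r$BPH, 0.2)   # (12 - 10)/10
  r2 <- mph_bph(toy_pheno(hybrid = c(7.5, 7.5)), d, "A", "B", "DPW", "1")
  expect_equal(r2$MPH, 0)
  r3 <- mph_bph(toy_pheno(hybrid = c(10, 10)), d, "A", "B", "DPW", "1")
  expect_equal(r3$BPH, 0)
  # single replicate at or above the high parent: ODH equals BPH
  o <- odh_table(toy_pheno(hybrid = 13), d, "DPW")
  expect_equal(o$ODH, o$BPH)
})

test_that("seed number derivation and its guards", {
  expect_equal(derive_seed_number(50, 5), 500)
  expect_equal(derive_seed_number(0, 5), 0)
  expect_equal(derive_seed_number(7.3, 2.0), 182.5)
  expect_warning(sn <- derive_seed_number(10, 0), "non-positive")
  expect_true(is.na(sn))
})

test_that("reciprocal test verdicts", {
  expect_equal(reciprocal_test(c(1, 1, 1), c(1, 1, 1))$verdict,
               "not different")
  x <- c(1, 1.01, 0.99); y <- c(9, 9.01, 8.99)
  rt <- reciprocal_test(x, y)
  expect_equal(rt$verdict, "different")
  expect_lt(rt$p, 1e-4)
  expect_equal(reciprocal_test(c(1, 2), c(3, 4, 5))$verdict, "untestable")
})

test_that("flagged crosses carry reasons instead of silent NaN", {
  ph <- toy_pheno()
  ph$DPW[ph$entry == "A"] <- c(-5, -5)   # non-positive parent mean
  d <- toy_cross_design()
  o <- odh_table(ph, d, "DPW")
  expect_equal(o$flag, "non-positive parent mean")
  expect_true(is.na(o$ODH))
  ph2 <- toy_pheno()[-(1:2), ]           # parent A unphenotyped
  o2 <- odh_table(ph2, d, "DPW")
  expect_equal(o2$flag, "parent unphenotyped")
})

test_that("reciprocal replicates are pooled and differing pairs flagged", {
  ph <- rbind(toy_pheno(hybrid = c(8, 8, 8)),
              data.frame(entry = "BxA", year = "1", replicate = 1:3,
                         DPW = c(8, 8, 8)))
  d <- diallel_design(data.frame(cross_id = c("AxB", "BxA"),
                                 female = c("A", "B"), male = c("B", "A"),
                                 year = "1"))
  o <- odh_table(ph, d, "DPW")
  expect_equal(nrow(o), 1L)
  expect_equal(o$R, 6L)
  expect_false(o$recip_diff)
  ph$DPW[ph$entry == "BxA"] <- c(30.0, 30.2, 29.8)
  o2 <- odh_table(ph, d, "DPW")
  expect_true(o2$recip_diff)
})
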