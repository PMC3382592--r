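# Small in-code fixtures shared across test files.

# Six founders, two markers: M1 has two alleles carried 3/3 (the classic
# two-group locus), M2 is monomorphic.
toy_geno <- function() {
  calls <- rbind(
    F1 = c(M1 = 154L, M2 = 200L),
    F2 = c(M1 = 154L, M2 = 200L),
    F3 = c(M1 = 154L, M2 = 200L),
    F4 = c(M1 = 162L, M2 = 200L),
    F5 = c(M1 = 162L, M2 = 200L),
    F6 = c(M1 = 162L, M2 = 200L))
  founder_geno(calls,
               map = data.frame(marker = c("M1", "M2"),
                                chromosome = c(1, 2),
                                position = c(1e6, 2e6)))
}

toy_design <- function(year = "1") half_diallel(rownames(toy_geno()$calls), year)

# A tiny phenotype table for one cross (A x B) and its parents, with exact
# values for hand-computed heterosis checks.
toy_pheno <- function(parent_a = c(5, 5), parent_b = c(10, 10),
                      hybrid = c(12, 7, 4), year = "1") {
  rbind(
    data.frame(entry = "A", year = year, replicate = seq_along(parent_a),
               DPW = parent_a),
    data.frame(entry = "B", year = year, replicate = seq_along(parent_b),
               DPW = parent_b),
    data.frame(entry = "AxB", year = year, replicate = seq_along(hybrid),
               DPW = hybrid))
}

toy_cross_design <- function(year = "1") {
  diallel_design(data.frame(cross_id = "AxB", female = "A", male = "B",
                            year = year))
}

# Brute-force three-branch ODH definition, kept deliberately naive.
odh_oracle <- function(f1, p1, p2) {
  vapply(f1, function(v) {
    if (v >= p2) (v - p2) / p2
    else if (v <= p1) (v - p1) / p1
    else 0
  }, numeric(1))
}

# Closed-form one-way ANOVA F from group sums of squares.
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(n * (gm[names(n)] - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- length(gm) - 1
  df2 <- length(values) - length(gm)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Exhaustive ECDF-difference enumeration for the two-sample KS statistic.
ks_oracle <- function(het, hom) {
  xs <- sort(unique(c(het, hom)))
  Fh <- vapply(xs, function(t) mean(het <= t), numeric(1))
  Fo <- vapply(xs, function(t) mean(hom <= t), numeric(1))
  list(d_adv = max(Fo - Fh), d_dis = max(Fh - Fo),
       d_two = max(abs(Fo - Fh)))
}
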