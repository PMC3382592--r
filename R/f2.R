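#' Genotype-group summaries and ANOVA in an F2
#'
#' Per-genotype sample size, mean and standard error for one trait, plus
#' the one-way ANOVA p-value testing linkage between the focal marker and
#' the trait.
#'
#' @param genotype character/factor of genotypes at the focal marker
#'   (e.g. `"154/154"`, `"154/162"`, `"162/162"`).
#' @param values numeric trait values, aligned with `genotype`.
#' @return List with `table` (data.frame `group`, `n`, `mean`, `se`),
#'   `F`, `p`, `df1`, `df2`, `ms_error` and `df_error` (pooled residual
#'   mean square, for [hsu_mcb()]).
#' @export
f2_group_stats <- function(genotype, values) {
  ok <- !is.na(genotype) & !is.na(values)
  g <- droplevels(factor(genotype[ok])); y <- values[ok]
  if (nlevels(g) < 2) stop("need at least two non-empty genotype groups")
  tab <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(y, g, mean)),
    se = as.numeric(tapply(y, g, function(v)
      stats::sd(v) / sqrt(length(v)))),
    stringsAsFactors = FALSE)
  an <- stats::anova(stats::lm(y ~ g))
  list(table = tab, F = an[1, "F value"], p = an[1, "Pr(>F)"],
       df1 = an[1, "Df"], df2 = an[2, "Df"],
       ms_error = an[2, "Mean Sq"], df_error = an[2, "Df"])
}

#' Hsu's multiple comparisons with the best
#'
#' For each genotype group, one-sided comparison of its mean against the
#' best of the other groups, using the pooled residual mean square. The
#' "best set" is the set of groups not significantly worse than the
#' (unknown) best; its members share letter `"a"`, the rest get `"b"`.
#' With two groups the procedure reduces exactly to a one-sided pooled
#' t-test; with three or more, the per-group p-value
#' `P(max_j (Ybar_j - Ybar_i) >= observed)` is computed by seeded
#' Monte-Carlo from the fitted null (equal means, pooled variance), which
#' keeps the implementation self-contained.
#'
#' @param stats a [f2_group_stats()] result (or any list with `table`,
#'   `ms_error`, `df_error`).
#' @param alpha familywise level (default 0.05).
#' @param n_mc Monte-Carlo draws for the null distribution (default
#'   20000).
#' @param mc_seed seed for the Monte-Carlo draws (default 1), so results
#'   are reproducible.
#' @return data.frame with columns `group`, `n`, `mean`, `diff_best`
#'   (mean minus best other mean), `p`, `in_best_set`, `letter`.
#' @export
hsu_mcb <- function(stats, alpha = 0.05, n_mc = 20000, mc_seed = 1) {
  tab <- stats$table
  k <- nrow(tab)
  if (k < 2) stop("need at least two groups")
  s2 <- stats$ms_error; df <- stats$df_error
  degenerate <- !is.finite(s2) || s2 <= 0
  m <- tab$mean; n <- tab$n
  diff_best <- vapply(seq_len(k), function(i) m[i] - max(m[-i]), 0)
  if (degenerate) {
    p <- as.numeric(diff_best < 0)   # exact ordering, no noise
  } else if (k == 2) {
    tstat <- vapply(seq_len(k), function(i) {
      j <- if (i == 1) 2 else 1
      (m[j] - m[i]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    }, 0)
    p <- stats::pt(tstat, df, lower.tail = FALSE)
  } else {
    draws <- with_seed(mc_seed, {
      z <- matrix(stats::rnorm(n_mc * k), n_mc, k)
      z <- sweep(z, 2, sqrt(1 / n), "*")
      sdr <- sqrt(stats::rchisq(n_mc, df) / df)
      list(z = z, sdr = sdr)
    })
    p <- vapply(seq_len(k), function(i) {
      obs <- (max(m[-i]) - m[i]) / sqrt(s2)
      tmc <- (apply(draws$z[, -i, drop = FALSE], 1, max) - draws$z[, i]) /
        draws$sdr
      mean(tmc >= obs)
    }, 0)
  }
  in_best <- p > alpha | diff_best >= 0
  data.frame(group = tab$group, n = n, mean = m, diff_best = diff_best,
             p = p, in_best_set = in_best,
             letter = ifelse(in_best, "a", "b"),
             stringsAsFactors = FALSE)
}

#' Percent overdominant effect of the heterozygote
#'
#' Relative gain of the heterozygote mean over the homozygote baseline,
#' in percent: `100 * (mean_het - baseline) / baseline`. The default
#' baseline is the unweighted average of the two homozygote group means
#' (the symmetric convention); `baseline = "best"` uses the better
#' homozygote instead.
#'
#' @param stats a [f2_group_stats()] result; heterozygous groups are
#'   identified from the `"a1/a2"` group labels (two distinct alleles).
#' @param baseline `"mean"` (default) or `"best"`.
#' @return Percent effect (single number).
#' @export
overdominance_effect <- function(stats, baseline = c("mean", "best")) {
  baseline <- match.arg(baseline)
  tab <- stats$table
  al <- strsplit(tab$group, "/", fixed = TRUE)
  is_het <- vapply(al, function(a) length(unique(a)) == 2, TRUE)
  if (sum(is_het) != 1 || sum(!is_het) < 2)
    stop("need one heterozygous and two homozygous groups")
  het <- tab$mean[is_het]
  homs <- tab$mean[!is_het]
  base <- if (baseline == "mean") mean(homs) else max(homs)
  if (base <= 0) stop("non-positive homozygote baseline")
  100 * (het - base) / base
}
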