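#' Recode a locus into P/N genetic states
#'
#' At a detected HTL, hybrids carrying an advantaged allele pair form the
#' `P` (positive intra-locus interaction) state; every other allelic
#' combination is `N` (neutral). Crosses with a missing projected genotype
#' are dropped.
#'
#' @param proj a [project_hybrid_genotypes()] result.
#' @param marker marker name of the HTL.
#' @param advantaged character vector of advantaged pairs (`"a1/a2"`, as
#'   in [partition_by_locus()] labels).
#' @return Named factor (levels `P`, `N`) over crosses with a genotype.
#' @export
pn_recode <- function(proj, marker, advantaged) {
  if (!length(advantaged)) stop("need at least one advantaged pair")
  if (!marker %in% colnames(proj$a1))
    stop("marker ", marker, " absent from the projected genotypes")
  a1 <- proj$a1[, marker]; a2 <- proj$a2[, marker]
  ok <- !is.na(a1) & !is.na(a2)
  pair <- paste(a1[ok], a2[ok], sep = "/")
  f <- factor(ifelse(pair %in% advantaged, "P", "N"), levels = c("P", "N"))
  setNames(f, rownames(proj$a1)[ok])
}

anova_result <- function(fit, terms, note = "") {
  an <- stats::anova(fit)
  rows <- match(terms, rownames(an))
  present <- !is.na(rows)
  tab <- data.frame(term = terms[present],
                    df = an[rows[present], "Df"],
                    ss = an[rows[present], "Sum Sq"],
                    F = an[rows[present], "F value"],
                    p = an[rows[present], "Pr(>F)"],
                    stringsAsFactors = FALSE)
  sst <- sum(an[, "Sum Sq"])
  tab$r2 <- tab$ss / sst
  accum <- data.frame(term = tab$term, cum_r2 = cumsum(tab$ss) / sst,
                      stringsAsFactors = FALSE)
  model_r2 <- sum(tab$ss) / sst
  structure(list(table = tab, r2 = model_r2, accum = accum,
                 residual_df = an["Residuals", "Df"],
                 residual_ss = an["Residuals", "Sum Sq"],
                 total_ss = sst, note = note),
            class = "htl_anova")
}

#' @export
print.htl_anova <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("Model R2 = %.3f (residual df = %d)\n", x$r2, x$residual_df))
  if (nzchar(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

check_levels <- function(f, name) {
  f <- droplevels(factor(f))
  if (nlevels(f) < 2)
    warning("factor ", name, " has a single level")
  f
}

#' Two-locus ANOVA of heterotic values with interaction
#'
#' Fits `Y = mu + A + B + A:B + year + e` with the year entering first as
#' a random blocking term whose variance is absorbed before the fixed
#' tests, and the fixed HTL effects (and their interaction) tested against
#' the residual, following the expected-mean-squares convention for a
#' random block without block-by-factor interactions. Sums of squares are
#' sequential (Type I), so the decomposition always sums to the total.
#'
#' @param values numeric response (cross-level ODH, possibly over several
#'   years).
#' @param year year label per observation.
#' @param A,B P/N factors per observation (see [pn_recode()]).
#' @return Object of class `htl_anova`: term table (df, SS, F, p, per-term
#'   R2), model `r2`, `accum` (cumulative R2) and a `note` when the
#'   interaction is untestable (an empty A x B cell).
#' @export
two_way_anova <- function(values, year, A, B) {
  d <- data.frame(y = values, year = factor(year),
                  A = factor(A), B = factor(B))
  d <- d[complete.cases(d), , drop = FALSE]
  note <- ""
  cells <- table(d$A, d$B)
  if (any(cells == 0))
    note <- "empty A x B cell: interaction untestable"
  multi_year <- nlevels(droplevels(d$year)) > 1
  form <- if (multi_year) y ~ year + A + B + A:B else y ~ A + B + A:B
  fit <- stats::lm(form, data = d)
  terms <- c(if (multi_year) "year", "A", "B", "A:B")
  anova_result(fit, terms, note = note)
}

#' Three-locus ANOVA with one planted interaction
#'
#' Fits `Y = mu + A + B + C + A:B + year + e` (year first, as in
#' [two_way_anova()]); only the A:B interaction is modeled. The entry
#' order of the main effects defaults to descending single-factor R2 so
#' the sequential decomposition credits the strongest locus first;
#' `order` overrides it.
#'
#' @inheritParams two_way_anova
#' @param C third P/N factor.
#' @param order optional character permutation of `c("A","B","C")` giving
#'   the sequential entry order of the main effects.
#' @param include_interaction include the `A:B` term (default `TRUE`).
#' @return Object of class `htl_anova`.
#' @export
three_way_model <- function(values, year, A, B, C, order = NULL,
                            include_interaction = TRUE) {
  d <- data.frame(y = values, year = factor(year),
                  A = factor(A), B = factor(B), C = factor(C))
  d <- d[complete.cases(d), , drop = FALSE]
  if (is.null(order)) {
    r2_one <- vapply(c("A", "B", "C"), function(f) {
      ff <- stats::lm(stats::reformulate(f, "y"), data = d)
      1 - sum(stats::resid(ff)^2) / sum((d$y - mean(d$y))^2)
    }, numeric(1))
    order <- names(sort(r2_one, decreasing = TRUE))
  }
  stopifnot(setequal(order, c("A", "B", "C")))
  note <- ""
  if (include_interaction && any(table(d$A, d$B) == 0))
    note <- "empty A x B cell: interaction untestable"
  multi_year <- nlevels(droplevels(d$year)) > 1
  rhs <- c(if (multi_year) "year", order,
           if (include_interaction) "A:B")
  fit <- stats::lm(stats::reformulate(rhs, "y"), data = d)
  anova_result(fit, rhs, note = note)
}

#' Accumulated variance explained
#'
#' Sequence of cumulative R2 values as each model term is added, in the
#' fitted sequential order. Non-decreasing by construction; the final
#' entry equals the model R2.
#'
#' @param result an `htl_anova` object.
#' @return data.frame with columns `term`, `cum_r2`.
#' @export
variance_explained <- function(result) {
  stopifnot(inherits(result, "htl_anova"))
  result$accum
}
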