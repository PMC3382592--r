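#' Scan configuration
#'
#' @param alpha experiment-wise (genome-wide) type-I level for step 1
#'   (default 0.05).
#' @param n_perm number of permutations for the experiment-wise threshold
#'   (default 1000; at least 100).
#' @param seed integer RNG seed; all permutation streams derive from it.
#' @param min_group minimum crosses per genotypic group (default 3).
#' @param ks_alpha per-contrast level of the step-2 Kolmogorov-Smirnov
#'   test (default 0.05).
#' @param ks_sided `"greater"` (hetero group stochastically larger;
#'   default) or `"two.sided"`.
#' @param require_both_years call an HTL only when the same allele pair is
#'   advantaged in every scanned year (default `TRUE`).
#' @param split_homo per-allele homozygous groups instead of one pooled
#'   reference group (default `FALSE`).
#' @param per_locus_bonferroni divide `ks_alpha` by the number of hetero
#'   groups tested at a locus (default `FALSE`, matching raw per-contrast
#'   p-values).
#' @return List of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.05, n_perm = 1000, seed = 1,
                        min_group = 3, ks_alpha = 0.05,
                        ks_sided = c("greater", "two.sided"),
                        require_both_years = TRUE, split_homo = FALSE,
                        per_locus_bonferroni = FALSE) {
  ks_sided <- match.arg(ks_sided)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_group >= 1)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), min_group = as.integer(min_group),
                 ks_alpha = ks_alpha, ks_sided = ks_sided,
                 require_both_years = require_both_years,
                 split_homo = split_homo,
                 per_locus_bonferroni = per_locus_bonferroni),
            class = "scan_config")
}

# ---- step 1: genotypic-group linear model ---------------------------------

group_labels <- function(groups) {
  lab <- c(
    unlist(lapply(names(groups$hetero), function(g)
      setNames(rep(g, length(groups$hetero[[g]])), groups$hetero[[g]]))),
    if (is.list(groups$homo))
      unlist(lapply(names(groups$homo), function(g)
        setNames(rep(g, length(groups$homo[[g]])), groups$homo[[g]])))
    else setNames(rep("H:H", length(groups$homo)), groups$homo))
  lab
}

#' One-way genotypic-group test at a marker
#'
#' Fixed-effects one-way analysis of variance of cross-level mean ODH on
#' genotypic group (the step-1 model `Y_ij = mu + alpha_i + e_ij`): the
#' error term is the variation between the ODH means of different crosses
#' within a group.
#'
#' @param values named numeric vector of cross-level mean ODH (names =
#'   cross keys).
#' @param groups a [partition_by_locus()] result.
#' @return List with `F`, `p`, `df1`, `df2`, `n`, `k` (group count),
#'   `skipped`, `reason`.
#' @export
glm_marker_test <- function(values, groups) {
  lab <- group_labels(groups)
  lab <- lab[names(lab) %in% names(values)]
  y <- values[names(lab)]
  keep <- !is.na(y)
  y <- y[keep]; lab <- lab[keep]
  k <- length(unique(lab))
  if (k < 2)
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                n = length(y), k = k, skipped = TRUE,
                reason = "fewer than 2 eligible groups"))
  if (length(y) - k < 1)
    return(list(F = NA_real_, p = NA_real_, df1 = k - 1, df2 = length(y) - k,
                n = length(y), k = k, skipped = TRUE,
                reason = "no residual degrees of freedom"))
  g <- factor(lab)
  sst <- sum((y - mean(y))^2)
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  Fv <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  sse <- an[2, "Sum Sq"]
  if (sst < .Machine$double.eps^0.5 * max(1, mean(y)^2)) {
    Fv <- 0; p <- 1                      # all values identical
  } else if (sse <= sst * 1e-12) {
    Fv <- Inf; p <- 0                    # perfect group separation
  }
  list(F = unname(Fv), p = unname(p), df1 = k - 1, df2 = length(y) - k,
       n = length(y), k = k, skipped = FALSE, reason = "")
}

# Precompute orthonormal bases for the reduced (intercept [+ cofactor]) and
# full (+ genotypic group) design at one marker, over the crosses that have
# an ODH value. Returns NULL with attr "reason" when untestable.
marker_design <- function(values, groups, comb = NULL) {
  values <- values[!is.na(values)]
  lab <- group_labels(groups)
  lab <- lab[names(lab) %in% names(values)]
  if (length(unique(lab)) < 2) {
    out <- NULL; attr(out, "reason") <- "fewer than 2 eligible groups"
    return(out)
  }
  idx <- match(names(lab), names(values))
  g <- factor(lab)
  df <- data.frame(g = g)
  if (!is.null(comb)) {
    cf <- factor(comb[names(lab)])
    if (nlevels(droplevels(cf)) > 1) df$comb <- droplevels(cf)
  }
  Xr <- if (is.null(df$comb)) matrix(1, nrow(df), 1)
        else stats::model.matrix(~comb, df)
  Xf <- if (is.null(df$comb)) stats::model.matrix(~g, df)
        else stats::model.matrix(~comb + g, df)
  qr_r <- qr(Xr); qr_f <- qr(Xf)
  df1 <- qr_f$rank - qr_r$rank
  df2 <- nrow(Xf) - qr_f$rank
  if (df1 < 1 || df2 < 1) {
    out <- NULL
    attr(out, "reason") <- if (df1 < 1) "genotype aliased with cofactor"
                           else "no residual degrees of freedom"
    return(out)
  }
  list(idx = idx,
       Qr = qr.Q(qr_r)[, seq_len(qr_r$rank), drop = FALSE],
       Qf = qr.Q(qr_f)[, seq_len(qr_f$rank), drop = FALSE],
       df1 = df1, df2 = df2, n = nrow(Xf))
}

# F and p for each column of Y (crosses x B) at one precomputed design.
marker_F <- function(des, Y) {
  Ym <- Y[des$idx, , drop = FALSE]
  tot <- colSums(Ym^2)
  sse_r <- tot - colSums((crossprod(des$Qr, Ym))^2)
  sse_f <- tot - colSums((crossprod(des$Qf, Ym))^2)
  eps <- pmax(sse_r, 1) * 1e-12
  Fv <- ((sse_r - sse_f) / des$df1) / pmax(sse_f / des$df2, 0)
  Fv[sse_f <= eps & sse_r - sse_f > eps] <- Inf
  Fv[sse_r <= eps] <- 0
  p <- stats::pf(Fv, des$df1, des$df2, lower.tail = FALSE)
  p[Fv == 0] <- 1
  list(F = Fv, p = p)
}

#' Experiment-wise permutation threshold for step 1
#'
#' Cross-level ODH values are shuffled against the cross identities
#' `n_perm` times (the genotype structure stays fixed), the genotypic-group
#' model is recomputed at every testable marker, and the genome-wide
#' minimum nominal p-value is recorded per permutation. The threshold is
#' the empirical `alpha`-quantile of that minimum-p distribution (the
#' `floor(alpha * n_perm)`-th smallest value); a marker passes step 1 when
#' its observed nominal p-value does not exceed it.
#'
#' @param values named numeric vector of cross-level mean ODH.
#' @param groups_list list of [partition_by_locus()] results, one per
#'   marker.
#' @param config a [scan_config()]; `seed` makes the permutations (and so
#'   the threshold) deterministic.
#' @param comb optional named character vector: the founder-cluster pair
#'   combination of each cross, used as a model cofactor.
#' @return List with `threshold`, `min_p` (length `n_perm`) and
#'   `n_testable`.
#' @export
permutation_threshold <- function(values, groups_list, config, comb = NULL) {
  values <- values[!is.na(values)]
  designs <- lapply(groups_list, marker_design, values = values, comb = comb)
  designs <- designs[!vapply(designs, is.null, logical(1))]
  perm_min_p(designs, values, config)
}

# Shared permutation engine over precomputed marker designs.
perm_min_p <- function(designs, values, config) {
  if (!length(designs)) stop("no testable markers")
  n <- length(values)
  perm <- with_seed(config$seed,
    vapply(seq_len(config$n_perm), function(i) sample.int(n), integer(n)))
  Y <- matrix(values[as.vector(perm)], n, config$n_perm)
  minp <- rep(Inf, config$n_perm)
  for (des in designs) minp <- pmin(minp, marker_F(des, Y)$p)
  kth <- max(1L, floor(config$alpha * config$n_perm))
  list(threshold = sort(minp)[kth], min_p = minp,
       n_testable = length(designs))
}

# ---- step 2: Kolmogorov-Smirnov hetero-vs-homo contrast -------------------

ks_ecdf_diff <- function(het, hom) {
  xs <- sort(unique(c(het, hom)))
  Fh <- findInterval(xs, sort(het)) / length(het)
  Fo <- findInterval(xs, sort(hom)) / length(hom)
  list(d_adv = max(Fo - Fh), d_dis = max(Fh - Fo))
}

ks_p_asymptotic <- function(d, n1, n2, sided) {
  m <- n1 * n2 / (n1 + n2)
  if (d <= 0) return(1)
  if (sided == "greater") return(min(1, exp(-2 * m * d^2)))
  k <- seq_len(100)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * m * d^2))))
}

#' Kolmogorov-Smirnov contrast of a hetero group against the homozygotes
#'
#' Compares the empirical ODH distribution of one hetero-genotypic group
#' with that of the pooled homozygous group,
#' `D = sup_x [F_homo(x) - F_hetero(x)]` in the default one-sided
#' (`"greater"`) direction, which is large when the hetero group is
#' stochastically larger. The p-value uses the asymptotic two-sample law
#' (`exp(-2 m D^2)` one-sided, with `m = n n' / (n + n')`). The advantage
#' flag is `TRUE` only when the contrast is significant at `ks_alpha` and
#' the hetero group is the stochastically larger sample. ECDFs are
#' right-continuous; ties are allowed.
#'
#' @param het,hom numeric ODH values of the hetero group and the
#'   homozygous reference group.
#' @param ks_alpha per-contrast level (default 0.05).
#' @param sided `"greater"` (default) or `"two.sided"`.
#' @return List with `D`, `p`, `advantage`, `n_het`, `n_hom`.
#' @export
ks_hetero_vs_homo <- function(het, hom, ks_alpha = 0.05,
                              sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  het <- het[!is.na(het)]; hom <- hom[!is.na(hom)]
  if (!length(het) || !length(hom)) stop("empty sample in KS contrast")
  dd <- ks_ecdf_diff(het, hom)
  if (sided == "greater") {
    D <- max(dd$d_adv, 0)
    p <- ks_p_asymptotic(D, length(het), length(hom), "greater")
    adv <- p <= ks_alpha
  } else {
    D <- max(dd$d_adv, dd$d_dis)
    p <- ks_p_asymptotic(D, length(het), length(hom), "two.sided")
    adv <- p <= ks_alpha && dd$d_adv > dd$d_dis
  }
  list(D = D, p = p, advantage = adv,
       n_het = length(het), n_hom = length(hom))
}

# ---- population-structure adjustment --------------------------------------

#' Cluster-pair combination of each cross
#'
#' @param female,male parent id vectors.
#' @param clusters named character vector founder -> cluster label.
#' @return Character vector of unordered cluster-pair labels (`"A:B"`).
#' @export
cluster_combination <- function(female, male, clusters) {
  miss <- setdiff(unique(c(female, male)), names(clusters))
  if (length(miss))
    stop("founder(s) without a cluster label: ", paste(miss, collapse = ", "))
  cf <- clusters[female]; cm <- clusters[male]
  paste(pmin(cf, cm), pmax(cf, cm), sep = ":")
}

#' Adjust ODH values for founder genomic structure
#'
#' The effect of each cluster-pair combination is its mean ODH deviation
#' from the size-weighted overall mean (i.e. the grand mean of all
#' values); the adjusted value of a cross is its ODH minus the effect of
#' its combination. The weighted grand mean of the adjusted values equals
#' the original grand mean, and all between-combination variance is
#' removed.
#'
#' @param values numeric ODH values.
#' @param combination character vector of cluster-pair labels, aligned
#'   with `values`.
#' @return Numeric vector of adjusted values (names preserved).
#' @export
adjust_for_structure <- function(values, combination) {
  if (length(values) != length(combination))
    stop("values and combination must be aligned")
  ok <- !is.na(values)
  eff <- stats::ave(values[ok], combination[ok]) - mean(values[ok])
  out <- values
  out[ok] <- values[ok] - eff
  out
}

#' Genotypic-group test with a structure cofactor
#'
#' Two-factor additive fixed-effects model `Y_ij = mu + alpha_i + beta_k +
#' e_ij`: the cluster-pair cofactor is fitted first and the genotypic-group
#' effect is tested sequentially after it.
#'
#' @inheritParams glm_marker_test
#' @param combination named character vector: cluster-pair combination per
#'   cross.
#' @return As [glm_marker_test()]; `skipped` with reason
#'   `"genotype aliased with cofactor"` when the genotypic groups are
#'   nested in cofactor levels.
#' @export
glm_with_cofactor <- function(values, groups, combination) {
  lab <- group_labels(groups)
  lab <- lab[names(lab) %in% names(values)]
  y <- values[names(lab)]
  keep <- !is.na(y)
  y <- y[keep]; lab <- lab[keep]
  k <- length(unique(lab))
  if (k < 2)
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                n = length(y), k = k, skipped = TRUE,
                reason = "fewer than 2 eligible groups"))
  cf <- factor(combination[names(lab)])
  if (nlevels(droplevels(cf)) < 2)
    return(glm_marker_test(values, groups))
  g <- factor(lab)
  fit <- stats::lm(y ~ cf + g)
  an <- stats::anova(fit)
  row <- which(rownames(an) == "g")
  if (!length(row) || an[row, "Df"] < 1 || an["Residuals", "Df"] < 1)
    return(list(F = NA_real_, p = NA_real_, df1 = NA,
                df2 = an["Residuals", "Df"], n = length(y), k = k,
                skipped = TRUE, reason = "genotype aliased with cofactor"))
  list(F = unname(an[row, "F value"]), p = unname(an[row, "Pr(>F)"]),
       df1 = an[row, "Df"], df2 = an["Residuals", "Df"],
       n = length(y), k = k, skipped = FALSE, reason = "")
}

# ---- full scan -------------------------------------------------------------

subset_hybrid_geno <- function(proj, keys) {
  keys <- intersect(rownames(proj$a1), keys)
  structure(list(a1 = proj$a1[keys, , drop = FALSE],
                 a2 = proj$a2[keys, , drop = FALSE],
                 crosses = proj$crosses[match(keys, proj$crosses$key), ],
                 map = proj$map),
            class = "hybrid_geno")
}

scan_one_year <- function(y, proj, config, comb = NULL) {
  markers <- colnames(proj$a1)
  groups_list <- lapply(markers, function(m)
    partition_by_locus(proj, m, min_group = config$min_group,
                       split_homo = config$split_homo))
  names(groups_list) <- markers
  designs <- lapply(groups_list, marker_design, values = y, comb = comb)
  testable <- !vapply(designs, is.null, logical(1))
  if (!any(testable)) stop("no testable markers this year")
  Fv <- p <- rep(NA_real_, length(markers))
  for (i in which(testable)) {
    mf <- marker_F(designs[[i]], matrix(y[!is.na(y)], ncol = 1))
    Fv[i] <- mf$F; p[i] <- mf$p
  }
  reasons <- vapply(seq_along(designs), function(i)
    if (testable[i]) "" else attr(designs[[i]], "reason") %||% "untestable",
    character(1))
  pt <- perm_min_p(designs[testable], y[!is.na(y)], config)
  passed <- !is.na(p) & p <= pt$threshold
  mtab <- data.frame(marker = markers, F = Fv, p = p,
                     threshold = pt$threshold, passed = passed,
                     skipped = !testable, reason = reasons,
                     stringsAsFactors = FALSE)
  # step 2 only at markers that passed step 1
  yv <- if (is.null(comb)) y else {
    ok <- names(y)
    adjust_for_structure(y, comb[ok])
  }
  ks <- list()
  for (m in markers[passed]) {
    gr <- groups_list[[m]]
    homo_keys <- if (is.list(gr$homo)) unlist(gr$homo) else gr$homo
    hom <- yv[intersect(homo_keys, names(yv))]
    hom <- hom[!is.na(hom)]
    if (length(hom) < config$min_group) next
    alpha_m <- if (config$per_locus_bonferroni && length(gr$hetero))
      config$ks_alpha / length(gr$hetero) else config$ks_alpha
    for (pair in names(gr$hetero)) {
      het <- yv[intersect(gr$hetero[[pair]], names(yv))]
      het <- het[!is.na(het)]
      if (length(het) < config$min_group) next
      kk <- ks_hetero_vs_homo(het, hom, ks_alpha = alpha_m,
                              sided = config$ks_sided)
      ks[[length(ks) + 1L]] <- data.frame(
        marker = m, pair = pair, n_het = kk$n_het, n_hom = kk$n_hom,
        D = kk$D, p = kk$p, advantage = kk$advantage,
        stringsAsFactors = FALSE)
    }
  }
  ks <- if (length(ks)) do.call(rbind, ks) else
    data.frame(marker = character(0), pair = character(0),
               n_het = integer(0), n_hom = integer(0), D = numeric(0),
               p = numeric(0), advantage = logical(0))
  list(markers = mtab, ks = ks, threshold = pt$threshold,
       n_testable = pt$n_testable)
}

#' Two-step genome scan for heterotic trait loci
#'
#' For each year separately: (step 1) every marker's genotypic-group model
#' is tested against a permutation-based experiment-wise threshold;
#' (step 2) at passing markers, each hetero-genotypic group's ODH
#' distribution is contrasted with the pooled homozygous group by a
#' one-sided Kolmogorov-Smirnov test. A marker is called an HTL when at
#' least one hetero combination is significantly advantaged — by default
#' the *same* allele pair — in all scanned years. When founder cluster
#' labels are supplied, step 1 adds the cluster-pair combination as a
#' model cofactor and step 2 runs on structure-adjusted ODH values.
#'
#' @param geno a [founder_geno()] object.
#' @param design a [diallel_design()].
#' @param trait trait name to scan.
#' @param config a [scan_config()].
#' @param pheno phenotype data.frame; used (with `design`) to compute the
#'   ODH table when `odh` is not given.
#' @param odh optional precomputed [odh_table()] result.
#' @param clusters optional named character vector founder -> cluster;
#'   enables the structure-cofactor variant of both steps.
#' @return Object of class `htl_scan`: list with `trait`, `years`,
#'   `per_year` (per-year `markers` and `ks` tables and threshold),
#'   `calls` (named HTL calls), `call_stats` (per-year KS rows of the
#'   calls) and `config`.
#' @export
htl_scan <- function(geno, design, trait, config = scan_config(),
                     pheno = NULL, odh = NULL, clusters = NULL) {
  if (is.null(odh)) {
    if (is.null(pheno)) stop("supply either `pheno` or a precomputed `odh`")
    odh <- odh_table(pheno, design, trait)
  }
  odh <- odh[odh$trait == trait, , drop = FALSE]
  if (!nrow(odh)) stop("no ODH rows for trait ", trait)
  proj <- project_hybrid_genotypes(geno, design)
  if (is.null(clusters)) clusters <- geno$clusters
  years <- sort(unique(odh$year))
  per_year <- list()
  for (yr in years) {
    oy <- odh[odh$year == yr & odh$flag == "" & !odh$recip_diff &
                !is.na(odh$ODH), , drop = FALSE]
    y <- setNames(oy$ODH, oy$cross)
    common <- intersect(names(y), rownames(proj$a1))
    if (!length(common))
      stop("no crosses shared between the genotype projection and the ODH table")
    y <- y[common]
    proj_y <- subset_hybrid_geno(proj, common)
    comb <- NULL
    if (!is.null(clusters)) {
      cr <- proj_y$crosses
      comb <- setNames(cluster_combination(cr$female, cr$male, clusters),
                       cr$key)
    }
    cfg_y <- config
    cfg_y$seed <- config$seed + 7919L * (match(yr, years) - 1L)
    per_year[[as.character(yr)]] <- scan_one_year(y, proj_y, cfg_y, comb)
  }
  calls <- call_htls(per_year, map = geno$map, trait = trait,
                     require_both_years = config$require_both_years)
  structure(list(trait = trait, years = years, per_year = per_year,
                 calls = calls$calls, call_stats = calls$stats,
                 config = config),
            class = "htl_scan")
}

#' Intersect per-year advantages into named HTL calls
#'
#' An HTL is called when the same (marker, allele pair) is flagged as
#' advantaged in all required years (`require_both_years = FALSE` keeps
#' pairs advantaged in any year). Calls are named
#' `h<TRAIT><chromosome>.<ordinal>` with the ordinal assigned by map
#' position within each chromosome.
#'
#' @param per_year list of per-year scan results (each with a `ks` table).
#' @param map marker map data.frame (`marker`, `chromosome`, `position`)
#'   or `NULL`.
#' @param trait trait name used in the HTL names.
#' @param require_both_years require the same pair in every year.
#' @return List with `calls` (data.frame `name`, `marker`, `chromosome`,
#'   `position`, `pair`) and `stats` (the per-year KS rows of the calls,
#'   with a `year` column).
#' @export
call_htls <- function(per_year, map = NULL, trait = "TRAIT",
                      require_both_years = TRUE) {
  adv <- lapply(per_year, function(res) {
    k <- res$ks[res$ks$advantage, c("marker", "pair"), drop = FALSE]
    unique(paste(k$marker, k$pair, sep = "\r"))
  })
  hits <- if (require_both_years) Reduce(intersect, adv)
          else unique(unlist(adv))
  if (is.null(hits)) hits <- character(0)
  if (!length(hits)) {
    return(list(calls = data.frame(name = character(0), marker = character(0),
                                   chromosome = character(0),
                                   position = numeric(0),
                                   pair = character(0)),
                stats = data.frame()))
  }
  parts <- strsplit(hits, "\r", fixed = TRUE)
  calls <- data.frame(marker = vapply(parts, `[`, "", 1),
                      pair = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  if (!is.null(map)) {
    i <- match(calls$marker, map$marker)
    calls$chromosome <- as.character(map$chromosome[i])
    calls$position <- map$position[i]
  } else {
    calls$chromosome <- ""
    calls$position <- seq_len(nrow(calls))
  }
  ord <- order(calls$chromosome, calls$position, calls$marker, calls$pair)
  calls <- calls[ord, , drop = FALSE]
  # ordinal: markers (not pairs) numbered by position within chromosome
  mk <- unique(calls[, c("chromosome", "marker")])
  mk$ordinal <- stats::ave(seq_len(nrow(mk)), mk$chromosome,
                           FUN = seq_along)
  calls$ordinal <- mk$ordinal[match(paste(calls$chromosome, calls$marker),
                                    paste(mk$chromosome, mk$marker))]
  calls$name <- paste0("h", toupper(trait), calls$chromosome, ".",
                       calls$ordinal)
  calls <- calls[, c("name", "marker", "chromosome", "position", "pair")]
  rownames(calls) <- NULL
  stats_rows <- do.call(rbind, lapply(names(per_year), function(yr) {
    k <- per_year[[yr]]$ks
    k <- k[paste(k$marker, k$pair, sep = "\r") %in% hits, , drop = FALSE]
    if (nrow(k)) cbind(year = yr, k) else NULL
  }))
  list(calls = calls, stats = stats_rows %||% data.frame())
}

#' @export
print.htl_scan <- function(x, ...) {
  cat("HTL scan of trait", x$trait, "over year(s):",
      paste(x$years, collapse = ", "), "\n")
  for (yr in names(x$per_year)) {
    res <- x$per_year[[yr]]
    cat(sprintf("  year %s: %d/%d markers testable, threshold p <= %.4g, %d passed step 1\n",
                yr, res$n_testable, nrow(res$markers), res$threshold,
                sum(res$markers$passed)))
  }
  if (nrow(x$calls)) {
    cat("HTL calls:\n")
    print(x$calls)
  } else cat("No HTLs called.\n")
  invisible(x)
}
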