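#' Per-replicate overdominant heterosis (ODH)
#'
#' ODH measures how far a hybrid replicate falls outside the phenotypic
#' range of its two parents, relative to the bound it crosses:
#' \deqn{ODH_r = (F1_r - P2)/P2 \;\; if \; F1_r \ge P2;\quad
#'       (F1_r - P1)/P1 \;\; if \; F1_r \le P1;\quad 0 \; otherwise,}
#' where `P1 <= P2` are the low and high parental means. Positive values
#' indicate overdominance (above the high parent), negative values
#' underdominance (below the low parent), and replicates inside the
#' parental range contribute exactly 0. Traits must be positive-valued.
#'
#' @param f1 numeric vector of hybrid replicate values.
#' @param p_low,p_high low and high parental means (recycled).
#' @return Numeric vector of per-replicate ODH values; `NA` where a parent
#'   mean is non-positive (flagged with a warning).
#' @export
odh_replicate <- function(f1, p_low, p_high) {
  if (any(p_low > p_high, na.rm = TRUE))
    stop("p_low must not exceed p_high")
  bad <- !is.na(p_low) & !is.na(p_high) & (p_low <= 0 | p_high <= 0)
  if (any(bad))
    warning("non-positive parent mean(s): ODH undefined, returning NA")
  out <- ifelse(f1 >= p_high, (f1 - p_high) / p_high,
         ifelse(f1 <= p_low, (f1 - p_low) / p_low, 0))
  out[bad] <- NA_real_
  out
}

#' Parental phenotype bounds for a cross
#'
#' Low (`P1`) and high (`P2`) parental means for a trait in one year, each
#' computed from that parent's replicates in the same year only.
#'
#' @param pheno phenotype data.frame (see [read_phenotypes()]): columns
#'   `entry`, `year`, `replicate` and one column per trait.
#' @param female,male founder ids.
#' @param trait trait column name.
#' @param year year label.
#' @return List with `P1`, `P2`, `n1`, `n2` (replicate counts of the low
#'   and high parent) and `ok`; when a parent has no replicates, `ok` is
#'   `FALSE` and the bounds are `NA`.
#' @export
parent_bounds <- function(pheno, female, male, trait, year) {
  vf <- pheno[[trait]][pheno$entry == female & pheno$year == year]
  vm <- pheno[[trait]][pheno$entry == male & pheno$year == year]
  vf <- vf[!is.na(vf)]; vm <- vm[!is.na(vm)]
  if (!length(vf) || !length(vm))
    return(list(P1 = NA_real_, P2 = NA_real_, n1 = length(vf),
                n2 = length(vm), ok = FALSE,
                reason = "parent unphenotyped"))
  mf <- mean(vf); mm <- mean(vm)
  list(P1 = min(mf, mm), P2 = max(mf, mm),
       n1 = if (mf <= mm) length(vf) else length(vm),
       n2 = if (mf <= mm) length(vm) else length(vf),
       ok = TRUE, reason = "")
}

#' Mean ODH of one cross
#'
#' Arithmetic mean of [odh_replicate()] over the R hybrid replicates of an
#' unordered cross (reciprocal replicates pooled) in one year.
#'
#' @inheritParams parent_bounds
#' @param design a [diallel_design()].
#' @param female,male parent ids of the cross (order-free).
#' @return List with `ODH`, `R` (replicate count) and `ok`; no value when
#'   there are no hybrid replicates or the parental bounds are unusable.
#' @export
odh_cross <- function(pheno, design, female, male, trait, year) {
  key <- cross_key(female, male)
  ids <- design$cross_id[design$key == key & design$year == year]
  f1 <- pheno[[trait]][pheno$entry %in% ids & pheno$year == year]
  f1 <- f1[!is.na(f1)]
  pb <- parent_bounds(pheno, female, male, trait, year)
  if (!length(f1) || !pb$ok || pb$P1 <= 0)
    return(list(ODH = NA_real_, R = length(f1), ok = FALSE))
  list(ODH = mean(odh_replicate(f1, pb$P1, pb$P2)), R = length(f1), ok = TRUE)
}

#' Mid-parent and best-parent heterosis of one cross
#'
#' `MPH = (mean F1 - MP)/MP` with `MP = (P1+P2)/2`;
#' `BPH = (mean F1 - P2)/P2` with `P2` the better parent.
#'
#' @inheritParams odh_cross
#' @return List with `MPH`, `BPH`, `ok`.
#' @export
mph_bph <- function(pheno, design, female, male, trait, year) {
  key <- cross_key(female, male)
  ids <- design$cross_id[design$key == key & design$year == year]
  f1 <- pheno[[trait]][pheno$entry %in% ids & pheno$year == year]
  f1 <- f1[!is.na(f1)]
  pb <- parent_bounds(pheno, female, male, trait, year)
  if (!length(f1) || !pb$ok || pb$P1 <= 0)
    return(list(MPH = NA_real_, BPH = NA_real_, ok = FALSE))
  mp <- (pb$P1 + pb$P2) / 2
  list(MPH = (mean(f1) - mp) / mp, BPH = (mean(f1) - pb$P2) / pb$P2, ok = TRUE)
}

#' Seed number derived from panicle and seed weight
#'
#' `SN = (DPW / SDW) * 50`, with `DPW` the dry panicle weight (g) and
#' `SDW` the weight (g) of a 50-grain sample.
#'
#' @param dpw,sdw numeric vectors (recycled).
#' @return Seed number estimate; `NA` (with a warning) where `SDW <= 0`.
#' @export
derive_seed_number <- function(dpw, sdw) {
  bad <- !is.na(sdw) & sdw <= 0
  if (any(bad)) warning("non-positive SDW: seed number undefined, returning NA")
  out <- dpw / sdw * 50
  out[bad] <- NA_real_
  out
}

#' Reciprocal-cross difference test
#'
#' Welch two-sample t-test between the replicate values of a cross and its
#' reciprocal, used to check whether maternal/imprinting effects matter
#' before pooling reciprocals. Requires at least 3 replicates in each
#' direction; the verdict is `"different"` when `p <= alpha`.
#'
#' @param x,y numeric replicate values of the two directions.
#' @param alpha significance level (default 0.01).
#' @return List with `p`, `verdict` in
#'   `c("different", "not different", "untestable")`.
#' @export
reciprocal_test <- function(x, y, alpha = 0.01) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    return(list(p = NA_real_, verdict = "untestable"))
  p <- tryCatch(stats::t.test(x, y)$p.value,
                error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  list(p = p, verdict = if (p <= alpha) "different" else "not different")
}

#' Per-cross heterosis table
#'
#' Computes mean ODH, MPH and BPH for every unordered cross, trait and
#' year. Reciprocal replicates of the same parent pair are pooled; when
#' both directions have >= 3 replicates they are first compared with
#' [reciprocal_test()] and crosses whose reciprocals differ at
#' `reciprocal_alpha` are flagged (`recip_diff`) so the scan can exclude
#' them. Crosses with a missing or non-positive parental mean are flagged
#' in `flag` and carry `NA` heterosis values.
#'
#' @param pheno phenotype data.frame (`entry`, `year`, `replicate`,
#'   trait columns).
#' @param design a [diallel_design()].
#' @param traits character vector of trait column names.
#' @param reciprocal_alpha level of the reciprocal check (default 0.01).
#' @param pool_reciprocals if `FALSE`, reciprocal directions are still
#'   pooled for output rows but no reciprocal test is run.
#' @return data.frame with columns `cross` (unordered key), `female`,
#'   `male`, `trait`, `year`, `R`, `ODH`, `MPH`, `BPH`, `recip_diff`,
#'   `flag`.
#' @export
odh_table <- function(pheno, design, traits, reciprocal_alpha = 0.01,
                      pool_reciprocals = TRUE) {
  design <- as.data.frame(design)
  if (is.null(design$key)) design$key <- cross_key(design$female, design$male)
  pheno <- as.data.frame(pheno)
  missing_traits <- setdiff(traits, names(pheno))
  if (length(missing_traits))
    stop("trait column(s) not in phenotype table: ",
         paste(missing_traits, collapse = ", "))
  n_guess <- length(unique(design$key)) * length(unique(design$year)) *
    length(traits)
  col_cross <- col_female <- col_male <- col_trait <- col_year <-
    col_flag <- character(n_guess)
  col_R <- integer(n_guess)
  col_odh <- col_mph <- col_bph <- numeric(n_guess)
  col_recip <- logical(n_guess)
  nrec <- 0L
  for (trait in traits) {
    for (year in unique(design$year)) {
      py <- pheno[pheno$year == year, , drop = FALSE]
      dyr <- design[design$year == year, , drop = FALSE]
      hy <- py[py$entry %in% dyr$cross_id, , drop = FALSE]
      # parental means this year
      par <- py[!(py$entry %in% design$cross_id), , drop = FALSE]
      pm <- tapply(par[[trait]], par$entry, mean, na.rm = TRUE)
      hy_key <- dyr$key[match(hy$entry, dyr$cross_id)]
      hy_split <- split(seq_len(nrow(hy)), hy_key)
      dk <- unique(data.frame(key = dyr$key,
                              female = pmin(dyr$female, dyr$male),
                              male = pmax(dyr$female, dyr$male),
                              stringsAsFactors = FALSE))
      for (i in seq_len(nrow(dk))) {
        key <- dk$key[i]
        rows <- hy[hy_split[[key]], , drop = FALSE]
        f1 <- rows[[trait]][!is.na(rows[[trait]])]
        recip_diff <- FALSE
        ids <- unique(rows$entry)
        if (pool_reciprocals && length(ids) == 2) {
          x <- rows[[trait]][rows$entry == ids[1]]
          y <- rows[[trait]][rows$entry == ids[2]]
          rt <- reciprocal_test(x, y, alpha = reciprocal_alpha)
          recip_diff <- identical(rt$verdict, "different")
        }
        p1 <- unname(pm[dk$female[i]]); p2 <- unname(pm[dk$male[i]])
        flag <- ""
        odh <- mph <- bph <- NA_real_
        if (is.na(p1) || is.nan(p1) || is.na(p2) || is.nan(p2)) {
          flag <- "parent unphenotyped"
        } else if (min(p1, p2) <= 0) {
          flag <- "non-positive parent mean"
        } else if (!length(f1)) {
          next  # no hybrid replicates: no row emitted
        } else {
          plo <- min(p1, p2); phi <- max(p1, p2)
          odh <- mean(odh_replicate(f1, plo, phi))
          mp <- (plo + phi) / 2
          mph <- (mean(f1) - mp) / mp
          bph <- (mean(f1) - phi) / phi
        }
        nrec <- nrec + 1L
        if (nrec > length(col_cross)) {  # grow if estimate was low
          grow <- function(v) c(v, v)
          col_cross <- grow(col_cross); col_female <- grow(col_female)
          col_male <- grow(col_male); col_trait <- grow(col_trait)
          col_year <- grow(col_year); col_flag <- grow(col_flag)
          col_R <- grow(col_R); col_odh <- grow(col_odh)
          col_mph <- grow(col_mph); col_bph <- grow(col_bph)
          col_recip <- grow(col_recip)
        }
        col_cross[nrec] <- key; col_female[nrec] <- dk$female[i]
        col_male[nrec] <- dk$male[i]; col_trait[nrec] <- trait
        col_year[nrec] <- as.character(year); col_R[nrec] <- length(f1)
        col_odh[nrec] <- odh; col_mph[nrec] <- mph; col_bph[nrec] <- bph
        col_recip[nrec] <- recip_diff; col_flag[nrec] <- flag
      }
    }
  }
  idx <- seq_len(nrec)
  data.frame(cross = col_cross[idx], female = col_female[idx],
             male = col_male[idx], trait = col_trait[idx],
             year = col_year[idx], R = col_R[idx], ODH = col_odh[idx],
             MPH = col_mph[idx], BPH = col_bph[idx],
             recip_diff = col_recip[idx], flag = col_flag[idx],
             stringsAsFactors = FALSE)
}
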