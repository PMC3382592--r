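#' Simulation configuration for a synthetic diallel study
#'
#' Defaults emulate the structure of a two-year sorghum diallel field
#' study: 19 homozygous founders genotyped at 85 multi-allelic SSR loci
#' (5-8 alleles each, every locus with at least two alleles carried by
#' three or more founders), four founder clusters, a near-complete
#' half-diallel with some reciprocal crosses and ~10% missing hybrids,
#' 7/4 hybrid and 14/10 parent replicates in the two years, and a
#' positive-valued grain-yield-like trait (baseline 60 g).
#'
#' @param n_founders number of founder lines (>= 6; default 19).
#' @param n_markers number of markers (default 85).
#' @param alleles_range integer range of allele counts per locus
#'   (default `c(5, 8)`).
#' @param n_clusters founder clusters (default 4).
#' @param n_chromosomes chromosomes the markers are spread over
#'   (default 10).
#' @param planted_htls `NULL`, or a data.frame with columns `marker`
#'   (name, column index, or `NA` to auto-choose loci spread across
#'   chromosomes), optional `allele1`/`allele2`, and `d` (trait shift of
#'   carriers of the pair, as a fraction of the baseline; the carriers'
#'   mean ODH then exceeds the homozygotes' by about `d`). When the
#'   alleles are left unspecified, [simulate_founders()] lays out a
#'   balanced configuration at each planted locus — two alleles carried
#'   by `planted_carriers` founders, carrier sets disjoint across the
#'   planted loci — emulating a founder panel selected for balanced
#'   allele frequencies.
#' @param planted_carriers integer length-2: founder carrier counts of
#'   the two alleles of a designed planted pair (default `c(3, 3)`, a
#'   hetero group of about nine crosses).
#' @param baseline trait baseline (g).
#' @param gca_sd SD of the founder general-combining-ability effect (g).
#' @param sca_sd SD of the cross-by-year specific deviation (g): the
#'   non-additive background (specific combining ability and
#'   genotype-by-year interaction) that every hybrid carries on top of
#'   its parents' general effects. This is what makes weak locus effects
#'   year-inconsistent in real trials.
#' @param cluster_effect_sd SD of the cluster-pair effect on hybrids (g).
#' @param year_effect_sd SD of the year effect (g).
#' @param residual_sd replicate-level residual SD (g).
#' @param reps_hybrid,reps_parent integer replicates per hybrid / parent,
#'   recycled over years (defaults `c(7, 4)` and `c(14, 10)`).
#' @param missing_cross_rate fraction of crosses missing per year
#'   (default 0.1).
#' @param reciprocal_rate fraction of present crosses also grown as the
#'   reciprocal (default 0.15).
#' @param years number of years (default 2).
#' @param trait trait column name (default `"DPW"`).
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_founders = 19, n_markers = 85,
                       alleles_range = c(5, 8), n_clusters = 4,
                       n_chromosomes = 10, planted_htls = NULL,
                       planted_carriers = c(3, 3),
                       baseline = 60, gca_sd = 2, sca_sd = 6,
                       cluster_effect_sd = 1,
                       year_effect_sd = 2, residual_sd = 6,
                       reps_hybrid = c(7, 4), reps_parent = c(14, 10),
                       missing_cross_rate = 0.1, reciprocal_rate = 0.15,
                       years = 2, trait = "DPW", seed = 1) {
  stopifnot(n_markers >= 1, n_clusters >= 1, years >= 1,
            missing_cross_rate >= 0, missing_cross_rate < 1,
            reciprocal_rate >= 0, reciprocal_rate <= 1,
            residual_sd > 0, baseline > 0)
  if (n_founders < 6)
    stop("n_founders must be >= 6: with fewer founders no locus can have ",
         "two alleles each carried by three founders")
  structure(as.list(environment()), class = "sim_config")
}

# Force >=2 alleles with >=3 carriers by reassigning the fewest founders.
enforce_shared_alleles <- function(calls) {
  tab <- sort(table(calls), decreasing = TRUE)
  top2 <- as.integer(names(tab))[1:2]
  if (is.na(top2[2])) top2[2] <- top2[1] + 2L  # monomorphic draw
  for (a in top2) {
    while (sum(calls == a) < 3) {
      other <- which(!(calls %in% top2))
      if (!length(other)) other <- which(calls != a)
      calls[other[1]] <- a
    }
  }
  calls
}

#' Simulate founder genotypes and cluster structure
#'
#' Each locus draws its allele count from `alleles_range` and
#' cluster-correlated allele frequencies (a shared base frequency vector
#' perturbed per cluster), then samples one allele per founder according
#' to its cluster. Draws are retried, and finally minimally repaired, so
#' every locus carries at least two alleles shared by three or more
#' founders — the condition that makes hetero- and homo-genotypic groups
#' comparable. Planted loci with unspecified allele pairs receive a
#' balanced designed configuration (see [sim_config()]); the realized
#' pairs are recorded in the returned object's `planted` element.
#'
#' @param cfg a [sim_config()].
#' @return List with `geno` (a [founder_geno()] with marker map and
#'   clusters attached) and `clusters` (named vector founder -> cluster).
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    founders <- sprintf("FL%02d", seq_len(cfg$n_founders))
    markers <- sprintf("M%03d", seq_len(cfg$n_markers))
    clusters <- setNames(
      sample(rep_len(LETTERS[seq_len(cfg$n_clusters)], cfg$n_founders)),
      founders)
    calls <- matrix(NA_integer_, cfg$n_founders, cfg$n_markers,
                    dimnames = list(founders, markers))
    for (j in seq_len(cfg$n_markers)) {
      n_all <- sample(seq(cfg$alleles_range[1], cfg$alleles_range[2]), 1)
      alleles <- sample(120:260, 1) + 2L * (seq_len(n_all) - 1L)
      base_w <- rexp(n_all) + 0.3
      cl_w <- lapply(seq_len(cfg$n_clusters), function(c)
        base_w * exp(rnorm(n_all, 0, 0.8)))
      ok <- FALSE
      for (try in 1:100) {
        cl_idx <- match(clusters, LETTERS)
        col <- vapply(seq_len(cfg$n_founders), function(i)
          sample(alleles, 1, prob = cl_w[[cl_idx[i]]]), integer(1))
        tab <- sort(table(col), decreasing = TRUE)
        if (length(tab) >= 2 && tab[2] >= 3) { ok <- TRUE; break }
      }
      if (!ok) col <- enforce_shared_alleles(col)
      calls[, j] <- col
    }
    chrom <- rep_len(seq_len(cfg$n_chromosomes), cfg$n_markers)
    pos <- stats::ave(seq_len(cfg$n_markers), chrom, FUN = seq_along) * 1e6
    map <- data.frame(marker = markers, chromosome = chrom, position = pos,
                      stringsAsFactors = FALSE)
    geno <- founder_geno(calls, map = map, clusters = clusters)
    des <- design_planted_loci(geno$calls, geno$map, cfg)
    if (!is.null(des)) {
      geno$calls <- des$calls
      geno$planted <- des$planted
    }
    list(geno = geno, clusters = clusters)
  })
}

# Lay out a balanced allelic configuration at each planted locus whose
# allele pair was left unspecified: two alleles carried by three founders
# each (a testable hetero group of about nine crosses), with the
# carrier founder sets disjoint across planted loci (as far as the
# founder count allows). This emulates a founder
# panel chosen to balance allele frequencies in the mapped loci, and
# keeps each planted hetero-genotypic group specific to its own locus.
# Returns NULL when nothing is planted or the pairs are user-fixed,
# otherwise list(calls = updated matrix, planted = realized pair table).
design_planted_loci <- function(calls, map, cfg) {
  pl <- cfg$planted_htls
  if (is.null(pl) || !nrow(as.data.frame(pl))) return(NULL)
  pl <- as.data.frame(pl)
  markers <- colnames(calls)
  if (is.numeric(pl$marker) && !anyNA(pl$marker))
    pl$marker <- markers[pl$marker]
  if (anyNA(pl$marker)) {
    # spread auto-chosen loci across chromosomes
    spread <- markers[!duplicated(map$chromosome)]
    free <- setdiff(c(spread, markers), pl$marker)
    pl$marker[is.na(pl$marker)] <- free[seq_len(sum(is.na(pl$marker)))]
  }
  explicit <- !is.null(pl$allele1) && !is.null(pl$allele2) &&
    !anyNA(pl$allele1) && !anyNA(pl$allele2)
  if (explicit) return(NULL)   # user fixed the pairs: leave calls alone
  founders <- rownames(calls)
  nc <- cfg$planted_carriers
  need <- sum(nc)
  if (need > length(founders))
    stop("planted_carriers too large for the founder count")
  pool <- sample(founders)
  out <- data.frame()
  for (i in seq_len(nrow(pl))) {
    m <- pl$marker[i]
    if (length(pool) < need)  # refill, reusing assigned founders last
      pool <- c(pool, sample(setdiff(founders, pool)))
    aset <- pool[seq_len(nc[1])]
    bset <- pool[nc[1] + seq_len(nc[2])]
    pool <- pool[-seq_len(need)]
    col <- calls[, m]
    al <- sort(unique(col[!is.na(col)]))
    a <- al[1]; b <- al[2]
    others <- setdiff(al, c(a, b))
    if (!length(others)) others <- max(al) + c(2L, 4L)
    rest <- setdiff(founders, c(aset, bset))
    col[aset] <- a; col[bset] <- b
    col[rest] <- sample(others, length(rest), replace = TRUE)
    calls[, m] <- col
    out <- rbind(out, data.frame(marker = m, allele1 = min(a, b),
                                 allele2 = max(a, b),
                                 stringsAsFactors = FALSE))
  }
  list(calls = calls, planted = out)
}

# Smallest testable hetero group at a marker: the product of the carrier
# counts of the two least common alleles still carried by >= 3 founders.
min_pair_size <- function(calls) {
  tab <- sort(table(calls))
  elig <- tab[tab >= 3]
  if (length(elig) < 2) return(Inf)
  as.integer(elig[1]) * as.integer(elig[2])
}

resolve_planted <- function(planted, geno) {
  if (is.null(planted) || !nrow(as.data.frame(planted)))
    return(data.frame(marker = character(0), allele1 = integer(0),
                      allele2 = integer(0), d = numeric(0)))
  planted <- as.data.frame(planted)
  if (is.numeric(planted$marker) && !anyNA(planted$marker))
    planted$marker <- colnames(geno$calls)[planted$marker]
  if (is.null(planted$allele1)) planted$allele1 <- NA_integer_
  if (is.null(planted$allele2)) planted$allele2 <- NA_integer_
  if (!is.null(geno$planted)) {
    # the founder simulator laid out balanced pairs for these loci
    if (anyNA(planted$marker))
      planted$marker[is.na(planted$marker)] <-
        setdiff(geno$planted$marker,
                planted$marker)[seq_len(sum(is.na(planted$marker)))]
    i <- match(planted$marker, geno$planted$marker)
    take <- !is.na(i) & is.na(planted$allele1)
    planted$allele1[take] <- geno$planted$allele1[i[take]]
    planted$allele2[take] <- geno$planted$allele2[i[take]]
  }
  if (anyNA(planted$marker)) {
    # choose loci whose least common testable allele pair gives the most
    # specific hetero group, greedily spreading over chromosomes
    sizes <- apply(geno$calls, 2, min_pair_size)
    cand <- setdiff(names(sort(sizes)), planted$marker)
    chrom <- if (!is.null(geno$map))
      setNames(geno$map$chromosome, geno$map$marker)[cand]
    else setNames(seq_along(cand), cand)
    chosen <- character(0)
    for (i in seq_len(sum(is.na(planted$marker)))) {
      pool <- setdiff(cand, chosen)
      fresh <- pool[!(chrom[pool] %in% chrom[chosen])]
      chosen <- c(chosen, if (length(fresh)) fresh[1] else pool[1])
    }
    planted$marker[is.na(planted$marker)] <- chosen
  }
  bad <- setdiff(planted$marker, colnames(geno$calls))
  if (length(bad)) stop("planted marker(s) not simulated: ",
                        paste(bad, collapse = ", "))
  if (is.null(planted$allele1)) planted$allele1 <- NA_integer_
  if (is.null(planted$allele2)) planted$allele2 <- NA_integer_
  for (i in seq_len(nrow(planted))) {
    if (is.na(planted$allele1[i]) || is.na(planted$allele2[i])) {
      # smallest testable pair: alleles with >= 3 carrier founders, taking
      # the least common such alleles so the hetero group stays specific
      tab <- table(geno$calls[, planted$marker[i]])
      elig <- tab[tab >= 3]
      if (length(elig) < 2) elig <- sort(tab, decreasing = TRUE)[1:2]
      elig <- elig[order(elig, as.integer(names(elig)))]
      planted$allele1[i] <- as.integer(names(elig))[1]
      planted$allele2[i] <- as.integer(names(elig))[2]
    }
  }
  lo <- pmin(planted$allele1, planted$allele2)
  hi <- pmax(planted$allele1, planted$allele2)
  planted$allele1 <- lo; planted$allele2 <- hi
  planted$pair <- paste(lo, hi, sep = "/")
  planted
}

positive_noise <- function(n, mean_part, sd) {
  val <- mean_part + rnorm(n, 0, sd)
  for (i in 1:50) {
    bad <- val <= 0
    if (!any(bad)) break
    val[bad] <- mean_part[bad] + rnorm(sum(bad), 0, sd)
  }
  val[val <= 0] <- .Machine$double.eps
  val
}

#' Simulate replicated diallel phenotypes with planted overdominance
#'
#' Founder replicates are `baseline + 2 GCA_f + year + noise`; hybrid
#' replicates are `baseline + GCA_x + GCA_y + cluster-pair effect + year +
#' SCA_xy(year) + sum of planted shifts + noise`, where the specific
#' deviation `SCA_xy(year)` is drawn per cross and year (shared by
#' reciprocals) and a planted heterotic locus adds
#' `d * baseline` to every hybrid whose projected allele pair at that
#' marker equals the planted pair (a multiplicative shift, so the
#' carriers' mean ODH exceeds the homozygotes' by about `d`). Values are
#' kept positive by resampling the noise. Per year, a fraction of crosses
#' is dropped and a fraction is duplicated as reciprocals.
#'
#' @param geno a [founder_geno()] from [simulate_founders()].
#' @param clusters named founder -> cluster vector.
#' @param cfg a [sim_config()].
#' @return List with `pheno` (entry/year/replicate/trait data.frame),
#'   `design` (a [diallel_design()]) and `truth` (list: `planted`
#'   data.frame with resolved pairs and shifts, plus the effect draws).
#' @export
simulate_diallel_phenotypes <- function(geno, clusters, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  planted <- resolve_planted(cfg$planted_htls, geno)
  founders <- rownames(geno$calls)
  with_seed(cfg$seed + 1L, {
    gca <- setNames(rnorm(length(founders), 0, cfg$gca_sd), founders)
    cl <- sort(unique(clusters))
    cl_pairs <- outer(cl, cl, function(a, b)
      paste(pmin(a, b), pmax(a, b), sep = ":"))
    cl_pairs <- sort(unique(as.vector(cl_pairs)))
    cl_eff <- setNames(rnorm(length(cl_pairs), 0, cfg$cluster_effect_sd),
                       cl_pairs)
    yr_eff <- rnorm(cfg$years, 0, cfg$year_effect_sd)
    all_pairs <- half_diallel(founders)
    design <- list(); pheno <- list()
    for (yr in seq_len(cfg$years)) {
      keep <- runif(nrow(all_pairs)) >= cfg$missing_cross_rate
      dy <- all_pairs[keep, c("cross_id", "female", "male"), drop = FALSE]
      recip <- runif(nrow(dy)) < cfg$reciprocal_rate
      if (any(recip)) {
        rv <- dy[recip, , drop = FALSE]
        rv <- data.frame(cross_id = paste(rv$male, rv$female, sep = "x"),
                         female = rv$male, male = rv$female,
                         stringsAsFactors = FALSE)
        dy <- rbind(dy, rv)
      }
      dy$year <- as.character(yr)
      design[[yr]] <- dy
      rp <- rep_len(cfg$reps_parent, cfg$years)[yr]
      rh <- rep_len(cfg$reps_hybrid, cfg$years)[yr]
      # parent replicates
      pe <- rep(founders, each = rp)
      pmean <- cfg$baseline + 2 * gca[pe] + yr_eff[yr]
      pv <- positive_noise(length(pe), pmean, cfg$residual_sd)
      pheno[[length(pheno) + 1L]] <- data.frame(
        entry = pe, year = as.character(yr),
        replicate = rep(seq_len(rp), times = length(founders)),
        value = pv, stringsAsFactors = FALSE)
      # hybrid replicates
      keys <- cross_key(dy$female, dy$male)
      sca <- setNames(rnorm(length(unique(keys)), 0, cfg$sca_sd),
                      unique(keys))
      he <- rep(dy$cross_id, each = rh)
      hf <- rep(dy$female, each = rh); hm <- rep(dy$male, each = rh)
      hk <- rep(keys, each = rh)
      comb <- cluster_combination(hf, hm, clusters)
      shift <- numeric(length(he))
      if (nrow(planted)) {
        for (i in seq_len(nrow(planted))) {
          g1 <- geno$calls[hf, planted$marker[i]]
          g2 <- geno$calls[hm, planted$marker[i]]
          carries <- !is.na(g1) & !is.na(g2) &
            pmin(g1, g2) == planted$allele1[i] &
            pmax(g1, g2) == planted$allele2[i]
          shift <- shift + ifelse(carries, planted$d[i] * cfg$baseline, 0)
        }
      }
      hmean <- cfg$baseline + gca[hf] + gca[hm] + cl_eff[comb] +
        yr_eff[yr] + sca[hk] + shift
      hv <- positive_noise(length(he), hmean, cfg$residual_sd)
      pheno[[length(pheno) + 1L]] <- data.frame(
        entry = he, year = as.character(yr),
        replicate = rep(seq_len(rh), times = nrow(dy)),
        value = hv, stringsAsFactors = FALSE)
    }
    design <- diallel_design(do.call(rbind, design))
    pheno <- do.call(rbind, pheno)
    names(pheno)[names(pheno) == "value"] <- cfg$trait
    rownames(pheno) <- NULL
    list(pheno = pheno, design = design,
         truth = list(planted = planted, gca = gca, cluster_effects = cl_eff,
                      year_effects = yr_eff))
  })
}

#' Simulate a whole diallel study in one call
#'
#' Convenience wrapper: [simulate_founders()] followed by
#' [simulate_diallel_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @return List with `geno`, `clusters`, `pheno`, `design`, `truth`.
#' @export
simulate_diallel <- function(cfg = sim_config()) {
  fg <- simulate_founders(cfg)
  ph <- simulate_diallel_phenotypes(fg$geno, fg$clusters, cfg)
  c(fg, ph)
}

#' Simulate an F2 population segregating at one overdominant locus
#'
#' Genotypes segregate 1:2:1; heterozygotes carry a multiplicative trait
#' shift. Traits are positive.
#'
#' @param allele1,allele2 the two parental alleles (must differ).
#' @param shift relative heterozygote advantage (e.g. 0.21 for +21%).
#' @param n_plants number of F2 plants (default 100).
#' @param baseline,residual_sd trait baseline and replicate SD.
#' @param seed RNG seed.
#' @return data.frame with columns `plant`, `genotype` (`"a1/a1"`,
#'   `"a1/a2"`, `"a2/a2"`), `value`.
#' @export
simulate_f2 <- function(allele1, allele2, shift = 0.21, n_plants = 100,
                        baseline = 60, residual_sd = 6, seed = 1) {
  if (allele1 == allele2)
    stop("parents are monomorphic at the focal marker")
  lo <- min(allele1, allele2); hi <- max(allele1, allele2)
  geno_levels <- c(paste0(lo, "/", lo), paste0(lo, "/", hi),
                   paste0(hi, "/", hi))
  with_seed(seed, {
    g <- sample(geno_levels, n_plants, replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
    mean_part <- baseline * (1 + shift * (g == geno_levels[2]))
    val <- positive_noise(n_plants, mean_part, residual_sd)
    data.frame(plant = sprintf("F2_%03d", seq_len(n_plants)),
               genotype = g, value = val, stringsAsFactors = FALSE)
  })
}

#' Simulate cross-years with planted P/N variance fractions
#'
#' Generates `n` cross-year heterosis observations from three independent
#' two-state (P/N) loci with planted main-effect variance fractions (of
#' the total non-year variance), an optional planted interaction between
#' the first two loci, a small year effect and Gaussian residual, using
#' centered Bernoulli codings so that the planted fractions are the
#' population R2 contributions of the loci.
#'
#' @param fractions numeric length-3 main-effect variance fractions
#'   (default `c(0.12, 0.07, 0.04)`).
#' @param interaction planted interaction variance fraction between loci
#'   1 and 2 (default 0).
#' @param n number of cross-year observations (default 280).
#' @param years number of year levels (default 2).
#' @param prevalence probability of the `P` state per locus (default 0.3).
#' @param year_sd SD of the year effect (default 0.1, on a unit total
#'   variance scale).
#' @param seed RNG seed.
#' @return List with `data` (data.frame `y`, `year`, `A`, `B`, `C`) and
#'   `truth` (the planted fractions).
#' @export
simulate_epistasis <- function(fractions = c(0.12, 0.07, 0.04),
                               interaction = 0, n = 280, years = 2,
                               prevalence = 0.3, year_sd = 0.1, seed = 1) {
  stopifnot(length(fractions) == 3, sum(fractions) + interaction < 1)
  with_seed(seed, {
    p <- prevalence
    x <- matrix(stats::runif(n * 3) < p, n, 3)
    z <- sweep(x, 2, p)                      # centered codings
    beta <- sqrt(fractions / (p * (1 - p)))
    bint <- sqrt(interaction / (p * (1 - p))^2)
    yr <- factor(rep_len(seq_len(years), n))
    yr_eff <- rnorm(years, 0, year_sd)
    res_sd <- sqrt(1 - sum(fractions) - interaction)
    y <- as.vector(z %*% beta) + bint * z[, 1] * z[, 2] +
      yr_eff[as.integer(yr)] + rnorm(n, 0, res_sd)
    lab <- function(v) factor(ifelse(v, "P", "N"), levels = c("P", "N"))
    list(data = data.frame(y = y, year = yr, A = lab(x[, 1]),
                           B = lab(x[, 2]), C = lab(x[, 3])),
         truth = list(fractions = fractions, interaction = interaction))
  })
}
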