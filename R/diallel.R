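#' Founder genotype matrix
#'
#' Container for single allele calls of homozygous founder lines at
#' multi-allelic (e.g. SSR) markers. Because founders are fully inbred,
#' one integer allele code (typically a fragment size in bp) per
#' (founder, marker) cell suffices; `NA` marks a missing call.
#'
#' @param calls integer matrix, founders in rows (rownames = founder ids),
#'   markers in columns (colnames = marker names).
#' @param map optional data.frame with columns `marker`, `chromosome`,
#'   `position` (physical bp or cM; only the order is used, for HTL naming).
#' @param clusters optional named character vector assigning each founder a
#'   population-structure cluster label (e.g. from an external Bayesian
#'   clustering run).
#' @return An object of class `founder_geno`: a list with elements `calls`,
#'   `map`, `clusters`.
#' @export
founder_geno <- function(calls, map = NULL, clusters = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` must have founder rownames and marker colnames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate founder ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker names")
  storage.mode(calls) <- "integer"
  if (!is.null(map)) {
    map <- as.data.frame(map)
    need <- c("marker", "chromosome", "position")
    if (!all(need %in% names(map)))
      stop("`map` must have columns marker, chromosome, position")
    if (any(!is.na(map$position) & map$position < 0))
      stop("marker positions must be non-negative")
    map <- map[match(colnames(calls), map$marker), , drop = FALSE]
  }
  if (!is.null(clusters)) {
    clusters <- setNames(as.character(clusters), names(clusters))
    if (is.null(names(clusters)))
      stop("`clusters` must be named by founder id")
  }
  structure(list(calls = calls, map = map, clusters = clusters),
            class = "founder_geno")
}

#' @export
print.founder_geno <- function(x, ...) {
  cat("Founder genotype matrix:", nrow(x$calls), "founders x",
      ncol(x$calls), "markers\n")
  if (!is.null(x$map)) cat("  marker map attached\n")
  if (!is.null(x$clusters))
    cat("  clusters:", paste(sort(unique(x$clusters)), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical unordered cross key
#'
#' A cross and its reciprocal share one key, `"<lo>:<hi>"` with the two
#' parent ids in lexicographic order.
#'
#' @param female,male character vectors of parent ids.
#' @return Character vector of keys.
#' @export
cross_key <- function(female, male) {
  paste(pmin(female, male), pmax(female, male), sep = ":")
}

#' Diallel crossing design
#'
#' Validates a table of directed crosses: no selfs, and at most two
#' directed crosses (the cross and its reciprocal) per unordered parent
#' pair within a year.
#'
#' @param crosses data.frame with columns `cross_id`, `female`, `male`,
#'   `year`.
#' @return The validated data.frame (class `diallel_design`) with an added
#'   `key` column holding the unordered pair key.
#' @export
diallel_design <- function(crosses) {
  crosses <- as.data.frame(crosses)
  need <- c("cross_id", "female", "male", "year")
  if (!all(need %in% names(crosses)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (any(crosses$female == crosses$male))
    stop("selfs are not part of the diallel: ",
         paste(crosses$cross_id[crosses$female == crosses$male], collapse = ", "))
  crosses$key <- cross_key(crosses$female, crosses$male)
  tab <- table(paste(crosses$key, crosses$year))
  if (any(tab > 2))
    stop("more than two directed crosses for pair(s): ",
         paste(names(tab)[tab > 2], collapse = ", "))
  class(crosses) <- c("diallel_design", "data.frame")
  crosses
}

#' Complete half-diallel among a set of founders
#'
#' All `n(n-1)/2` unordered crosses among `n` founders, one directed cross
#' per pair (lexicographically smaller parent as female).
#'
#' @param founders character vector of founder ids.
#' @param year year label attached to every cross (default `"1"`).
#' @return A [diallel_design()] data.frame.
#' @export
half_diallel <- function(founders, year = "1") {
  founders <- sort(unique(as.character(founders)))
  if (length(founders) < 2) stop("need at least two founders")
  idx <- utils::combn(length(founders), 2)
  female <- founders[idx[1, ]]
  male <- founders[idx[2, ]]
  diallel_design(data.frame(
    cross_id = paste(female, male, sep = "x"),
    female = female, male = male, year = as.character(year),
    stringsAsFactors = FALSE))
}

#' Number of unordered crosses in a complete half-diallel
#'
#' @param n_founders number of founder lines.
#' @return `n(n-1)/2`.
#' @export
half_diallel_size <- function(n_founders) {
  n_founders * (n_founders - 1) / 2
}

#' Project founder genotypes onto their hybrids
#'
#' Because the founders are homozygous, the genotype of each hybrid at
#' every marker is fully determined by its two parents: the unordered pair
#' of the parental allele calls. A pair is missing wherever either
#' parental call is missing. Reciprocal crosses share one projected
#' genotype.
#'
#' @param geno a [founder_geno()] object.
#' @param design a [diallel_design()] (or data.frame with `female`, `male`).
#' @return An object of class `hybrid_geno`: list with integer matrices
#'   `a1`, `a2` (crosses x markers, `a1 <= a2`, rownames = cross keys) and
#'   a `crosses` data.frame (`key`, `female`, `male`).
#' @export
project_hybrid_genotypes <- function(geno, design) {
  stopifnot(inherits(geno, "founder_geno"))
  design <- as.data.frame(design)
  if (is.null(design$key)) design$key <- cross_key(design$female, design$male)
  crosses <- unique(design[, c("key", "female", "male")])
  # reciprocals: collapse to one row per key, parents in key order
  lo <- pmin(crosses$female, crosses$male)
  hi <- pmax(crosses$female, crosses$male)
  crosses <- unique(data.frame(key = crosses$key, female = lo, male = hi,
                               stringsAsFactors = FALSE))
  parents <- unique(c(crosses$female, crosses$male))
  unknown <- setdiff(parents, rownames(geno$calls))
  if (length(unknown)) {
    bad <- crosses$key[crosses$female %in% unknown | crosses$male %in% unknown]
    stop("parent(s) ", paste(unknown, collapse = ", "),
         " absent from the founder genotype matrix (cross(es) ",
         paste(bad, collapse = ", "), ")")
  }
  gf <- geno$calls[crosses$female, , drop = FALSE]
  gm <- geno$calls[crosses$male, , drop = FALSE]
  a1 <- pmin(gf, gm)
  a2 <- pmax(gf, gm)
  rownames(a1) <- rownames(a2) <- crosses$key
  structure(list(a1 = a1, a2 = a2, crosses = crosses, map = geno$map),
            class = "hybrid_geno")
}

#' @export
print.hybrid_geno <- function(x, ...) {
  cat("Projected hybrid genotypes:", nrow(x$a1), "crosses x",
      ncol(x$a1), "markers\n")
  invisible(x)
}

#' Partition hybrids into genotypic groups at one locus
#'
#' Hybrids carrying two distinct alleles form hetero-genotypic groups keyed
#' by the unordered allele pair; all homozygous hybrids are pooled into a
#' single reference group (`split_homo = TRUE` keeps one homo group per
#' allele instead). Any group smaller than `min_group` crosses, and crosses
#' with a missing projected genotype, are moved to `excluded` with a
#' reason, so that hetero, homo and excluded partition the crosses.
#'
#' @param proj a [project_hybrid_genotypes()] result.
#' @param marker marker name.
#' @param min_group minimum number of crosses per testable group
#'   (default 3, generalizing the rare-allele rule: an allele carried by
#'   fewer than three founders cannot form a comparable group).
#' @param split_homo keep per-allele homozygous groups instead of pooling.
#' @return List of class `genotype_groups`: `marker`, `hetero` (named list
#'   of cross-key vectors, names `"a1/a2"`), `homo` (cross keys; named list
#'   when `split_homo`), `excluded` (data.frame `cross`, `reason`).
#' @export
partition_by_locus <- function(proj, marker, min_group = 3, split_homo = FALSE) {
  stopifnot(inherits(proj, "hybrid_geno"))
  if (!marker %in% colnames(proj$a1))
    stop("marker ", marker, " absent from the projected genotypes")
  a1 <- proj$a1[, marker]
  a2 <- proj$a2[, marker]
  keys <- rownames(proj$a1)
  miss <- is.na(a1) | is.na(a2)
  excluded <- data.frame(cross = keys[miss],
                         reason = rep("missing genotype", sum(miss)),
                         stringsAsFactors = FALSE)
  ok <- !miss
  het <- ok & a1 != a2
  hom <- ok & a1 == a2
  hetero <- split(keys[het], paste(a1[het], a2[het], sep = "/"))
  small <- names(hetero)[lengths(hetero) < min_group]
  for (g in small) {
    excluded <- rbind(excluded, data.frame(
      cross = hetero[[g]], reason = "below minimum group size",
      stringsAsFactors = FALSE))
  }
  hetero <- hetero[setdiff(names(hetero), small)]
  if (split_homo) {
    homo <- split(keys[hom], paste(a1[hom], a1[hom], sep = "/"))
    hsmall <- names(homo)[lengths(homo) < min_group]
    for (g in hsmall) {
      excluded <- rbind(excluded, data.frame(
        cross = homo[[g]], reason = "below minimum group size",
        stringsAsFactors = FALSE))
    }
    homo <- homo[setdiff(names(homo), hsmall)]
  } else {
    homo <- keys[hom]
    if (length(homo) > 0 && length(homo) < min_group) {
      excluded <- rbind(excluded, data.frame(
        cross = homo, reason = "below minimum group size",
        stringsAsFactors = FALSE))
      homo <- character(0)
    }
  }
  structure(list(marker = marker, hetero = hetero, homo = homo,
                 excluded = excluded, split_homo = split_homo),
            class = "genotype_groups")
}

#' Per-marker allele carrier counts and rare-allele flags
#'
#' A rare allele is one carried by fewer than `rare_threshold` founders;
#' genotypic groups defined by it are too small to test.
#'
#' @param geno a [founder_geno()] object.
#' @param rare_threshold carrier count below which an allele is rare
#'   (default 3).
#' @return data.frame with columns `marker`, `allele`, `count`, `rare`.
#' @export
allele_summary <- function(geno, rare_threshold = 3) {
  stopifnot(inherits(geno, "founder_geno"))
  out <- lapply(colnames(geno$calls), function(m) {
    calls <- geno$calls[, m]
    calls <- calls[!is.na(calls)]
    if (!length(calls))
      return(data.frame(marker = character(0), allele = integer(0),
                        count = integer(0), rare = logical(0)))
    tab <- table(calls)
    data.frame(marker = m, allele = as.integer(names(tab)),
               count = as.integer(tab),
               rare = as.integer(tab) < rare_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
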