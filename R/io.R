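#' Read a founder genotype table
#'
#' Wide TSV: first column the founder id, remaining columns marker names,
#' cells integer allele sizes or `NA`/empty for missing calls.
#'
#' @param path TSV file path.
#' @param map optional marker map (data.frame or TSV path; see
#'   [read_marker_map()]).
#' @param clusters optional cluster table (data.frame or TSV path; see
#'   [read_clusters()]).
#' @return A [founder_geno()] object.
#' @export
read_founder_genotypes <- function(path, map = NULL, clusters = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2) stop("expected founder id column plus marker columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate founder id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.integer(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer allele cell at line %d, marker %s",
                 bad[1, 1] + 1L, colnames(cells)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(cells))
  if (is.character(map)) map <- read_marker_map(map)
  if (is.character(clusters)) clusters <- read_clusters(clusters)
  if (is.data.frame(clusters))
    clusters <- setNames(as.character(clusters$cluster), clusters$founder)
  founder_geno(num, map = map, clusters = clusters)
}

#' Write a founder genotype table
#'
#' @param geno a [founder_geno()] object.
#' @param path output TSV path.
#' @export
write_founder_genotypes <- function(geno, path) {
  out <- data.frame(founder = rownames(geno$calls),
                    geno$calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a marker map (marker, chromosome, position)
#'
#' Positions are 1-based physical bp (or cM): only their order within a
#' chromosome is used, for HTL naming.
#'
#' @param path TSV path with columns `marker`, `chromosome`, `position`.
#' @return data.frame.
#' @export
read_marker_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position")
  if (!all(need %in% names(map)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  map
}

#' Read a founder cluster assignment (founder, cluster)
#'
#' @param path TSV path with columns `founder`, `cluster`.
#' @return data.frame.
#' @export
read_clusters <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("founder", "cluster") %in% names(cl)))
    stop("cluster table must have columns founder, cluster")
  cl
}

#' Read a replicated phenotype table
#'
#' Long TSV: columns `entry` (founder id or cross id), `year`,
#' `replicate`, then one numeric column per trait. Unknown trait names in
#' `traits` raise an error; trait columns not listed are kept. Negative
#' trait values are allowed through with a warning (downstream heterosis
#' computations flag them).
#'
#' @param path TSV path.
#' @param traits optional character vector of trait columns that must be
#'   present.
#' @return data.frame.
#' @export
read_phenotypes <- function(path, traits = NULL) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("entry", "year", "replicate")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  ph$year <- as.character(ph$year)
  trait_cols <- setdiff(names(ph), need)
  if (!is.null(traits)) {
    unknown <- setdiff(traits, trait_cols)
    if (length(unknown))
      stop("trait column(s) absent: ", paste(unknown, collapse = ", "))
    trait_cols <- traits
  }
  for (tc in trait_cols) {
    raw <- ph[[tc]]
    suppressWarnings(v <- as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw))
    if (length(bad))
      stop(sprintf("non-numeric value for trait %s at line %d", tc,
                   bad[1] + 1L))
    if (any(v < 0, na.rm = TRUE))
      warning(sprintf("negative %s value(s) at line(s) %s", tc,
                      paste(which(v < 0) + 1L, collapse = ", ")))
    ph[[tc]] <- v
  }
  dup <- duplicated(ph[, c("entry", "year", "replicate")])
  if (any(dup))
    stop("duplicate (entry, year, replicate) at line(s): ",
         paste(which(dup) + 1L, collapse = ", "))
  ph
}

#' Read a diallel design table
#'
#' @param path TSV path with columns `cross_id`, `female`, `male`, `year`.
#' @return A [diallel_design()].
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$year <- as.character(d$year)
  diallel_design(d)
}

#' Read an F2 table
#'
#' @param path TSV path with columns `plant`, `genotype`
#'   (`"allele1/allele2"`) and one or more numeric trait columns.
#' @return data.frame.
#' @export
read_f2 <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!all(c("plant", "genotype") %in% names(d)))
    stop("F2 table must have columns plant, genotype")
  d
}

#' Write ODH table, scan results and HTL calls to an output directory
#'
#' Writes `odh.tsv` (when given), `scan.tsv` and `ks.tsv` (per-year
#' step-1 and step-2 tables), `htl_calls.json` (schema-versioned JSON of
#' the calls with their per-year statistics) and `run_log.json` (seed and
#' configuration). Deterministic column order; rerunning with the same
#' inputs and seed reproduces the files byte for byte. Empty results
#' yield valid headered files.
#'
#' @param scan an [htl_scan()] result, or `NULL`.
#' @param dir output directory (created if needed).
#' @param odh optional [odh_table()] result to write alongside.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(scan, dir, odh = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  paths <- character(0)
  wtsv <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(odh)) paths <- c(paths, wtsv(odh, "odh.tsv"))
  if (!is.null(scan)) {
    mk <- do.call(rbind, lapply(names(scan$per_year), function(yr) {
      m <- scan$per_year[[yr]]$markers
      if (nrow(m)) cbind(year = yr, m) else NULL
    }))
    if (is.null(mk))
      mk <- data.frame(year = character(0), marker = character(0),
                       F = numeric(0), p = numeric(0),
                       threshold = numeric(0), passed = logical(0),
                       skipped = logical(0), reason = character(0))
    ks <- do.call(rbind, lapply(names(scan$per_year), function(yr) {
      k <- scan$per_year[[yr]]$ks
      if (nrow(k)) cbind(year = yr, k) else NULL
    }))
    if (is.null(ks))
      ks <- data.frame(year = character(0), marker = character(0),
                       pair = character(0), n_het = integer(0),
                       n_hom = integer(0), D = numeric(0), p = numeric(0),
                       advantage = logical(0))
    paths <- c(paths, wtsv(mk, "scan.tsv"), wtsv(ks, "ks.tsv"))
    payload <- list(
      schema = "htlmap/htl_calls/v1",
      trait = scan$trait,
      years = scan$years,
      config = unclass(scan$config),
      calls = scan$calls,
      call_stats = scan$call_stats)
    p <- file.path(dir, "htl_calls.json")
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    paths <- c(paths, p)
    log <- list(package = "htlmap",
                version = as.character(utils::packageVersion("htlmap")),
                seed = scan$config$seed,
                config = unclass(scan$config))
    lp <- file.path(dir, "run_log.json")
    jsonlite::write_json(log, lp, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, lp)
  }
  invisible(paths)
}

#' Write an epistasis ANOVA report
#'
#' @param result an `htl_anova` object.
#' @param dir output directory.
#' @return Invisibly, the paths written (`epistasis.tsv`,
#'   `epistasis_r2.json`).
#' @export
write_epistasis_report <- function(result, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  tp <- file.path(dir, "epistasis.tsv")
  utils::write.table(result$table, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jp <- file.path(dir, "epistasis_r2.json")
  jsonlite::write_json(list(schema = "htlmap/epistasis_r2/v1",
                            model_r2 = result$r2,
                            accumulated = result$accum,
                            note = result$note),
                       jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(tp, jp))
}

#' Write the simulated study to a directory
#'
#' Writes `founders.tsv`, `map.tsv`, `clusters.tsv`, `design.tsv`,
#' `pheno.tsv` and `truth.json`.
#'
#' @param sim a [simulate_diallel()] result.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  write_founder_genotypes(sim$geno, file.path(dir, "founders.tsv"))
  wtsv <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wtsv(sim$geno$map, "map.tsv")
  wtsv(data.frame(founder = names(sim$clusters),
                  cluster = unname(sim$clusters)), "clusters.tsv")
  wtsv(as.data.frame(sim$design)[, c("cross_id", "female", "male", "year")],
       "design.tsv")
  wtsv(sim$pheno, "pheno.tsv")
  jsonlite::write_json(list(schema = "htlmap/truth/v1",
                            planted = sim$truth$planted),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
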