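#' Construct an aligned sequence set
#'
#' Container for an alignment of equal-length sequences with sample ids and a
#' population label per sample. All sequence-level statistics in the package
#' operate on this class.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param sequences character vector of equal-length strings over
#'   `A,C,G,T,-,N` (lowercase is normalised to uppercase).
#' @param population_of named character vector mapping every sample id to a
#'   population label.
#' @return An object of class `aln_set`: a list with elements `sample_ids`,
#'   `sequences`, `population_of` and `k` (alignment length).
#' @export
aligned_sequence_set <- function(sample_ids, sequences, population_of) {
  sample_ids <- as.character(sample_ids)
  sequences <- toupper(as.character(sequences))
  if (length(sample_ids) != length(sequences))
    stop("sample_ids and sequences differ in length", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique", call. = FALSE)
  lens <- nchar(sequences)
  if (length(lens) == 0L || any(lens < 1L))
    stop("alignment must contain sequences of length >= 1", call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T,-,N}", call. = FALSE)
  population_of <- population_of[sample_ids]
  if (any(is.na(population_of)))
    stop("mapping error: samples without a population label: ",
         paste(sample_ids[is.na(population_of)], collapse = ", "),
         call. = FALSE)
  structure(
    list(sample_ids = sample_ids, sequences = sequences,
         population_of = stats::setNames(as.character(population_of),
                                         sample_ids),
         k = lens[1L]),
    class = "aln_set")
}

#' @export
print.aln_set <- function(x, ...) {
  cat("Aligned sequence set:", length(x$sample_ids), "sequences of length",
      x$k, "bp\n")
  tb <- table(x$population_of)
  cat("Populations (", length(tb), "): ",
      paste(names(tb), " (", tb, ")", sep = "", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

read_popmap <- function(popmap_path) {
  pm <- utils::read.table(popmap_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(pm) != 2L)
    stop("population map must be a 2-column TSV (sample_id, population)",
         call. = FALSE)
  stats::setNames(pm[[2L]], pm[[1L]])
}

#' Read an aligned FASTA file with a population map
#'
#' @param path path to an aligned FASTA file (all records equal length).
#' @param popmap_path path to a two-column TSV `sample_id<TAB>population`.
#' @return An [aligned_sequence_set()].
#' @export
read_fasta_alignment <- function(path, popmap_path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste0, character(1L), collapse = "")
  aligned_sequence_set(names(dna), seqs, read_popmap(popmap_path))
}

#' Write an aligned sequence set as FASTA plus population map
#'
#' @param aln an [aligned_sequence_set()].
#' @param path output FASTA path.
#' @param popmap_path optional output TSV path for the population map.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, popmap_path = NULL) {
  stopifnot(inherits(aln, "aln_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(aln$sample_ids))
    cat(">", aln$sample_ids[i], "\n", aln$sequences[i], "\n",
        sep = "", file = con)
  if (!is.null(popmap_path))
    utils::write.table(
      data.frame(aln$sample_ids, unname(aln$population_of)),
      popmap_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a dominant (presence/absence) marker matrix
#'
#' @param calls numeric matrix of 0/1/NA calls, individuals in rows, loci in
#'   columns; dimnames give individual and locus ids.
#' @param population_of named character vector mapping individuals to
#'   populations.
#' @return Object of class `marker_matrix`: list with `calls`,
#'   `individual_ids`, `locus_ids`, `population_of`, `missingness` (per-locus
#'   missing fraction).
#' @export
marker_matrix <- function(calls, population_of) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls matrix needs individual row names and locus column names",
         call. = FALSE)
  if (anyDuplicated(rownames(calls)) || anyDuplicated(colnames(calls)))
    stop("individual and locus ids must be unique", call. = FALSE)
  storage.mode(calls) <- "double"
  ok <- calls %in% c(0, 1) | is.na(calls)
  if (!all(ok))
    stop("parse error: marker calls must be 0, 1 or missing", call. = FALSE)
  population_of <- population_of[rownames(calls)]
  if (any(is.na(population_of)))
    stop("mapping error: individuals without a population label: ",
         paste(rownames(calls)[is.na(population_of)], collapse = ", "),
         call. = FALSE)
  structure(
    list(calls = calls,
         individual_ids = rownames(calls),
         locus_ids = colnames(calls),
         population_of = stats::setNames(as.character(population_of),
                                         rownames(calls)),
         missingness = colMeans(is.na(calls))),
    class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("Dominant marker matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "loci\n")
  tb <- table(x$population_of)
  cat("Populations (", length(tb), "): ",
      paste(names(tb), " (", tb, ")", sep = "", collapse = ", "), "\n",
      sep = "")
  cat(sprintf("Overall missingness: %.2f%%\n",
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read a dominant-marker band matrix (CSV) with a population map
#'
#' The CSV carries locus ids in the header and individual ids in the first
#' column; entries are 0, 1, or missing (empty cell or `NA`).
#'
#' @param path CSV path.
#' @param popmap_path two-column TSV `individual<TAB>population`.
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, popmap_path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m == "" | m == "NA"] <- NA_character_
  bad <- !(m %in% c("0", "1") | is.na(m))
  if (any(bad))
    stop("parse error: non-binary marker entries: ",
         paste(utils::head(unique(m[bad]), 5L), collapse = ", "),
         call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  marker_matrix(m, read_popmap(popmap_path))
}

#' Write a marker matrix as CSV plus population map
#' @param markers a [marker_matrix()].
#' @param path output CSV path.
#' @param popmap_path optional output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(markers, path, popmap_path = NULL) {
  stopifnot(inherits(markers, "marker_matrix"))
  df <- data.frame(individual = markers$individual_ids,
                   markers$calls, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(popmap_path))
    utils::write.table(
      data.frame(markers$individual_ids, unname(markers$population_of)),
      popmap_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an environmental covariate table
#'
#' One row per analysis unit (population or individual); named real-valued
#' environmental variables plus decimal-degree coordinates. Coordinates are
#' treated as plain covariates (no projection is performed).
#'
#' @param unit_ids character vector of unit labels (typically populations).
#' @param variables data frame of numeric environmental columns.
#' @param lon,lat numeric vectors, decimal degrees.
#' @param units optional character vector of measurement units per variable.
#' @return Object of class `env_table`: a data frame with row names
#'   `unit_ids`, the variables, and `lon`/`lat` columns; variable names kept
#'   in declared order, units carried as an attribute.
#' @export
env_table <- function(unit_ids, variables, lon, lat, units = NULL) {
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids))
    stop("duplicated unit id in environment table", call. = FALSE)
  variables <- as.data.frame(variables)
  if (nrow(variables) != length(unit_ids))
    stop("variables and unit_ids differ in length", call. = FALSE)
  if (!all(vapply(variables, is.numeric, logical(1L))))
    stop("environmental variables must be numeric", call. = FALSE)
  if (anyNA(variables))
    stop("validation error: missing value in a retained environmental ",
         "variable", call. = FALSE)
  if (anyNA(lon) || anyNA(lat))
    stop("validation error: missing coordinate", call. = FALSE)
  out <- cbind(variables, lon = as.numeric(lon), lat = as.numeric(lat))
  rownames(out) <- unit_ids
  attr(out, "variable_names") <- names(variables)
  attr(out, "units") <- units
  class(out) <- c("env_table", "data.frame")
  out
}

#' @export
print.env_table <- function(x, ...) {
  cat("Environment table:", nrow(x), "units,",
      length(attr(x, "variable_names")), "variables + lon/lat\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read an environmental covariate table from CSV
#'
#' First column = unit id; remaining columns = environmental variables plus
#' `lon` and `lat`.
#'
#' @param path CSV path.
#' @return An [env_table()].
#' @export
read_env_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if (!all(c("lon", "lat") %in% names(df)))
    stop("environment table must contain lon and lat columns", call. = FALSE)
  vars <- df[, setdiff(names(df), c("lon", "lat")), drop = FALSE]
  env_table(ids, vars, df$lon, df$lat)
}

#' Write an environment table to CSV
#' @param env an [env_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  stopifnot(inherits(env, "env_table"))
  df <- data.frame(unit = rownames(env), as.data.frame(env),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a marker matrix against an environment table
#'
#' Reports the intersection of population labels, per-population sample
#' counts, and loci that are monomorphic over all scored individuals. Fails
#' when any marker population lacks an environment row. Never mutates its
#' inputs.
#'
#' @param markers a [marker_matrix()].
#' @param env an [env_table()] with population-level rows.
#' @return A list of class `validation_report` with elements `ok`,
#'   `shared_populations`, `markers_only`, `env_only`, `counts`,
#'   `monomorphic_loci`.
#' @export
validate_dataset <- function(markers, env) {
  stopifnot(inherits(markers, "marker_matrix"), inherits(env, "env_table"))
  mpop <- unique(markers$population_of)
  epop <- rownames(env)
  shared <- intersect(mpop, epop)
  if (length(setdiff(mpop, epop)) > 0L)
    stop("fatal: marker populations missing from the environment table: ",
         paste(setdiff(mpop, epop), collapse = ", "), call. = FALSE)
  cm <- colMeans(markers$calls, na.rm = TRUE)
  mono <- markers$locus_ids[!is.na(cm) & (cm == 0 | cm == 1)]
  structure(
    list(ok = TRUE,
         shared_populations = shared,
         markers_only = setdiff(mpop, epop),
         env_only = setdiff(epop, mpop),
         counts = table(markers$population_of),
         monomorphic_loci = mono),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Dataset validation:", if (x$ok) "PASS" else "WARN", "\n")
  cat("Shared populations:", paste(x$shared_populations, collapse = ", "),
      "\n")
  if (length(x$markers_only))
    cat("In markers only:", paste(x$markers_only, collapse = ", "), "\n")
  if (length(x$env_only))
    cat("In environment only:", paste(x$env_only, collapse = ", "), "\n")
  cat("Monomorphic loci:", length(x$monomorphic_loci), "\n")
  invisible(x)
}
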