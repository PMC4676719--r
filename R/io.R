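# Plain-text readers/writers for every table the pipeline touches.
# Delimiters: tab or comma only, sniffed from the header line.

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t"
  else if (grepl(",", header)) ","
  else stop_bad_arg("%s: cannot detect delimiter (tab or comma required)", path)
}

read_delim_checked <- function(path) {
  if (!file.exists(path)) stop_bad_arg("file not found: %s", path)
  sep <- sniff_sep(path)
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("", "NA"))
}

#' Read a replicate log2 ratio table
#'
#' Expects a TSV/CSV with a protein-id column first and one numeric column
#' per replicate; empty cells are missing values. Proteins quantified in
#' fewer than `min_replicates` replicates are filtered (count reported).
#'
#' @param path file path.
#' @param min_replicates replicate filter threshold (default 2).
#' @return A [quant_table].
#' @export
read_quant_table <- function(path, min_replicates = 2L) {
  df <- read_delim_checked(path)
  if (ncol(df) < 2L) stop_bad_arg("%s: need id column plus >=1 replicate", path)
  ids <- as.character(df[[1]])
  dup <- duplicated(ids)
  if (any(dup))
    stop_bad_arg("%s: duplicated protein id(s) at row(s) %s: %s", path,
                 paste(which(dup), collapse = ", "),
                 paste(unique(ids[dup]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    bad <- !is.na(df[[j + 1]]) & is.na(suppressWarnings(as.numeric(df[[j + 1]])))
    if (any(bad))
      stop_bad_arg("%s: non-numeric value(s) in column '%s' at row(s) %s",
                   path, names(vals)[j], paste(which(bad), collapse = ", "))
  }
  m <- as.matrix(vapply(vals, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(vals)))
  rownames(m) <- ids
  quant_table(m, min_replicates = min_replicates)
}

#' Write a replicate log2 ratio table as TSV
#'
#' @param table a [quant_table].
#' @param path output path; missing values become empty cells.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  df <- data.frame(protein_id = rownames(table$values), table$values,
                   check.names = FALSE)
  colnames(df) <- c("protein_id", colnames(table$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a protein x stage RPKM matrix
#'
#' @param path TSV/CSV: protein-id column then one column per stage, in
#'   developmental order.
#' @return A [stage_matrix].
#' @export
read_stage_matrix <- function(path) {
  df <- read_delim_checked(path)
  if (ncol(df) < 2L) stop_bad_arg("%s: need id column plus >=1 stage", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_bad_arg("%s: duplicated protein id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_bad_arg("%s: non-numeric expression values", path)
  if (any(is.na(m)))
    stop_bad_arg("%s: missing RPKM value(s) at row(s) %s", path,
                 paste(which(rowSums(is.na(m)) > 0), collapse = ", "))
  rownames(m) <- ids
  stage_matrix(m)
}

#' Write a stage matrix as TSV
#' @param matrix a [stage_matrix].
#' @param path output path.
#' @export
write_stage_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "stage_matrix"))
  df <- data.frame(protein_id = rownames(matrix$rpkm), matrix$rpkm,
                   check.names = FALSE)
  colnames(df) <- c("protein_id", colnames(matrix$rpkm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Sets are restricted to the given universe; sets empty after
#' restriction are dropped with a message.
#'
#' @param path GMT file path.
#' @param universe character vector of protein ids.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path, universe) {
  if (!file.exists(path)) stop_bad_arg("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop_bad_arg("%s: malformed GMT line(s) (need name, description, >=1 member): %s",
                 path, paste(which(short), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop_bad_arg("%s: duplicated set name(s)", path)
  gene_set_collection(sets, universe,
                      descriptions = vapply(parts, `[[`, "", 2L))
}

#' Write gene sets as GMT
#' @param sets a [gene_set_collection].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, sets$descriptions[[nm]] %||% "", sets$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a photoconversion timecourse from long-format CSV/TSV
#'
#' Columns: `animal_id`, `group`, `converted`, `time_h`, `red`, `green`,
#' optional `dropped`. Validation (time 0 present for converted animals,
#' non-negative times) reports offending animals.
#'
#' @param path file path.
#' @return A [photo_timecourse].
#' @export
read_timecourse <- function(path) {
  df <- read_delim_checked(path)
  if ("converted" %in% names(df)) df$converted <- as.logical(df$converted)
  if ("dropped" %in% names(df)) df$dropped <- as.logical(df$dropped)
  photo_timecourse(df)
}

#' Write a photoconversion timecourse as CSV
#' @param tc a [photo_timecourse].
#' @param path output path.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "photo_timecourse"))
  utils::write.table(as.data.frame(tc), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a lifespan table from long-format CSV/TSV
#'
#' Columns: `group`, `time` (days, > 0), `event` (1 death / 0 censored),
#' optional `censor_reason`.
#'
#' @param path file path.
#' @return A [lifespan_table].
#' @export
read_lifespans <- function(path) {
  df <- read_delim_checked(path)
  lifespan_table(df)
}

#' Write a lifespan table as CSV
#' @param table a [lifespan_table].
#' @param path output path.
#' @export
write_lifespans <- function(table, path) {
  stopifnot(inherits(table, "lifespan_table"))
  utils::write.table(as.data.frame(table), path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write planted-truth metadata as JSON
#' @param truth a generator's `truth` list.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read planted-truth metadata
#' @param path JSON path.
#' @return The truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Build and write a run manifest
#'
#' Records everything needed to reproduce a pipeline run byte-identically:
#' input paths with md5 checksums, seeds, parameter values, output files,
#' package version and timestamp.
#'
#' @param inputs character vector of input file paths.
#' @param outputs character vector of output file paths.
#' @param params named list of parameter values (n_perm, fdr, ...).
#' @param seed the run seed.
#' @param path optional path to write the manifest JSON.
#' @return The manifest list (invisibly when written).
#' @export
run_manifest <- function(inputs = character(0), outputs = character(0),
                         params = list(), seed = NULL, path = NULL) {
  manifest <- list(
    tool = "agingproteome",
    version = as.character(utils::packageVersion("agingproteome")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = as.list(outputs))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
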