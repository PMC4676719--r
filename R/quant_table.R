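#' Replicate log2 ratio table
#'
#' Container for protein x replicate log2(heavy/light) abundance ratios, the
#' input to the rank-product differential analysis. Proteins quantified in
#' fewer than `min_replicates` replicates are filtered on construction (the
#' study design keeps proteins seen in at least 2 of 3 replicates); the count
#' removed is reported via a message.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   replicates in columns (colnames = replicate ids). `NA` marks a missing
#'   measurement.
#' @param min_replicates minimum number of non-missing replicate values a
#'   protein needs to be retained (default 2).
#'
#' @return An object of class `quant_table`: a list with elements `values`
#'   (the filtered matrix), `min_replicates`, and `n_filtered` (proteins
#'   removed by the replicate filter).
#' @export
quant_table <- function(values, min_replicates = 2L) {
  min_replicates <- check_count(min_replicates, "min_replicates", min = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop_bad_arg("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  dup <- duplicated(rownames(values))
  if (any(dup))
    stop_bad_arg("duplicated protein id(s): %s",
                 paste(unique(rownames(values)[dup]), collapse = ", "))
  if (any(is.infinite(values)))
    stop_bad_arg("non-finite ratio values present; log2 ratios must be finite")
  n_obs <- rowSums(!is.na(values))
  keep <- n_obs >= min_replicates
  if (any(!keep))
    message(sum(!keep), " protein(s) removed: fewer than ", min_replicates,
            " non-missing replicates")
  structure(
    list(values = values[keep, , drop = FALSE],
         min_replicates = min_replicates,
         n_filtered = sum(!keep)),
    class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table: ", nrow(x$values), " proteins x ", ncol(x$values),
      " replicates (", sum(is.na(x$values)), " missing cells; filter >= ",
      x$min_replicates, " replicates)\n", sep = "")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$values)

#' Median-center each replicate column
#'
#' Subtracts the per-replicate median of the non-missing log2 ratios so that
#' every replicate's median is zero. This controls for inexact 1:1 mixing of
#' the heavy- and light-labeled samples: changes are then interpreted relative
#' to the bulk of the proteome rather than on an absolute per-animal basis.
#'
#' @param table a [quant_table].
#' @return A `quant_table` with centered columns; the missingness pattern and
#'   within-replicate value ordering are unchanged.
#' @export
median_center <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  v <- table$values
  meds <- apply(v, 2, stats::median, na.rm = TRUE)
  if (any(is.na(meds)))
    stop_bad_arg("replicate(s) with no non-missing values: %s",
                 paste(colnames(v)[is.na(meds)], collapse = ", "))
  table$values <- sweep(v, 2, meds)
  table$median_centered <- TRUE
  table
}
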