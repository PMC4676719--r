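#' Protein x developmental-stage expression matrix
#'
#' Container for per-stage transcript abundance (RPKM) of the proteins in a
#' proteomic experiment, ordered through the developmental stages (early
#' embryo to young adult by default).
#'
#' @param rpkm non-negative numeric matrix, proteins in rows, stages in
#'   columns (colnames = stage labels in developmental order).
#' @param stage_labels optional character vector overriding the column names.
#' @return An object of class `stage_matrix`: list with `rpkm`,
#'   `stage_labels`, and (after [row_normalize()]) `normalized` + `method`.
#' @export
stage_matrix <- function(rpkm, stage_labels = NULL) {
  if (!is.matrix(rpkm) || !is.numeric(rpkm))
    stop_bad_arg("`rpkm` must be a numeric matrix")
  if (any(is.na(rpkm)) || any(rpkm < 0))
    stop_bad_arg("RPKM values must be non-negative and non-missing")
  if (!is.null(stage_labels)) {
    if (length(stage_labels) != ncol(rpkm))
      stop_bad_arg("stage_labels length != number of columns")
    colnames(rpkm) <- stage_labels
  }
  if (is.null(colnames(rpkm)))
    colnames(rpkm) <- c("EE", "LE", "L1", "L2", "L3", "L4", "YA")[seq_len(ncol(rpkm))]
  if (is.null(rownames(rpkm)))
    rownames(rpkm) <- paste0("P", seq_len(nrow(rpkm)))
  structure(list(rpkm = rpkm, stage_labels = colnames(rpkm)),
            class = "stage_matrix")
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat("stage_matrix: ", nrow(x$rpkm), " proteins x ", ncol(x$rpkm),
      " stages (", paste(x$stage_labels, collapse = ", "), ")",
      if (!is.null(x$method)) paste0("; normalized: ", x$method) else "",
      "\n", sep = "")
  invisible(x)
}

#' Row-normalize a stage matrix
#'
#' Converts absolute per-stage expression to a relative per-gene profile so
#' that clustering reflects the shape of a gene's developmental trajectory
#' rather than its absolute level. Methods: `sum` (rows sum to 1,
#' interpretable as stage proportions), `zscore` (row mean 0, SD 1 — the
#' convention of heatmap/clustergram tools), `max` (row maximum 1).
#'
#' @param matrix a [stage_matrix].
#' @param method normalization method.
#' @return The `stage_matrix` with a `normalized` matrix and `method` set.
#'   All-zero rows (sum/max) and constant rows (zscore) cannot be normalized
#'   and are dropped from the normalized view with a message.
#' @export
row_normalize <- function(matrix, method = c("zscore", "sum", "max")) {
  stopifnot(inherits(matrix, "stage_matrix"))
  method <- match.arg(method)
  v <- matrix$rpkm
  bad <- switch(method,
    sum = rowSums(v) == 0,
    max = apply(v, 1, max) == 0,
    zscore = apply(v, 1, stats::sd) == 0)
  if (any(bad)) {
    message(sum(bad), " row(s) dropped from normalized view (",
            if (method == "zscore") "constant" else "all zero", ")")
    v <- v[!bad, , drop = FALSE]
  }
  norm <- switch(method,
    sum = v / rowSums(v),
    max = v / apply(v, 1, max),
    zscore = t(scale(t(v))))
  dimnames(norm) <- dimnames(v)
  matrix$normalized <- norm
  matrix$method <- method
  matrix
}

#' Hierarchical clustering with correlation distance
#'
#' Clusters the (row-normalized) stage profiles with distance
#' `1 - Pearson correlation` between rows and agglomerative linkage. Rows with
#' zero variance (correlation undefined) are dropped with a message.
#'
#' @param matrix a [stage_matrix]; if not yet normalized, z-score row
#'   normalization is applied first.
#' @param linkage agglomeration method (default `average`).
#' @return A `stage_cluster_tree`: list with `hclust` (the merge tree),
#'   `protein_ids` (rows clustered), `matrix` (the normalized data used), and
#'   `linkage`.
#' @export
hierarchical_cluster <- function(matrix,
                                 linkage = c("average", "complete", "single")) {
  stopifnot(inherits(matrix, "stage_matrix"))
  linkage <- match.arg(linkage)
  if (is.null(matrix$normalized)) matrix <- row_normalize(matrix, "zscore")
  v <- matrix$normalized
  const <- apply(v, 1, stats::sd) == 0
  if (any(const)) {
    message(sum(const), " constant row(s) dropped (correlation undefined)")
    v <- v[!const, , drop = FALSE]
  }
  if (nrow(v) < 2L) stop_bad_arg("need at least 2 non-constant rows to cluster")
  d <- stats::as.dist(1 - stats::cor(t(v)))
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, protein_ids = rownames(v), matrix = matrix,
                 linkage = linkage),
            class = "stage_cluster_tree")
}

#' @export
print.stage_cluster_tree <- function(x, ...) {
  cat("stage_cluster_tree: ", length(x$protein_ids),
      " proteins, correlation distance, ", x$linkage, " linkage\n", sep = "")
  invisible(x)
}

#' Extract the most stage-specific cluster
#'
#' Cuts the tree into `k` clusters and returns the cluster with the highest
#' mean relative expression in `target_stage` (by default the adult stage,
#' the last label). Specificity is scored on the sum-normalized matrix so the
#' score is the mean proportion of a member gene's expression falling in the
#' target stage (1 = perfectly stage-specific, 1/n_stages = uniform). When
#' `k` is a vector the scan returns the best (cluster, k) pair by score.
#'
#' @param tree a `stage_cluster_tree` from [hierarchical_cluster()].
#' @param k number of clusters at the cut (scalar or vector to scan).
#' @param target_stage stage label (default: last stage in the matrix).
#' @return List with `cluster_id`, `k`, `members` (protein ids),
#'   `specificity` (mean target-stage proportion), `labels` (the full cut
#'   assignment at the chosen k), and `profile` (per-stage mean proportion of
#'   the winning cluster).
#' @export
find_stage_specific_cluster <- function(tree, k, target_stage = NULL) {
  stopifnot(inherits(tree, "stage_cluster_tree"))
  n <- length(tree$protein_ids)
  if (any(k < 2L) || any(k > n))
    stop_bad_arg("k must lie in [2, %d]", n)
  sm <- tree$matrix
  if (is.null(target_stage)) target_stage <- utils::tail(sm$stage_labels, 1)
  if (!target_stage %in% sm$stage_labels)
    stop_bad_arg("unknown stage label '%s'", target_stage)
  prop <- row_normalize(sm, "sum")$normalized
  prop <- prop[intersect(tree$protein_ids, rownames(prop)), , drop = FALSE]

  best <- NULL
  for (kk in as.integer(k)) {
    labels <- stats::cutree(tree$hclust, k = kk)
    names(labels) <- tree$protein_ids
    for (cl in unique(labels)) {
      ids <- intersect(names(labels)[labels == cl], rownames(prop))
      if (length(ids) == 0L) next
      score <- mean(prop[ids, target_stage])
      if (is.null(best) || score > best$specificity) {
        best <- list(cluster_id = cl, k = kk,
                     members = names(labels)[labels == cl],
                     specificity = score, labels = labels,
                     profile = colMeans(prop[ids, , drop = FALSE]))
      }
    }
  }
  best
}

#' Mean per-stage expression profile of a protein subset
#'
#' Unnormalized per-stage mean RPKM and standard error for a subset and its
#' complement, as used to compare the absolute developmental expression of a
#' hit list against the background.
#'
#' @param matrix a [stage_matrix].
#' @param subset character vector of protein ids (must be rows of the matrix).
#' @return A data.frame with columns `stage`, `group` (subset/complement),
#'   `mean`, `sem`, `n`. SEM is `NA` for single-protein groups.
#' @export
mean_stage_profile <- function(matrix, subset) {
  stopifnot(inherits(matrix, "stage_matrix"))
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) stop_bad_arg("empty subset")
  if (!all(subset %in% rownames(matrix$rpkm)))
    stop_bad_arg("%d subset id(s) not in the matrix",
                 sum(!subset %in% rownames(matrix$rpkm)))
  groups <- list(subset = subset,
                 complement = setdiff(rownames(matrix$rpkm), subset))
  do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) == 0L) return(NULL)
    m <- matrix$rpkm[ids, , drop = FALSE]
    data.frame(stage = colnames(m), group = g, mean = colMeans(m),
               sem = if (nrow(m) > 1L) apply(m, 2, stats::sd) / sqrt(nrow(m))
                     else NA_real_,
               n = nrow(m), row.names = NULL)
  }))
}
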