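#' Rank products of a replicate ratio table
#'
#' Within each replicate the non-missing log2 ratios are ranked (rank 1 is the
#' largest value for `direction = "up"`, the smallest for `"down"`; ties get
#' average ranks). A protein's rank product is the geometric mean of its
#' available ranks, each divided by the number of non-missing proteins in that
#' replicate, rescaled by the universe size so that proteins measured in
#' replicates of different depth stay comparable and the attainable minimum is
#' 1. Small rank products flag proteins consistently extreme across
#' replicates.
#'
#' @param table a [quant_table], normally after [median_center()].
#' @param direction `"up"` to rank increases first, `"down"` for decreases.
#' @return Named numeric vector of rank products (>= 1), one per retained
#'   protein.
#' @export
rank_product <- function(table, direction = c("up", "down")) {
  stopifnot(inherits(table, "quant_table"))
  direction <- match.arg(direction)
  if (!isTRUE(table$median_centered))
    warning("table does not appear to be median-centered; ",
            "rank products use raw column orderings", call. = FALSE)
  v <- table$values
  rank_product_from_ranks(replicate_ranks(v, direction), nrow(v))
}

# Within-replicate ranks: matrix with NA where the value is missing.
replicate_ranks <- function(v, direction) {
  signed <- if (direction == "up") -v else v
  apply(signed, 2, rank, ties.method = "average", na.last = "keep")
}

# Core rank-product formula shared by the observed and permuted paths:
# rp = N * geometric mean over available replicates of rank / depth.
rank_product_from_ranks <- function(ranks, n_universe) {
  depth <- colSums(!is.na(ranks))
  lg <- sweep(log(ranks), 2, log(depth))
  k <- rowSums(!is.na(ranks))
  rp <- n_universe * exp(rowSums(lg, na.rm = TRUE) / k)
  names(rp) <- rownames(ranks)
  rp
}

#' Permutation estimate of the proportion of false predictions (PFP)
#'
#' For each permutation the observed ranks are independently shuffled within
#' every replicate (the missingness pattern is held fixed, so each replicate's
#' depth is respected) and the rank products recomputed. For a protein whose
#' observed rank product sits at position `r` in the ascending rank-product
#' list, the expected number of false positives is the number of permuted rank
#' products at or below its observed value divided by `n_perm`, and
#' PFP = E(false positives) / r. PFP values are monotonized by a cumulative
#' minimum from the bottom of the sorted list (so PFP never decreases as the
#' cutoff loosens) and reported clipped to \[0, 1\] with the raw value kept in
#' a diagnostic column.
#'
#' @inheritParams rank_product
#' @param n_perm number of rank permutations (the study design uses 10000).
#' @param seed integer seed for the permutation stream.
#' @return A data.frame with columns `protein_id`, `rp`, `rank_position`,
#'   `expected_fp`, `pfp_raw`, `pfp` (monotonized, clipped), in the input
#'   protein order.
#' @export
permutation_pfp <- function(table, direction = c("up", "down"),
                            n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(table, "quant_table"))
  direction <- match.arg(direction)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (n_perm < 100L)
    warning("n_perm < 100 gives unstable PFP estimates", call. = FALSE)
  v <- table$values
  n <- nrow(v)
  obs_ranks <- replicate_ranks(v, direction)
  rp <- rank_product_from_ranks(obs_ranks, n)

  depth <- colSums(!is.na(obs_ranks))
  present <- !is.na(obs_ranks)
  k <- rowSums(present)
  sorted_rp <- sort(rp)
  counts <- numeric(n)  # permuted rp values <= each sorted observed rp

  # Permutations are processed in blocks: each block builds, per replicate, a
  # depth x block matrix of shuffled ranks assigned to the non-missing
  # proteins, accumulates log(rank/depth), and pools the resulting permuted
  # rank products against the observed ones.
  with_seed(seed, {
    block <- 250L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      acc <- matrix(0, n, b)
      for (j in seq_len(ncol(v))) {
        d <- depth[j]
        perm <- matrix(0L, d, b)
        for (p in seq_len(b)) perm[, p] <- sample.int(d)
        lgj <- log(perm) - log(d)
        acc[present[, j], ] <- acc[present[, j], ] + lgj
      }
      rp_perm <- n * exp(acc / k)
      counts <- counts + findInterval(sorted_rp, sort(rp_perm))
      done <- done + b
    }
  })

  ord <- order(rp)
  r_pos <- seq_len(n)
  e_fp_sorted <- counts / n_perm
  pfp_sorted <- e_fp_sorted / r_pos
  pfp_mono <- rev(cummin(rev(pfp_sorted)))

  out <- data.frame(protein_id = names(rp)[ord],
                    rp = rp[ord],
                    rank_position = r_pos,
                    expected_fp = e_fp_sorted,
                    pfp_raw = pfp_sorted,
                    pfp = pmin(pfp_mono, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[match(names(rp), out$protein_id), , drop = FALSE]
}

#' Call significantly changed proteins at a target FDR
#'
#' Combines the up- and down-direction PFP tables into one differential
#' result: a protein is called up if its up PFP is at or below `fdr`, down if
#' its down PFP is; in the pathological case where both directions pass, the
#' smaller PFP wins and a warning is issued.
#'
#' @param up_pfp,down_pfp data.frames from [permutation_pfp()] computed on the
#'   same table for directions `"up"` and `"down"`.
#' @param fdr target false discovery rate in (0, 1) (default 0.10).
#' @param mean_log2fc optional named vector of per-protein mean log2 fold
#'   changes to carry into the result.
#' @return A `differential_result`: data.frame with per-protein
#'   `mean_log2fc`, `rp_up`, `rp_down`, `pfp_up`, `pfp_down`, `direction`
#'   (up/down/none) and `significant`, plus attributes `n_up`, `n_down`,
#'   `fdr`.
#' @export
call_significant <- function(up_pfp, down_pfp, fdr = 0.10, mean_log2fc = NULL) {
  if (!is.numeric(fdr) || length(fdr) != 1L || is.na(fdr) || fdr <= 0 || fdr >= 1)
    stop_bad_arg("`fdr` must be in (0,1) (got %s)", format(fdr))
  if (!identical(sort(up_pfp$protein_id), sort(down_pfp$protein_id)))
    stop_bad_arg("up and down PFP tables cover different protein universes")
  down_pfp <- down_pfp[match(up_pfp$protein_id, down_pfp$protein_id), ]
  up_call <- up_pfp$pfp <= fdr
  down_call <- down_pfp$pfp <= fdr
  both <- up_call & down_call
  if (any(both)) {
    warning(sum(both), " protein(s) significant in both directions; ",
            "assigning the direction with smaller PFP", call. = FALSE)
    prefer_up <- up_pfp$pfp[both] <= down_pfp$pfp[both]
    down_call[both][prefer_up] <- FALSE
    up_call[both][!prefer_up] <- FALSE
  }
  direction <- ifelse(up_call, "up", ifelse(down_call, "down", "none"))
  res <- data.frame(protein_id = up_pfp$protein_id,
                    mean_log2fc = if (is.null(mean_log2fc)) NA_real_ else
                      unname(mean_log2fc[up_pfp$protein_id]),
                    rp_up = up_pfp$rp, rp_down = down_pfp$rp,
                    pfp_up = up_pfp$pfp, pfp_down = down_pfp$pfp,
                    direction = direction,
                    significant = direction != "none",
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, n_up = sum(up_call), n_down = sum(down_call), fdr = fdr,
            class = c("differential_result", "data.frame"))
}

#' @export
print.differential_result <- function(x, ...) {
  cat("differential_result: ", nrow(x), " proteins; ",
      attr(x, "n_up"), " up, ", attr(x, "n_down"), " down at FDR ",
      attr(x, "fdr"), "\n", sep = "")
  NextMethod()
}

#' Full rank-product differential test
#'
#' Convenience composition of the differential-abundance stage:
#' median-centering, rank products in both directions, permutation PFP, and
#' significance calls at the target FDR.
#'
#' @inheritParams permutation_pfp
#' @param fdr target false discovery rate (default 0.10).
#' @param center median-center the table first (default TRUE).
#' @return A `differential_result` (see [call_significant()]); the seed and
#'   `n_perm` used are attached as attributes.
#' @export
rank_product_test <- function(table, n_perm = 10000L, fdr = 0.10,
                              seed = NULL, center = TRUE) {
  stopifnot(inherits(table, "quant_table"))
  if (center) table <- median_center(table)
  up <- permutation_pfp(table, "up", n_perm = n_perm, seed = seed)
  down <- permutation_pfp(table, "down", n_perm = n_perm,
                          seed = if (is.null(seed)) NULL else seed + 1L)
  fc <- rowMeans(table$values, na.rm = TRUE)
  res <- call_significant(up, down, fdr = fdr, mean_log2fc = fc)
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  res
}
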