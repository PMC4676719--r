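#' Gene set collection
#'
#' Named list of protein-id character vectors restricted to an explicit
#' universe. Sets that become empty after restriction are dropped with a
#' message.
#'
#' @param sets named list of character vectors of member protein ids.
#' @param universe character vector of protein ids defining the background.
#' @param descriptions optional character vector (one per set).
#' @return An object of class `gene_set_collection` with elements `sets`,
#'   `universe`, `descriptions`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop_bad_arg("`sets` must be a named list of protein-id vectors")
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_bad_arg("empty universe")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  restricted <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  empty <- vapply(restricted, length, 1L) == 0L
  if (any(empty))
    message(sum(empty), " set(s) empty after restriction to universe, dropped: ",
            paste(names(restricted)[empty], collapse = ", "))
  structure(list(sets = restricted[!empty], universe = universe,
                 descriptions = descriptions[!empty]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection: ", length(x$sets), " sets over a universe of ",
      length(x$universe), " proteins\n", sep = "")
  invisible(x)
}

enrichment_result <- function(set_id, a, n_hits, K, N) {
  expected <- n_hits * K / N
  fold <- if (expected > 0) a / expected else NA_real_
  # upper tail: P(X >= a) for X ~ Hypergeom(N, K, n_hits)
  p_upper <- stats::phyper(a - 1, K, N - K, n_hits, lower.tail = FALSE)
  tab <- matrix(c(a, n_hits - a, K - a, N - K - n_hits + a), 2)
  p_two <- stats::fisher.test(tab)$p.value
  data.frame(set_id = set_id, a = a, n_hits = n_hits, K = K, N = N,
             expected = expected, fold = fold,
             p = p_upper, p_two_sided = p_two,
             stringsAsFactors = FALSE)
}

#' Fisher fold enrichment of an annotation among hits
#'
#' Tests whether a hit list (e.g. proteins significantly increased with age)
#' is over-represented in an annotation set (e.g. predicted secreted
#' proteins), relative to a stated universe. Reports the fold enrichment over
#' expectation, `(a/n_hits)/(K/N)`, the exact hypergeometric upper-tail
#' probability (the one-sided Fisher test for over-representation) as the
#' primary `p`, and the two-sided Fisher probability alongside.
#'
#' @param hits character vector of hit protein ids (must lie in `universe`).
#' @param annotation_set character vector of annotated protein ids; restricted
#'   to the universe before testing.
#' @param universe character vector of background protein ids.
#' @param set_id label carried into the result row.
#' @return A one-row data.frame: `a` (hits in set), `n_hits`, `K` (set size in
#'   universe), `N`, `expected`, `fold`, `p`, `p_two_sided`.
#' @export
fisher_fold_enrichment <- function(hits, annotation_set, universe,
                                   set_id = "set") {
  universe <- unique(as.character(universe))
  hits <- unique(as.character(hits))
  if (length(hits) == 0L || length(universe) == 0L)
    stop_bad_arg("`hits` and `universe` must be non-empty")
  if (!all(hits %in% universe))
    stop_bad_arg("%d hit id(s) outside the universe", sum(!hits %in% universe))
  K_set <- intersect(unique(as.character(annotation_set)), universe)
  if (length(K_set) == 0L) {
    warning("annotation set does not intersect the universe; fold undefined",
            call. = FALSE)
    out <- enrichment_result(set_id, 0L, length(hits), 0L, length(universe))
    out$fold <- NA_real_
    return(out)
  }
  enrichment_result(set_id, length(intersect(hits, K_set)), length(hits),
                    length(K_set), length(universe))
}

#' Enrichment of the overlap between two protein sets
#'
#' Tests whether two sets (e.g. adult-specific and predicted-secreted
#' proteins) overlap more than expected by chance in a common universe:
#' observed = the overlap size, expected = `|a|*|b|/N`, with the same exact
#' hypergeometric test as [fisher_fold_enrichment()].
#'
#' @param set_a,set_b character vectors of protein ids, both within `universe`.
#' @param universe character vector of background protein ids.
#' @param set_id label carried into the result row.
#' @return A one-row data.frame as in [fisher_fold_enrichment()] with `set_a`
#'   playing the role of the hits.
#' @export
overlap_enrichment <- function(set_a, set_b, universe, set_id = "overlap") {
  universe <- unique(as.character(universe))
  set_a <- intersect(unique(as.character(set_a)), universe)
  set_b <- intersect(unique(as.character(set_b)), universe)
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop_bad_arg("both sets must be non-empty within the universe")
  enrichment_result(set_id, length(intersect(set_a, set_b)),
                    length(set_a), length(set_b), length(universe))
}

#' Kolmogorov-Smirnov distribution-shift test
#'
#' Compares the distribution of a statistic (e.g. log2 aging fold change) in
#' a protein subset against a reference distribution (typically all measured
#' proteins) with the two-sample KS test. Used to ask whether e.g. secreted
#' proteins as a class shift toward increasing abundance with age even when
#' few members individually reach significance. The reference may contain the
#' subset (the study's primary comparison) or the caller may pass an
#' already-filtered subset and set `exclude_overlap` to record that the
#' shared members were removed.
#'
#' @param subset_values,reference_values numeric vectors.
#' @param exclude_overlap flag recorded in the result noting that overlapping
#'   members were excluded from `subset_values` by the caller.
#' @return A one-row data.frame: `D`, `p`, `direction` (sign of the median
#'   difference), `n_subset`, `n_reference`, `excluded_overlap`.
#' @export
ks_shift_test <- function(subset_values, reference_values,
                          exclude_overlap = FALSE) {
  subset_values <- subset_values[!is.na(subset_values)]
  reference_values <- reference_values[!is.na(reference_values)]
  if (length(subset_values) == 0L || length(reference_values) == 0L)
    stop_bad_arg("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(subset_values, reference_values,
                                        exact = FALSE))
  data.frame(D = unname(kt$statistic), p = kt$p.value,
             direction = sign(stats::median(subset_values) -
                              stats::median(reference_values)),
             n_subset = length(subset_values),
             n_reference = length(reference_values),
             excluded_overlap = isTRUE(exclude_overlap))
}

# Weighted running-sum enrichment score. scores sorted decreasing; member is
# a logical vector aligned with the sorted scores.
gsea_es <- function(sorted_scores, member, weight_exponent) {
  w <- abs(sorted_scores)^weight_exponent
  w_hit <- w * member
  total_hit <- sum(w_hit)
  n_miss <- sum(!member)
  if (total_hit == 0 || n_miss == 0L) return(NA_real_)
  steps <- ifelse(member, w_hit / total_hit, -1 / n_miss)
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Permutation gene set enrichment analysis (GSEA)
#'
#' Running-sum GSEA over a ranked protein list: walking down the list sorted
#' by score, the sum increases by a set member's weight (|score| to the
#' `weight_exponent`, normalized over members) and decreases uniformly for
#' non-members; the enrichment score (ES) is the maximum deviation from zero.
#' The null is built by permuting protein labels (with three paired replicates
#' there are too few samples to permute), the normalized score (NES) divides
#' the ES by the mean |ES| of same-sign permuted scores, the permutation p
#' uses the add-one estimator, and the permutation FDR pools the null NES
#' across sets as in the standard procedure.
#'
#' @param ranking named numeric vector: score (e.g. mean log2 fold change) per
#'   protein; names define the universe.
#' @param sets a [gene_set_collection] (its universe must be contained in the
#'   ranking's names).
#' @param weight_exponent 0 (classic Kolmogorov-Smirnov-like) or 1 (weighted).
#' @param n_perm label permutations per set (the study design uses 1000).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after restriction; sets outside
#'   the bounds are skipped with a message.
#' @param exhaustive if TRUE and `choose(N, K)` is small (<= 1e5), enumerate
#'   all member placements instead of sampling; `p_perm` is then exact.
#' @return A data.frame with one row per tested set: `set_id`, `size`, `es`,
#'   `nes`, `p_perm`, `q_perm`, `n_perm`.
#' @export
gsea <- function(ranking, sets, weight_exponent = 1, n_perm = 1000L,
                 seed = NULL, min_size = 5L, max_size = 500L,
                 exhaustive = FALSE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(names(ranking))) stop_bad_arg("`ranking` must be named")
  if (!weight_exponent %in% c(0, 1))
    stop_bad_arg("`weight_exponent` must be 0 or 1")
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  missing_ids <- setdiff(unlist(sets$sets), names(ranking))
  if (length(missing_ids) > 0L)
    stop_bad_arg("%d set member(s) absent from the ranking", length(missing_ids))
  ord <- order(ranking, decreasing = TRUE)
  sorted_scores <- unname(ranking[ord])
  sorted_ids <- names(ranking)[ord]
  n <- length(ranking)

  keep <- vapply(sets$sets, function(s) {
    k <- length(s)
    k >= min_size && k <= max_size && k < n
  }, logical(1))
  if (any(!keep))
    message(sum(!keep), " set(s) outside size bounds [", min_size, ", ",
            max_size, "] or spanning the whole universe, skipped")
  use_sets <- sets$sets[keep]
  if (length(use_sets) == 0L) stop_bad_arg("no testable sets")

  res <- with_seed(seed, {
    lapply(names(use_sets), function(sid) {
      member <- sorted_ids %in% use_sets[[sid]]
      k <- sum(member)
      es <- gsea_es(sorted_scores, member, weight_exponent)
      if (exhaustive && choose(n, k) <= 1e5) {
        combos <- utils::combn(n, k)
        null_es <- apply(combos, 2, function(idx) {
          m <- logical(n); m[idx] <- TRUE
          gsea_es(sorted_scores, m, weight_exponent)
        })
        same <- null_es[sign(null_es) == sign(es)]
        p <- sum(abs(null_es) >= abs(es) & sign(null_es) == sign(es)) /
          length(null_es)
        np <- length(null_es)
      } else {
        null_es <- vapply(seq_len(n_perm), function(i) {
          m <- logical(n); m[sample.int(n, k)] <- TRUE
          gsea_es(sorted_scores, m, weight_exponent)
        }, numeric(1))
        same <- null_es[sign(null_es) == sign(es)]
        p <- (1 + sum(abs(null_es) >= abs(es) & sign(null_es) == sign(es))) /
          (n_perm + 1)
        np <- n_perm
      }
      denom <- mean(abs(same))
      nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
      null_nes <- if (is.finite(denom) && denom > 0) null_es / denom else
        rep(NA_real_, length(null_es))
      list(row = data.frame(set_id = sid, size = k, es = es, nes = nes,
                            p_perm = p, n_perm = np,
                            stringsAsFactors = FALSE),
           null_nes = null_nes)
    })
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  pooled <- unlist(lapply(res, `[[`, "null_nes"))
  pooled <- pooled[is.finite(pooled)]
  out$q_perm <- vapply(seq_len(nrow(out)), function(i) {
    nes <- out$nes[i]
    if (!is.finite(nes) || length(pooled) == 0L) return(NA_real_)
    if (nes >= 0) {
      num <- mean(pooled >= nes)
      den <- mean(out$nes >= nes, na.rm = TRUE)
    } else {
      num <- mean(pooled <= nes)
      den <- mean(out$nes <= nes, na.rm = TRUE)
    }
    min(1, if (den > 0) num / den else NA_real_)
  }, numeric(1))
  out[, c("set_id", "size", "es", "nes", "p_perm", "q_perm", "n_perm")]
}

#' Direction concordance between two fold-change datasets
#'
#' Fraction of shared proteins whose fold changes agree in sign between two
#' studies, a binomial test of that fraction against 0.5, and the squared
#' Pearson correlation of the fold changes. A zero fold change counts as
#' discordant (conservative).
#'
#' @param fc_a,fc_b named numeric vectors of fold changes.
#' @param restrict_to optional character vector restricting the comparison
#'   (e.g. proteins significant in study a).
#' @return A one-row data.frame: `n_shared`, `n_concordant`, `concordance`,
#'   `p_binomial`, `r_squared`.
#' @export
direction_concordance <- function(fc_a, fc_b, restrict_to = NULL) {
  if (is.null(names(fc_a)) || is.null(names(fc_b)))
    stop_bad_arg("fold-change vectors must be named by protein id")
  shared <- intersect(names(fc_a), names(fc_b))
  if (!is.null(restrict_to)) shared <- intersect(shared, restrict_to)
  if (length(shared) == 0L) stop_bad_arg("no shared protein ids")
  a <- fc_a[shared]; b <- fc_b[shared]
  conc <- sign(a) == sign(b) & sign(a) != 0
  bt <- stats::binom.test(sum(conc), length(conc), p = 0.5)
  data.frame(n_shared = length(shared), n_concordant = sum(conc),
             concordance = mean(conc), p_binomial = bt$p.value,
             r_squared = stats::cor(a, b)^2)
}

#' Benjamini-Hochberg adjustment across sets
#'
#' Step-up false-discovery-rate adjustment of a vector of per-set p values.
#'
#' @param p_values numeric vector of p values in (0, 1].
#' @return Numeric vector of q values (same order, `q >= p`).
#' @export
adjust_across_sets <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_bad_arg("p values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
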