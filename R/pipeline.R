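# Stage orchestration: each run_* function composes the documented module
# operations, writes tidy result tables, and records a manifest. Defaults
# follow the study design (n_perm = 10000, GSEA 1000 permutations, 10% FDR,
# min 2 replicates, GSEA FDR 0.05).

write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the differential-abundance stage end to end
#'
#' Median-centering, rank products in both directions, permutation PFP, and
#' significance calls, from either a file path or an in-memory
#' [quant_table]. Writes `differential.tsv` (sorted by the smaller of the
#' two PFPs) and `manifest.json` to `out_dir` when given.
#'
#' @param input path to a ratio table or a [quant_table].
#' @param n_perm rank permutations (default 10000).
#' @param fdr target FDR (default 0.10).
#' @param min_replicates replicate filter for file input (default 2).
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return The `differential_result` (invisibly carries `n_up`, `n_down`).
#' @export
run_differential <- function(input, n_perm = 10000L, fdr = 0.10,
                             min_replicates = 2L, seed = 1L, out_dir = NULL) {
  table <- if (inherits(input, "quant_table")) input
           else read_quant_table(input, min_replicates = min_replicates)
  if (nrow(table$values) == 0L)
    stop_bad_arg("differential: no proteins retained after filtering")
  res <- rank_product_test(table, n_perm = n_perm, fdr = fdr, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ord <- order(pmin(res$pfp_up, res$pfp_down))
    out <- file.path(out_dir, "differential.tsv")
    write_result_tsv(as.data.frame(res)[ord, ], out)
    run_manifest(inputs = if (is.character(input)) input else character(0),
                 outputs = out,
                 params = list(stage = "differential", n_perm = n_perm,
                               fdr = fdr, min_replicates = min_replicates),
                 seed = seed, path = file.path(out_dir, "manifest.json"))
  }
  res
}

#' Run the set-level enrichment stage
#'
#' Fisher fold enrichment of the up- and down-hit lists in every annotation
#' set, BH-adjusted across sets, plus KS shift tests of each set's fold
#' changes against the full distribution, and (optionally) permutation GSEA
#' on the mean log2 fold-change ranking.
#'
#' @param differential a `differential_result`.
#' @param sets a [gene_set_collection] over the same universe.
#' @param run_gsea also run permutation GSEA (default TRUE).
#' @param gsea_n_perm GSEA permutations (default 1000).
#' @param gsea_fdr significance threshold on the GSEA permutation FDR
#'   (default 0.05).
#' @param seed integer seed.
#' @param out_dir optional output directory (writes `enrichment.tsv`,
#'   `ks_shift.tsv`, `gsea.tsv`, `manifest.json`).
#' @return List with `fisher` (up/down enrichment rows per set with `q`),
#'   `ks` (per-set shift tests), and `gsea` (or NULL).
#' @export
run_enrichment <- function(differential, sets, run_gsea = TRUE,
                           gsea_n_perm = 1000L, gsea_fdr = 0.05, seed = 1L,
                           out_dir = NULL) {
  stopifnot(inherits(differential, "differential_result"),
            inherits(sets, "gene_set_collection"))
  universe <- differential$protein_id
  hits <- list(up = differential$protein_id[differential$direction == "up"],
               down = differential$protein_id[differential$direction == "down"])
  fisher <- do.call(rbind, lapply(names(sets$sets), function(sid) {
    do.call(rbind, lapply(names(hits), function(h) {
      if (length(hits[[h]]) == 0L) return(NULL)
      row <- fisher_fold_enrichment(hits[[h]], sets$sets[[sid]], universe,
                                    set_id = sid)
      row$hit_list <- h
      row
    }))
  }))
  if (!is.null(fisher)) fisher$q <- adjust_across_sets(fisher$p)
  fc <- stats::setNames(differential$mean_log2fc, differential$protein_id)
  ks <- do.call(rbind, lapply(names(sets$sets), function(sid) {
    row <- ks_shift_test(fc[intersect(sets$sets[[sid]], universe)], fc)
    row$set_id <- sid
    row
  }))
  gsea_res <- NULL
  if (run_gsea) {
    gsea_res <- gsea(fc, sets, n_perm = gsea_n_perm, seed = seed)
    gsea_res$significant <- !is.na(gsea_res$q_perm) & gsea_res$q_perm < gsea_fdr
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outs <- character(0)
    if (!is.null(fisher))
      outs <- c(outs, write_result_tsv(fisher, file.path(out_dir, "enrichment.tsv")))
    outs <- c(outs, write_result_tsv(ks, file.path(out_dir, "ks_shift.tsv")))
    if (!is.null(gsea_res))
      outs <- c(outs, write_result_tsv(gsea_res, file.path(out_dir, "gsea.tsv")))
    run_manifest(outputs = outs,
                 params = list(stage = "enrichment", gsea_n_perm = gsea_n_perm,
                               gsea_fdr = gsea_fdr),
                 seed = seed, path = file.path(out_dir, "manifest.json"))
  }
  list(fisher = fisher, ks = ks, gsea = gsea_res)
}

#' Run the stage-clustering stage
#'
#' Row normalization, correlation-distance hierarchical clustering, and
#' extraction of the most adult-specific cluster at the configured cut.
#'
#' @param input path to a stage matrix or a [stage_matrix].
#' @param k cluster count(s) for the cut (vector scans and keeps the best).
#' @param normalization row normalization for clustering (default zscore).
#' @param linkage agglomeration method (default average).
#' @param target_stage stage whose specificity is maximized (default: last).
#' @param out_dir optional output directory (writes `clusters.tsv`,
#'   `adult_cluster.tsv`, `manifest.json`).
#' @return List with `tree`, `adult_cluster` (see
#'   [find_stage_specific_cluster()]), and `profile` (per-stage means of the
#'   winning cluster members, via [mean_stage_profile()]).
#' @export
run_cluster <- function(input, k = 12L, normalization = "zscore",
                        linkage = "average", target_stage = NULL,
                        out_dir = NULL) {
  sm <- if (inherits(input, "stage_matrix")) input else read_stage_matrix(input)
  sm <- row_normalize(sm, normalization)
  tree <- hierarchical_cluster(sm, linkage = linkage)
  best <- find_stage_specific_cluster(tree, k = k, target_stage = target_stage)
  profile <- mean_stage_profile(sm, best$members)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    labs <- data.frame(protein_id = names(best$labels),
                       cluster = unname(best$labels))
    o1 <- write_result_tsv(labs, file.path(out_dir, "clusters.tsv"))
    o2 <- write_result_tsv(
      data.frame(protein_id = best$members,
                 cluster = best$cluster_id,
                 specificity = best$specificity),
      file.path(out_dir, "adult_cluster.tsv"))
    run_manifest(inputs = if (is.character(input)) input else character(0),
                 outputs = c(o1, o2),
                 params = list(stage = "cluster", k = best$k,
                               normalization = normalization,
                               linkage = linkage),
                 path = file.path(out_dir, "manifest.json"))
  }
  list(tree = tree, adult_cluster = best, profile = profile)
}

#' Run the turnover stage
#'
#' Background subtraction and time-0 normalization, per-group half-life
#' estimation (both methods), and model-based synthesis-rate inference from
#' the unconverted (total green) trajectories.
#'
#' @param input path to a timecourse file or a [photo_timecourse].
#' @param method half-life estimator for the primary report (default
#'   interpolation).
#' @param n_boot bootstrap resamples for half-life CIs.
#' @param seed integer seed.
#' @param out_dir optional output directory (writes `turnover.tsv`,
#'   `manifest.json`).
#' @return List with per-group elements: `half_life` (a `turnover_estimate`),
#'   `half_life_loglinear`, `synthesis` (see [estimate_synthesis()]), and a
#'   `report` data.frame.
#' @export
run_turnover <- function(input, method = "interpolation", n_boot = 1000L,
                         seed = 1L, out_dir = NULL) {
  tc <- if (inherits(input, "photo_timecourse")) input else read_timecourse(input)
  norm <- normalize_decay(tc)
  groups <- unique(norm$rel$group)
  per_group <- lapply(groups, function(g) {
    rel_g <- norm$rel[norm$rel$group == g, ]
    hl <- estimate_half_life(rel_g, method = method, n_boot = n_boot,
                             seed = seed)
    hl_ll <- tryCatch(
      estimate_half_life(rel_g, method = "loglinear", n_boot = 0L),
      error = function(e) NULL)
    unconv <- tc[!tc$converted & !tc$dropped & tc$group == g, ]
    synth <- if (!hl$censored && nrow(unconv) > 0L)
      estimate_synthesis(unconv[, c("animal_id", "time_h", "green")],
                         hl$decay_constant)
    else NULL
    list(half_life = hl, half_life_loglinear = hl_ll, synthesis = synth)
  })
  names(per_group) <- groups
  report <- do.call(rbind, lapply(groups, function(g) {
    hl <- per_group[[g]]$half_life
    sy <- per_group[[g]]$synthesis
    data.frame(group = g,
               half_life_hours = hl$half_life_hours,
               censored = hl$censored,
               censor_bound = hl$censor_bound,
               method = hl$method,
               ci_lo = hl$ci[1], ci_hi = hl$ci[2],
               synthesis_rate = if (is.null(sy)) NA_real_ else sy$synthesis_rate,
               fold_change_tmax = if (is.null(sy)) NA_real_ else sy$fold_change_tmax)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- write_result_tsv(report, file.path(out_dir, "turnover.tsv"))
    run_manifest(inputs = if (is.character(input)) input else character(0),
                 outputs = out,
                 params = list(stage = "turnover", method = method,
                               n_boot = n_boot),
                 seed = seed, path = file.path(out_dir, "manifest.json"))
  }
  c(per_group, list(report = report, normalized = norm))
}

#' Run the survival stage
#'
#' Kaplan-Meier curves, pairwise log-rank tests against a reference group,
#' and percent median-lifespan extension.
#'
#' @param input path to a lifespan file or a [lifespan_table].
#' @param reference_group reference for extensions and pairwise tests
#'   (default: first group).
#' @param out_dir optional output directory (writes `survival.tsv`,
#'   `km_curves.tsv`, `manifest.json`).
#' @return List with `km` (a `survival_result`), `extension`, and `logrank`
#'   (data.frame `group`, `statistic`, `p` vs the reference).
#' @export
run_survival <- function(input, reference_group = NULL, out_dir = NULL) {
  table <- if (inherits(input, "lifespan_table")) input else read_lifespans(input)
  km <- km_estimate(table)
  groups <- names(km$medians)
  if (is.null(reference_group)) reference_group <- groups[1]
  ext <- median_extension(km, reference_group)
  lr <- do.call(rbind, lapply(setdiff(groups, reference_group), function(g) {
    t <- logrank_test(table, c(reference_group, g))
    data.frame(group = g, statistic = t$statistic, p = t$p)
  }))
  report <- merge(ext, lr, by = "group", all.x = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    o1 <- write_result_tsv(report, file.path(out_dir, "survival.tsv"))
    o2 <- write_result_tsv(km$curves, file.path(out_dir, "km_curves.tsv"))
    run_manifest(inputs = if (is.character(input)) input else character(0),
                 outputs = c(o1, o2),
                 params = list(stage = "survival",
                               reference_group = reference_group),
                 path = file.path(out_dir, "manifest.json"))
  }
  list(km = km, extension = ext, logrank = lr, report = report)
}
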