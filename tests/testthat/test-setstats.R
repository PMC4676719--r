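# Set-level statistics: Fisher fold enrichment, overlap enrichment, KS
# shift, GSEA, concordance, BH adjustment.

universe_ids <- function(n) sprintf("P%04d", seq_len(n))

test_that("fold enrichment reproduces arithmetic and its boundary cases", {
  u <- universe_ids(1796)
  hits <- u[1:40]
  secreted <- c(u[1:34], u[101:315])  # K = 249, overlap a = 34
  e <- fisher_fold_enrichment(hits, secreted, u)
  expect_equal(e$a, 34)
  expect_equal(e$K, 249)
  expect_equal(e$fold, (34 / 40) / (249 / 1796))
  expect_equal(e$fold * e$expected, e$a)

  # annotation = universe: fold exactly 1, p exactly 1
  all_e <- fisher_fold_enrichment(hits, u, u)
  expect_equal(all_e$fold, 1)
  expect_equal(all_e$p, 1)

  # annotation disjoint from universe: flagged, fold undefined
  expect_warning(out <- fisher_fold_enrichment(hits, c("X1", "X2"), u),
                 "fold undefined")
  expect_true(is.na(out$fold))
  expect_error(fisher_fold_enrichment(character(0), secreted, u), "non-empty")
})

test_that("exact tail probability agrees with brute-force enumeration", {
  # all 2x2 configurations on small universes
  for (N in c(8L, 10L, 12L)) {
    for (K in c(3L, 4L)) {
      for (n_hits in c(2L, 3L)) {
        u <- universe_ids(N)
        ann <- u[seq_len(K)]
        for (a in 0:min(K, n_hits)) {
          hits <- c(u[seq_len(a)], u[K + seq_len(n_hits - a)])
          e <- fisher_fold_enrichment(hits, ann, u)
          expect_equal(e$p, bruteforce_hyper_upper(a, n_hits, K, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("overlap enrichment handles disjoint and saturated sets", {
  u <- universe_ids(100)
  ov <- overlap_enrichment(u[1:20], u[21:40], u)
  expect_equal(ov$a, 0)
  expect_equal(ov$fold, 0)
  expect_gt(ov$p, 0.9)
  full <- overlap_enrichment(u[1:20], u, u)
  expect_equal(full$fold, 1)
  part <- overlap_enrichment(u[1:30], u[16:45], u)
  expect_equal(part$a, 15)
  expect_equal(part$fold, 15 / (30 * 30 / 100))
})

test_that("KS shift test detects shifts, is null-calibrated, and transform-invariant", {
  # identical samples: D = 0
  x <- rnorm(50)
  expect_equal(ks_shift_test(x, x)$D, 0)

  # invariance under a common strictly monotone transform
  set.seed(8)
  a <- rnorm(100); b <- rnorm(150, 0.5)
  k1 <- ks_shift_test(a, b)
  k2 <- ks_shift_test(exp(a), exp(b))
  expect_equal(k1$D, k2$D)
  expect_equal(k1$p, k2$p)

  # null calibration over seeds
  rej <- vapply(1:50, function(s) {
    set.seed(s)
    ref <- rnorm(500)
    ks_shift_test(sample(ref, 100), ref)$p < 0.05
  }, logical(1))
  expect_lte(sum(rej), qbinom(0.975, 50, 0.05))

  # a +1 SD shift at the study's subset/background sizes is overwhelming
  set.seed(1)
  shifted <- ks_shift_test(rnorm(249, 1), rnorm(1796))
  expect_lt(shifted$p, 1e-10)
  expect_equal(shifted$direction, 1)
})

test_that("GSEA p matches exhaustive enumeration and extremes behave", {
  # 6-protein universe, 2-member set, weight 0
  scores <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  sets <- gene_set_collection(list(s = c("g1", "g2")), names(scores))
  res <- gsea(scores, sets, weight_exponent = 0, n_perm = 4000, seed = 12,
              min_size = 1)
  p_exact <- exhaustive_gsea_p(6, c(1, 2))
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_perm - p_exact), 3 * se + 1 / 4000)
  # built-in exhaustive mode agrees with the oracle exactly
  res_ex <- gsea(scores, sets, weight_exponent = 0, n_perm = 100,
                 min_size = 1, exhaustive = TRUE)
  expect_equal(res_ex$p_perm, p_exact)

  # a set of the top-k proteins maximizes the weight-0 ES over size-k sets
  top <- gene_set_collection(list(top = c("g1", "g2")), names(scores))
  es_top <- gsea(scores, top, weight_exponent = 0, n_perm = 50, seed = 1,
                 min_size = 1)$es
  combos <- combn(6, 2)
  all_es <- apply(combos, 2, function(ix) oracle_es_w0(6, ix))
  expect_equal(es_top, max(all_es))

  # antisymmetry under ranking reversal for weight 0
  rev_scores <- setNames(-scores, names(scores))
  es_rev <- gsea(rev_scores, top, weight_exponent = 0, n_perm = 50, seed = 1,
                 min_size = 1)$es
  expect_equal(es_rev, -es_top)
})

test_that("GSEA respects size bounds and permutation-p floor", {
  set.seed(3)
  scores <- setNames(rnorm(40), paste0("g", 1:40))
  sets <- gene_set_collection(
    list(tiny = "g1", ok = paste0("g", 2:11), whole = names(scores)),
    names(scores))
  expect_message(res <- gsea(scores, sets, n_perm = 99, seed = 2, min_size = 5),
                 "skipped")
  expect_equal(res$set_id, "ok")
  expect_gte(res$p_perm, 1 / 100)
})

test_that("direction concordance measures sign agreement conservatively", {
  fc <- setNames(c(1, -2, 3, -4, 0), paste0("p", 1:5))
  same <- direction_concordance(fc, fc)
  expect_equal(same$concordance, 4 / 5)  # the zero counts as discordant
  opp <- direction_concordance(fc, -fc)
  expect_equal(opp$concordance, 0)
  r2 <- direction_concordance(fc[1:4], 2 * fc[1:4])
  expect_equal(r2$r_squared, 1)
  expect_equal(r2$concordance, 1)
  expect_error(direction_concordance(fc, setNames(1, "zzz")), "no shared")

  # independent random signs hover at 0.5
  set.seed(21)
  conc <- vapply(1:50, function(i) {
    a <- setNames(rnorm(100), paste0("p", 1:100))
    b <- setNames(rnorm(100), paste0("p", 1:100))
    direction_concordance(a, b)$concordance
  }, numeric(1))
  expect_lt(abs(mean(conc) - 0.5), 0.05)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_across_sets(0.03), 0.03)
  expect_equal(adjust_across_sets(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_across_sets(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.9)
  q <- adjust_across_sets(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p))
  expect_error(adjust_across_sets(c(0.1, 0)), "p values")
})
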