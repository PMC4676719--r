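# Synthetic-data generators: determinism, planted structure, argument
# validation, null behavior.

test_that("generators are pure functions of their arguments including seed", {
  a <- gen_quant_table(50, 3, frac_up = 0.1, seed = 42)
  b <- gen_quant_table(50, 3, frac_up = 0.1, seed = 42)
  expect_identical(a, b)
  c <- gen_quant_table(50, 3, frac_up = 0.1, seed = 43)
  expect_false(identical(a$table$values, c$table$values))

  expect_identical(gen_stage_matrix(30, seed = 7), gen_stage_matrix(30, seed = 7))
  expect_identical(gen_decay_timecourse(5, 5, seed = 3),
                   gen_decay_timecourse(5, 5, seed = 3))
  expect_identical(gen_lifespans(20, c(a = 10), seed = 9),
                   gen_lifespans(20, c(a = 10), seed = 9))
  # generators do not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(gen_quant_table(10, 3, seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("quant-table generator plants the promised structure", {
  g <- gen_quant_table(1000, 3, frac_up = 0.05, frac_down = 0.03,
                       effect_log2 = 2, noise_sd = 0.5, missing_rate = 0.1,
                       seed = 2)
  expect_length(g$truth$changed_up, 50)
  expect_length(g$truth$changed_down, 30)
  expect_length(intersect(g$truth$changed_up, g$truth$changed_down), 0)
  ids <- rownames(g$table$values)
  expect_true(all(c(g$truth$changed_up, g$truth$changed_down) %in% ids))
  # every retained protein keeps >= 2 replicates despite missingness
  expect_true(all(rowSums(!is.na(g$table$values)) >= 2))
  # planted means sit near the effect after removing the replicate offsets
  centered <- sweep(g$table$values, 2, g$truth$replicate_offsets)
  up_mean <- mean(centered[g$truth$changed_up, ], na.rm = TRUE)
  expect_lt(abs(up_mean - 2), 3 * 0.5 / sqrt(150))

  # pure null: grand mean within 3 SE of zero, no truth sets
  n0 <- gen_quant_table(1000, 3, frac_up = 0, frac_down = 0, noise_sd = 0.5,
                        missing_rate = 0, seed = 3)
  expect_length(n0$truth$changed_up, 0)
  v <- sweep(n0$table$values, 2, n0$truth$replicate_offsets)
  expect_lt(abs(mean(v)), 3 * 0.5 / sqrt(length(v)))
  expect_true(all(rowSums(!is.na(n0$table$values)) == 3))

  expect_error(gen_quant_table(0, 3), "n_proteins")
  expect_error(gen_quant_table(10, 3, frac_up = 0.7, frac_down = 0.6), "<= 1")
  expect_error(gen_quant_table(10, 3, missing_rate = 0.5), "1/3")
})

test_that("stage-matrix generator plants an adult-specific block", {
  g <- gen_stage_matrix(200, n_adult_specific = 20, base_rpkm = 50,
                        specificity = 20, noise_cv = 0, seed = 1)
  planted <- g$matrix$rpkm[g$truth$adult_specific, ]
  expect_true(all(planted[, "YA"] == 1000))
  expect_true(all(planted[, colnames(planted) != "YA"] == 50))
  bg <- g$matrix$rpkm[setdiff(rownames(g$matrix$rpkm), g$truth$adult_specific), ]
  expect_true(all(bg == 50))

  # lognormal noise is mean-corrected: expectations hold at cv > 0
  gn <- gen_stage_matrix(3000, n_adult_specific = 0, base_rpkm = 50,
                         noise_cv = 0.3, seed = 2)
  expect_lt(abs(mean(gn$matrix$rpkm) - 50) / 50, 0.02)
  expect_true(all(gn$matrix$rpkm >= 0))
  expect_error(gen_stage_matrix(10, specificity = 0.5), "specificity")
})

test_that("gene-set generator controls overlap with the planted up-set", {
  g <- gen_quant_table(500, 3, frac_up = 0.1, seed = 5)
  u <- rownames(g$table$values)
  sets <- gen_gene_sets(g$truth, u, n_sets = 5, set_size = 40,
                        overlap_with_up = 0.5, seed = 6)
  expect_length(sets$sets, 5)
  # 20 guaranteed members from the up-set; the uniform remainder may add a few
  n_overlap <- length(intersect(sets$sets$planted, g$truth$changed_up))
  expect_gte(n_overlap, 20)
  expect_lte(n_overlap, 28)
  expect_true(all(vapply(sets$sets, length, 1L) == 40))
  # overlap demanding more than |changed_up| is rejected
  expect_error(gen_gene_sets(g$truth, u, n_sets = 2, set_size = 400,
                             overlap_with_up = 0.5, seed = 1), "exceeds")
  # zero-overlap planted set is enrichment-null on average
  # seeds disjoint from the table's own seed: a shared seed would replay the
  # same RNG stream and draw the very ids picked as changed_up
  folds <- vapply(1:10, function(s) {
    ss <- gen_gene_sets(g$truth, u, n_sets = 1, set_size = 50,
                        overlap_with_up = 0, seed = 100 + s)
    fisher_fold_enrichment(g$truth$changed_up, ss$sets$planted, u)$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.35)
})

test_that("planted enrichment arithmetic mirrors the designed proportions", {
  # a set built to mirror a 249/1796 background rate with 85% of a 40-hit
  # list inside it gives a fold near (34/40)/(249/1796) ~ 6
  g <- gen_quant_table(1796, 3, frac_up = 40 / 1796, effect_log2 = 3,
                       noise_sd = 0.3, missing_rate = 0, seed = 8)
  up <- g$truth$changed_up
  u <- rownames(g$table$values)
  set.seed(9)
  planted_set <- c(sample(up, 34), sample(setdiff(u, up), 249 - 34))
  e <- fisher_fold_enrichment(up, planted_set, u)
  expect_equal(e$fold, (34 / 40) / (249 / 1796), tolerance = 1e-12)
  expect_equal(round(e$fold), 6)
})

test_that("decay generator honors its closed forms and flags clipping", {
  d <- gen_decay_timecourse(3, 3, half_life_hours = 4, init_red = 100,
                            background_red = 0, green_synthesis_rate = 0,
                            timepoints = c(0, 4, 8), noise_sd = 0, seed = 1)
  conv <- d$timecourse[d$timecourse$converted, ]
  expect_equal(conv$red[conv$time_h == 4] / conv$red[conv$time_h == 0],
               rep(0.5, 3))
  expect_equal(d$clipped, 0)
  # the growth scenario reaches the designed 12 h fold exactly when noiseless
  d2 <- gen_decay_timecourse(2, 2, half_life_hours = 6, init_red = 100,
                             background_red = 0, green_synthesis_rate = 10,
                             timepoints = c(0, 6, 12), noise_sd = 0,
                             fold_12h = 1.5, seed = 1)
  un <- d2$timecourse[!d2$timecourse$converted, ]
  expect_equal(un$green[un$time_h == 12] / un$green[un$time_h == 0],
               rep(1.5, 2), tolerance = 1e-12)
  # heavy noise on a dim signal must clip and count it
  d3 <- gen_decay_timecourse(10, 10, half_life_hours = 2, init_red = 5,
                             background_red = 1, green_synthesis_rate = 0,
                             timepoints = c(0, 4, 8), noise_sd = 20, seed = 2)
  expect_gt(d3$clipped, 0)
  expect_true(all(d3$timecourse$red >= 0))
  expect_error(gen_decay_timecourse(2, 2, timepoints = c(2, 4)), "include 0")
})

test_that("lifespan generator matches the requested medians and censor rate", {
  g <- gen_lifespans(2000, c(a = 15, b = 18), shape = 4, censor_rate = 0.2,
                     seed = 11)
  tab <- g$table
  deaths_a <- tab$time[tab$group == "a" & tab$event == 1]
  expect_lt(abs(median(deaths_a) - 15) / 15, 0.05)
  expect_lt(abs(mean(tab$event == 0) - 0.2), 0.03)
  expect_true(all(tab$time > 0))
  expect_error(gen_lifespans(10, setNames(numeric(0), character(0))), "non-empty")
  expect_error(gen_lifespans(10, c(a = -1)), "medians")
})
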