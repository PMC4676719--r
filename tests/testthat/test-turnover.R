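# Photoconversion turnover: decay normalization, half-life estimation with
# censoring, synthesis-rate inference, reporter summaries.

noiseless_tc <- function(half_life, timepoints, background = 10,
                         init_red = 100, n = 3) {
  gen_decay_timecourse(n_converted = n, n_unconverted = n,
                       half_life_hours = half_life, init_red = init_red,
                       background_red = background,
                       green_synthesis_rate = 0, timepoints = timepoints,
                       noise_sd = 0, seed = 1)$timecourse
}

test_that("decay normalization removes background and anchors time 0 at 1", {
  tc <- noiseless_tc(4, c(0, 2, 4, 8))
  norm <- normalize_decay(tc)
  rel <- norm$rel
  expect_true(all(rel$rel[rel$time_h == 0] == 1))
  # noiseless exponential: rel(t) = 2^(-t/4) exactly
  for (t in c(2, 4, 8))
    expect_equal(unique(rel$rel[rel$time_h == t]), 2^(-t / 4),
                 tolerance = 1e-12)
  # background estimate equals the true level
  expect_true(all(abs(norm$background$B - 10) < 1e-12))
})

test_that("an animal identical to background normalizes to zero and bad anchors are excluded", {
  tc <- noiseless_tc(4, c(0, 2, 4))
  df <- as.data.frame(tc)
  flat <- df[df$animal_id == "group1_conv01", ]
  flat$red <- 10  # at background at every t
  flat$red[flat$time_h == 0] <- 110
  df[df$animal_id == "group1_conv01", ] <- flat
  rel <- normalize_decay(photo_timecourse(df))$rel
  expect_true(all(rel$rel[rel$animal_id == "group1_conv01" & rel$time_h > 0] == 0))

  # R(0) <= B(0): undefined normalization, excluded with a message
  df2 <- as.data.frame(tc)
  df2$red[df2$animal_id == "group1_conv02" & df2$time_h == 0] <- 5
  expect_message(out <- normalize_decay(photo_timecourse(df2)), "excluded")
  expect_true("group1_conv02" %in% out$excluded)
  expect_false("group1_conv02" %in% out$rel$animal_id)
})

test_that("both half-life methods are exact on noiseless exponentials", {
  # sampling grids contain the half-life, where the two estimators coincide
  for (hl in c(4, 6)) {
    tc <- noiseless_tc(hl, c(0, 2, 4, 6, 8))
    rel <- normalize_decay(tc)$rel
    est_i <- estimate_half_life(rel, "interpolation", n_boot = 0)
    est_l <- estimate_half_life(rel, "loglinear", n_boot = 0)
    expect_equal(est_i$half_life_hours, hl, tolerance = 1e-9)
    expect_equal(est_l$half_life_hours, hl, tolerance = 1e-9)
    expect_equal(est_i$decay_constant, log(2) / hl, tolerance = 1e-9)
    expect_false(est_i$censored)
  }
})

test_that("slow decay inside the window is censored, never a point estimate", {
  # half-life beyond the window: mean curve never crosses 0.5
  tc <- noiseless_tc(48, c(0, 4, 8, 12))
  est <- estimate_half_life(normalize_decay(tc)$rel, n_boot = 0)
  expect_true(est$censored)
  expect_equal(est$censor_bound, 12)
  expect_true(is.na(est$half_life_hours))

  # flat at 1 over a 36 h window
  tc36 <- noiseless_tc(1e6, c(0, 12, 24, 36))
  est36 <- estimate_half_life(normalize_decay(tc36)$rel, n_boot = 0)
  expect_true(est36$censored)
  expect_equal(est36$censor_bound, 36)
})

test_that("noisy half-life recovery stays within 15% at the study group size", {
  errs <- vapply(1:20, function(s) {
    d <- gen_decay_timecourse(15, 15, half_life_hours = 6, init_red = 100,
                              background_red = 10, green_synthesis_rate = 0,
                              timepoints = c(0, 2, 4, 6, 8, 12),
                              noise_sd = 5, seed = s)
    rel <- suppressMessages(normalize_decay(d$timecourse))$rel
    est <- estimate_half_life(rel, "interpolation", n_boot = 0)
    abs(est$half_life_hours - 6) / 6
  }, numeric(1))
  expect_gte(mean(errs <= 0.15), 0.9)
  # group-mean rel at the half-life is near 0.5
  d <- gen_decay_timecourse(15, 15, half_life_hours = 6, init_red = 100,
                            background_red = 10, green_synthesis_rate = 0,
                            timepoints = c(0, 2, 4, 6, 8, 12), noise_sd = 5,
                            seed = 3)
  rel <- suppressMessages(normalize_decay(d$timecourse))$rel
  expect_lt(abs(mean(rel$rel[rel$time_h == 6]) - 0.5), 0.1)
})

test_that("bootstrap CI brackets the point estimate deterministically", {
  d <- gen_decay_timecourse(12, 12, half_life_hours = 5, init_red = 100,
                            background_red = 10, green_synthesis_rate = 0,
                            timepoints = c(0, 2, 4, 6, 8, 12), noise_sd = 4,
                            seed = 2)
  rel <- suppressMessages(normalize_decay(d$timecourse))$rel
  a <- estimate_half_life(rel, "interpolation", n_boot = 200, seed = 5)
  b <- estimate_half_life(rel, "interpolation", n_boot = 200, seed = 5)
  expect_identical(a$ci, b$ci)
  expect_lte(a$ci[1], a$half_life_hours)
  expect_gte(a$ci[2], a$half_life_hours)
})

test_that("synthesis estimator matches closed forms and recovers planted rates", {
  # k = 0: pure linear rise 100 -> 150 over 12 h
  tot <- data.frame(animal_id = "a", time_h = c(0, 6, 12),
                    green = c(100, 125, 150))
  sy <- suppressWarnings(estimate_synthesis(tot, 0))
  expect_equal(sy$synthesis_rate, 50 / 12, tolerance = 1e-9)
  expect_equal(sy$fold_change_tmax, 1.5, tolerance = 1e-9)

  # s = 0: pure decay, model-implied fold change is exp(-k t_max)
  k <- log(2) / 6
  t <- c(0, 3, 6, 12)
  tot0 <- data.frame(animal_id = "a", time_h = t, green = 80 * exp(-k * t))
  sy0 <- suppressWarnings(estimate_synthesis(tot0, k))
  expect_equal(sy0$synthesis_rate, 0, tolerance = 1e-8)
  expect_equal(sy0$fold_change_tmax, exp(-k * 12), tolerance = 1e-8)
  expect_error(estimate_synthesis(tot0, -1), "decay_constant")

  # planted-growth scenario: +50% total at 12 h with t1/2 = 6, 5% noise
  errs <- vapply(1:20, function(s) {
    d <- gen_decay_timecourse(5, 10, half_life_hours = 6, init_red = 100,
                              background_red = 0, green_synthesis_rate = 10,
                              timepoints = c(0, 2, 4, 6, 8, 12), noise_sd = 5,
                              seed = s)
    un <- d$timecourse[!d$timecourse$converted, ]
    fit <- estimate_synthesis(un[, c("animal_id", "time_h", "green")],
                              log(2) / 6)
    abs(fit$synthesis_rate - 10) / 10
  }, numeric(1))
  expect_gte(mean(errs <= 0.2), 0.9)
})

test_that("reporter summaries scale to the reference and test pairs", {
  set.seed(6)
  d <- data.frame(group = rep(c("day4", "day13"), each = 20),
                  intensity = c(rnorm(20, 100, 5), rnorm(20, 500, 25)))
  s <- summarize_reporter(d, reference = "day4")
  expect_equal(s$summary$relative_mean[s$summary$group == "day4"], 1)
  expect_equal(s$summary$relative_mean[s$summary$group == "day13"], 5,
               tolerance = 0.1)
  expect_lt(s$tests$p, 0.001)

  # identical groups: ratio 1, comfortably non-significant
  d2 <- data.frame(group = rep(c("a", "b"), each = 15),
                   intensity = rep(rnorm(15, 50, 5), 2))
  s2 <- summarize_reporter(d2, reference = "a")
  expect_equal(s2$summary$relative_mean, c(1, 1))
  expect_gt(s2$tests$p, 0.99)

  # background subtraction feeds the ratio; bad reference rejected
  s3 <- summarize_reporter(d, background = c(day4 = 50, day13 = 50),
                           reference = "day4")
  expect_equal(s3$summary$relative_mean[s3$summary$group == "day13"],
               450 / 50, tolerance = 0.2)
  expect_error(summarize_reporter(d, background = c(day4 = 1e4, day13 = 0),
                                  reference = "day4"), "reference group mean")
})
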