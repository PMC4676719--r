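#' Photoconversion timecourse table
#'
#' Long-format per-animal fluorescence records from a photoconvertible
#' reporter (green-to-red) pulse-chase experiment: red intensity tracks the
#' converted (pre-existing) protein pool, green the total pool. Converted and
#' unconverted animals of the same group are imaged at the same timepoints;
#' the unconverted animals provide the red background.
#'
#' @param records data.frame with columns `animal_id`, `group`, `converted`
#'   (logical), `time_h` (hours, >= 0), `red`, `green`, and optionally
#'   `dropped` (animal died mid-course; excluded from estimates).
#' @return Object of class `photo_timecourse` (the validated data.frame).
#' @export
photo_timecourse <- function(records) {
  needed <- c("animal_id", "group", "converted", "time_h", "red", "green")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L)
    stop_bad_arg("missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(records$dropped)) records$dropped <- FALSE
  if (any(records$time_h < 0)) stop_bad_arg("negative timepoint(s)")
  by_animal <- split(records$time_h, records$animal_id)
  no_t0 <- names(by_animal)[!vapply(by_animal, function(t) any(t == 0), logical(1))]
  conv_ids <- unique(records$animal_id[records$converted])
  bad <- intersect(no_t0, conv_ids)
  if (length(bad) > 0L)
    stop_bad_arg("converted animal(s) missing a time-0 record: %s",
                 paste(bad, collapse = ", "))
  if (any(vapply(by_animal, function(t) anyDuplicated(t) > 0, logical(1))))
    stop_bad_arg("duplicated timepoints within an animal")
  n_drop <- length(unique(records$animal_id[records$dropped]))
  if (n_drop > 0L)
    message(n_drop, " dropped animal(s) excluded from estimates")
  structure(records[order(records$group, records$animal_id, records$time_h), ],
            class = c("photo_timecourse", "data.frame"))
}

#' Normalize converted red traces to background and time 0
#'
#' For each group and timepoint, the red background `B(t)` is the mean red
#' intensity over unconverted animals. Each converted animal's relative red
#' signal is `rel(t) = (R(t) - B(t)) / (R(0) - B(0))`, so `rel(0) = 1` and
#' `rel = 0` means the animal is indistinguishable from unconverted
#' background (complete removal of the converted pool). Noise can push
#' `rel` below 0; such values are retained and flagged, not clipped. Animals
#' with `R(0) <= B(0)` have an undefined normalization and are excluded with
#' a message; dropped (died) animals are excluded up front.
#'
#' @param tc a [photo_timecourse].
#' @return List with `rel` (data.frame `animal_id`, `group`, `time_h`, `rel`,
#'   `below_zero`), `background` (data.frame `group`, `time_h`, `B`, `n`),
#'   and `excluded` (animal ids removed for undefined normalization).
#' @export
normalize_decay <- function(tc) {
  stopifnot(inherits(tc, "photo_timecourse"))
  tc <- tc[!tc$dropped, ]
  unconv <- tc[!tc$converted, ]
  conv <- tc[tc$converted, ]
  if (nrow(unconv) == 0L) stop_bad_arg("no unconverted animals for background")
  bg <- stats::aggregate(red ~ group + time_h, unconv,
                         function(x) c(mean(x), length(x)))
  background <- data.frame(group = bg$group, time_h = bg$time_h,
                           B = bg$red[, 1], n = bg$red[, 2])
  key <- paste(background$group, background$time_h)
  need <- unique(paste(conv$group, conv$time_h))
  if (!all(need %in% key))
    stop_bad_arg("no unconverted background for group/timepoint(s): %s",
                 paste(setdiff(need, key), collapse = "; "))
  conv$B <- background$B[match(paste(conv$group, conv$time_h), key)]
  excluded <- character(0)
  out <- do.call(rbind, lapply(split(conv, conv$animal_id), function(a) {
    a <- a[order(a$time_h), ]
    denom <- a$red[a$time_h == 0] - a$B[a$time_h == 0]
    if (denom <= 0) {
      excluded <<- c(excluded, a$animal_id[1])
      return(NULL)
    }
    data.frame(animal_id = a$animal_id, group = a$group, time_h = a$time_h,
               rel = (a$red - a$B) / denom)
  }))
  if (length(excluded) > 0L)
    message(length(excluded), " animal(s) excluded: time-0 red at or below ",
            "background (undefined normalization)")
  if (is.null(out)) stop_bad_arg("no usable converted animals")
  out$below_zero <- out$rel < 0
  rownames(out) <- NULL
  list(rel = out, background = background, excluded = excluded)
}

#' Estimate protein half-life from normalized decay traces
#'
#' Two estimators of the half-life of the converted (pre-existing) protein
#' pool from per-animal relative red traces (one experimental group):
#' `interpolation` (default) finds the first linear-interpolated crossing of
#' 0.5 on the group-mean curve, matching bound-style statements ("less than 4
#' hours"); if the mean curve never reaches 0.5 inside the observation
#' window the estimate is right-censored and reported as
#' `> max(time)` with no point value. `loglinear` least-squares fits
#' `ln(rel)` against time over all animal-level points with `rel > 0` and
#' reports `t_half = ln(2)/|slope|`. A bootstrap confidence interval over
#' animals is attached for uncensored estimates.
#'
#' @param rel data.frame from [normalize_decay()]`$rel` (a single group).
#' @param method `"interpolation"` or `"loglinear"`.
#' @param n_boot bootstrap resamples over animals (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return Object of class `turnover_estimate`: list with `half_life_hours`
#'   (`NA` when censored), `censored`, `censor_bound` (the window end when
#'   censored), `decay_constant` (`ln(2)/t_half`), `method`, `ci`
#'   (percentile bootstrap; `NA` when censored), `mean_curve` (data.frame
#'   `time_h`, `mean_rel`, `sem`, `n`), `n_animals`.
#' @export
estimate_half_life <- function(rel, method = c("interpolation", "loglinear"),
                               n_boot = 1000L, seed = NULL, conf = 0.95) {
  method <- match.arg(method)
  if (length(unique(rel$group)) > 1L)
    stop_bad_arg("pass one group at a time (got: %s)",
                 paste(unique(rel$group), collapse = ", "))
  times <- sort(unique(rel$time_h))
  if (length(times) < 2L) stop_bad_arg("need at least 2 timepoints")
  t_max <- max(times)
  animals <- unique(rel$animal_id)

  point_est <- function(d) {
    if (method == "interpolation") {
      mc <- vapply(times, function(t) mean(d$rel[d$time_h == t]), numeric(1))
      interp_crossing(times, mc, 0.5)
    } else {
      pos <- d[d$rel > 0, ]
      if (nrow(pos) < 2L || length(unique(pos$time_h)) < 2L)
        stop_bad_arg("loglinear fit needs >= 2 timepoints with rel > 0")
      slope <- stats::coef(stats::lm(log(rel) ~ time_h, data = pos))[["time_h"]]
      if (slope >= 0) return(NA_real_)  # no decay inside the window
      log(2) / abs(slope)
    }
  }
  est <- point_est(rel)
  censored <- is.na(est) || est > t_max
  mc <- vapply(times, function(t) mean(rel$rel[rel$time_h == t]), numeric(1))
  sems <- vapply(times, function(t) {
    x <- rel$rel[rel$time_h == t]
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  ci <- c(NA_real_, NA_real_)
  if (!censored && n_boot > 0L && length(animals) > 1L) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      ids <- sample(animals, replace = TRUE)
      d <- do.call(rbind, lapply(ids, function(a) rel[rel$animal_id == a, ]))
      tryCatch({
        b <- point_est(d)
        if (is.na(b) || b > t_max) NA_real_ else b
      }, error = function(e) NA_real_)
    }, numeric(1)))
    ci <- unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
  }
  structure(list(
    half_life_hours = if (censored) NA_real_ else est,
    censored = censored,
    censor_bound = if (censored) t_max else NA_real_,
    decay_constant = if (censored) NA_real_ else log(2) / est,
    method = method, ci = ci,
    mean_curve = data.frame(time_h = times, mean_rel = mc, sem = sems,
                            n = vapply(times, function(t)
                              sum(rel$time_h == t), numeric(1))),
    n_animals = length(animals)),
    class = "turnover_estimate")
}

# First downward linear-interpolated crossing of `level` on curve (t, y);
# NA when the curve never reaches the level.
interp_crossing <- function(t, y, level) {
  if (y[1] <= level) return(t[1])
  for (i in seq_len(length(t) - 1L)) {
    if (y[i] > level && y[i + 1L] <= level) {
      return(t[i] + (y[i] - level) / (y[i] - y[i + 1L]) * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

#' @export
print.turnover_estimate <- function(x, ...) {
  if (x$censored) {
    cat("half-life > ", x$censor_bound, " h (censored; ", x$method,
        ", n = ", x$n_animals, " animals)\n", sep = "")
  } else {
    cat("half-life ", signif(x$half_life_hours, 3), " h (", x$method,
        ", n = ", x$n_animals, " animals; ", 100 * 0.95, "% CI [",
        signif(x$ci[1], 3), ", ", signif(x$ci[2], 3), "])\n", sep = "")
  }
  invisible(x)
}

#' Estimate the synthesis rate from total (green) fluorescence
#'
#' Fits the linear production-decay model `dT/dt = s - k*T`, with closed form
#' `T(t) = s/k + (T(0) - s/k) exp(-k t)` (and the limit `T(t) = s*t + T(0)`
#' when `k = 0`), to the group-mean total-fluorescence trajectory by least
#' squares with the decay constant `k` supplied (e.g. from
#' [estimate_half_life()]). With `k` fixed the model is linear in `s` and
#' `T(0)`. This is a model-based inference: the synthesis rate is whatever
#' production must accompany the measured removal to explain the observed
#' total-level trajectory.
#'
#' @param total data.frame with columns `animal_id`, `time_h`, `green`
#'   (one group).
#' @param decay_constant removal rate k in 1/h (>= 0).
#' @return List with `synthesis_rate` (signal units/h), `se` (from the linear
#'   fit), `T0`, `decay_constant`, `fold_change_tmax` (model-implied
#'   `T(t_max)/T(0)`), `t_max`, and `fit` (the `lm` object).
#' @export
estimate_synthesis <- function(total, decay_constant) {
  if (!is.numeric(decay_constant) || decay_constant < 0)
    stop_bad_arg("`decay_constant` must be >= 0")
  times <- sort(unique(total$time_h))
  if (length(times) < 2L) stop_bad_arg("need at least 2 timepoints")
  G <- vapply(times, function(t) mean(total$green[total$time_h == t]),
              numeric(1))
  k <- decay_constant
  if (k == 0) {
    fit <- stats::lm(G ~ times)
    s <- stats::coef(fit)[["times"]]
    T0 <- stats::coef(fit)[["(Intercept)"]]
    se <- summary(fit)$coefficients["times", "Std. Error"]
  } else {
    x1 <- (1 - exp(-k * times)) / k   # coefficient of s
    x2 <- exp(-k * times)             # coefficient of T(0)
    fit <- stats::lm(G ~ 0 + x1 + x2)
    s <- stats::coef(fit)[["x1"]]
    T0 <- stats::coef(fit)[["x2"]]
    se <- summary(fit)$coefficients["x1", "Std. Error"]
  }
  t_max <- max(times)
  pred_tmax <- if (k == 0) s * t_max + T0 else
    s / k + (T0 - s / k) * exp(-k * t_max)
  list(synthesis_rate = s, se = se, T0 = T0, decay_constant = k,
       fold_change_tmax = pred_tmax / T0, t_max = t_max, fit = fit)
}

#' Two-group reporter intensity summary
#'
#' Background-subtracted group means of a scalar fluorescence readout, scaled
#' to a reference group, with SEMs and a Welch two-sample test between any
#' named pair (classic pooled-variance Student test available by flag). This
#' is the generic comparison behind figure-style statements like "day 13
#' intensity is N-fold that of day 4".
#'
#' @param intensities data.frame with columns `group` and `intensity`
#'   (one row per animal).
#' @param background named numeric vector: background level per group
#'   (default 0 for all).
#' @param reference group label whose mean is scaled to 1.
#' @param welch use Welch's unequal-variance test (default TRUE).
#' @return List with `summary` (data.frame `group`, `n`, `mean`,
#'   `relative_mean`, `sem`, `relative_sem`) and `tests` (data.frame of all
#'   pairwise comparisons: `group_a`, `group_b`, `t`, `df`, `p`).
#' @export
summarize_reporter <- function(intensities, background = NULL,
                               reference = NULL, welch = TRUE) {
  if (!all(c("group", "intensity") %in% names(intensities)))
    stop_bad_arg("`intensities` needs columns `group` and `intensity`")
  groups <- unique(as.character(intensities$group))
  if (is.null(background)) background <- stats::setNames(rep(0, length(groups)), groups)
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop_bad_arg("unknown reference group '%s'", reference)
  vals <- lapply(groups, function(g) {
    x <- intensities$intensity[intensities$group == g] - (background[g] %||% 0)
    if (length(x) < 2L) stop_bad_arg("group '%s' has fewer than 2 animals", g)
    x
  })
  names(vals) <- groups
  ref_mean <- mean(vals[[reference]])
  if (ref_mean <= 0)
    stop_bad_arg("reference group mean <= 0 after background subtraction")
  summ <- data.frame(
    group = groups,
    n = vapply(vals, length, 1L),
    mean = vapply(vals, mean, 1),
    sem = vapply(vals, function(x) stats::sd(x) / sqrt(length(x)), 1),
    row.names = NULL)
  summ$relative_mean <- summ$mean / ref_mean
  summ$relative_sem <- summ$sem / ref_mean
  pairs <- utils::combn(groups, 2)
  tests <- do.call(rbind, apply(pairs, 2, function(pr) {
    tt <- stats::t.test(vals[[pr[1]]], vals[[pr[2]]], var.equal = !welch)
    data.frame(group_a = pr[1], group_b = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  list(summary = summ, tests = tests)
}
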