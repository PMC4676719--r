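# Seeded generators for every input type the pipeline consumes, each paired
# with the planted ground truth so recovery and calibration can be measured.

#' Generate a replicate log2 ratio table with planted changes
#'
#' Emulates the input of the differential-abundance stage: three paired
#' replicates of per-protein log2(old/young) ratios. A planted fraction of
#' proteins is shifted up or down by `effect_log2`; all proteins get
#' independent Normal noise per replicate, a per-replicate additive offset
#' (uniform in +/-`mixing_offset`) emulating inexact 1:1 mixing of the two
#' labeled samples (what median-centering corrects), and
#' missing-completely-at-random dropout capped so every protein keeps at
#' least 2 non-missing replicates.
#'
#' @param n_proteins,n_replicates table dimensions (n_replicates >= 2).
#' @param frac_up,frac_down planted fractions of increased/decreased proteins
#'   (`frac_up + frac_down <= 1`).
#' @param effect_log2 planted shift on the log2 scale.
#' @param noise_sd replicate noise SD (log2 units).
#' @param missing_rate per-cell missingness probability (< 1/3).
#' @param mixing_offset half-width of the per-replicate additive offset.
#' @param seed integer seed; identical arguments give identical output.
#' @return List with `table` (a [quant_table]) and `truth` (list with
#'   `changed_up`, `changed_down` protein-id sets and the generator
#'   parameters).
#' @export
gen_quant_table <- function(n_proteins, n_replicates = 3L, frac_up = 0.05,
                            frac_down = 0.0, effect_log2 = 2, noise_sd = 0.5,
                            missing_rate = 0.1, mixing_offset = 0.5,
                            seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  frac_up <- check_proportion(frac_up, "frac_up")
  frac_down <- check_proportion(frac_down, "frac_down")
  if (frac_up + frac_down > 1) stop_bad_arg("frac_up + frac_down must be <= 1")
  missing_rate <- check_proportion(missing_rate, "missing_rate")
  if (missing_rate >= 1 / 3) stop_bad_arg("missing_rate must be < 1/3")
  if (noise_sd < 0) stop_bad_arg("noise_sd must be >= 0")

  ids <- sprintf("P%04d", seq_len(n_proteins))
  with_seed(seed, {
    n_up <- round(frac_up * n_proteins)
    n_down <- round(frac_down * n_proteins)
    dir <- rep(0, n_proteins)
    planted <- sample(ids, n_up + n_down)
    up_ids <- planted[seq_len(n_up)]
    down_ids <- setdiff(planted, up_ids)
    dir[match(up_ids, ids)] <- 1
    dir[match(down_ids, ids)] <- -1

    offsets <- stats::runif(n_replicates, -mixing_offset, mixing_offset)
    v <- matrix(effect_log2 * dir, n_proteins, n_replicates) +
      matrix(stats::rnorm(n_proteins * n_replicates, sd = noise_sd),
             n_proteins, n_replicates)
    v <- sweep(v, 2, offsets, `+`)
    dimnames(v) <- list(ids, paste0("rep", seq_len(n_replicates)))

    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_proteins * n_replicates) < missing_rate,
                     n_proteins, n_replicates)
      # cap per-protein missingness so >= 2 replicates survive
      excess <- rowSums(miss) > n_replicates - 2L
      for (i in which(excess)) {
        hit <- which(miss[i, ])
        keep_missing <- sample(hit, n_replicates - 2L)
        miss[i, ] <- FALSE
        miss[i, keep_missing] <- TRUE
      }
      v[miss] <- NA_real_
    }
    list(table = quant_table(v, min_replicates = 2L),
         truth = list(changed_up = up_ids, changed_down = down_ids,
                      effect_log2 = effect_log2, noise_sd = noise_sd,
                      replicate_offsets = offsets, seed = seed))
  })
}

#' Generate a stage expression matrix with a planted adult-specific cluster
#'
#' Background proteins get a stage-independent expected RPKM of `base_rpkm`;
#' the planted adult-specific proteins get `base_rpkm * specificity` in the
#' final (adult) stage and `base_rpkm` elsewhere. Noise is multiplicative
#' lognormal with coefficient of variation `noise_cv`, mean-corrected so the
#' expectations above hold exactly.
#'
#' @param n_proteins number of rows.
#' @param stages ordered stage labels; the last is the adult stage.
#' @param n_adult_specific planted cluster size (<= n_proteins).
#' @param base_rpkm baseline expected expression (> 0).
#' @param specificity adult-stage fold-up of planted rows (>= 1).
#' @param noise_cv lognormal coefficient of variation (0 = noiseless).
#' @param seed integer seed.
#' @return List with `matrix` (a [stage_matrix]) and `truth` (list with
#'   `adult_specific` ids and the parameters).
#' @export
gen_stage_matrix <- function(n_proteins, stages = c("EE", "LE", "L1", "L2",
                                                    "L3", "L4", "YA"),
                             n_adult_specific = 0L, base_rpkm = 50,
                             specificity = 20, noise_cv = 0.3, seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_adult_specific <- check_count(n_adult_specific, "n_adult_specific", min = 0L)
  if (n_adult_specific > n_proteins)
    stop_bad_arg("n_adult_specific must be <= n_proteins")
  base_rpkm <- check_positive(base_rpkm, "base_rpkm")
  if (specificity < 1) stop_bad_arg("specificity must be >= 1")
  if (noise_cv < 0) stop_bad_arg("noise_cv must be >= 0")

  ids <- sprintf("P%04d", seq_len(n_proteins))
  n_stage <- length(stages)
  with_seed(seed, {
    adult <- sample(ids, n_adult_specific)
    mu <- matrix(base_rpkm, n_proteins, n_stage, dimnames = list(ids, stages))
    mu[match(adult, ids), n_stage] <- base_rpkm * specificity
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- matrix(exp(stats::rnorm(n_proteins * n_stage, sd = sdlog) -
                          sdlog^2 / 2), n_proteins, n_stage)
      mu <- mu * noise
    }
    list(matrix = stage_matrix(mu, stage_labels = stages),
         truth = list(adult_specific = adult, base_rpkm = base_rpkm,
                      specificity = specificity, noise_cv = noise_cv,
                      seed = seed))
  })
}

#' Generate gene sets overlapping a planted hit list
#'
#' Builds `n_sets` annotation sets over the universe of a generated ratio
#' table: one designated `"planted"` set draws `overlap_with_up` of its
#' members from the truth's `changed_up` proteins, the rest uniformly from
#' the remainder; all other sets are drawn uniformly from the universe.
#'
#' @param truth the `truth` element of a [gen_quant_table()] result (needs
#'   `changed_up`).
#' @param universe character vector of protein ids.
#' @param n_sets number of sets (the first is the planted one).
#' @param set_size members per set (<= universe size).
#' @param overlap_with_up proportion of the planted set drawn from
#'   `changed_up`.
#' @param seed integer seed.
#' @return A [gene_set_collection]; the planted set is named `"planted"`,
#'   the rest `"random01"`, `"random02"`, ...
#' @export
gen_gene_sets <- function(truth, universe, n_sets = 10L, set_size = 50L,
                          overlap_with_up = 0.5, seed = 1L) {
  n_sets <- check_count(n_sets, "n_sets")
  set_size <- check_count(set_size, "set_size")
  overlap_with_up <- check_proportion(overlap_with_up, "overlap_with_up")
  universe <- unique(as.character(universe))
  if (set_size > length(universe))
    stop_bad_arg("set_size exceeds universe size")
  up <- intersect(truth$changed_up, universe)
  n_from_up <- round(overlap_with_up * set_size)
  if (n_from_up > length(up))
    stop_bad_arg("requested overlap (%d) exceeds |changed_up| (%d)",
                 n_from_up, length(up))
  with_seed(seed, {
    from_up <- sample(up, n_from_up)
    planted <- c(from_up,
                 sample(setdiff(universe, from_up), set_size - n_from_up))
    sets <- c(list(planted = planted),
              stats::setNames(
                lapply(seq_len(n_sets - 1L),
                       function(i) sample(universe, set_size)),
                sprintf("random%02d", seq_len(max(0L, n_sets - 1L)))))
    gene_set_collection(sets[seq_len(n_sets)], universe)
  })
}

#' Generate photoconversion decay timecourses
#'
#' Converted animals' red signal follows
#' `red(t) = background_red + init_red * 2^(-t / half_life_hours) + noise`;
#' unconverted animals give `background_red + noise`. All animals' green
#' (total) signal follows the production-decay model `dG/dt = s - k G` with
#' `k = ln(2)/half_life_hours` and `G(0)` chosen so the noiseless 12-hour
#' total change equals `fold_12h` when `s > 0` (the observed-growth
#' scenario), or `G(0) = init_red` for pure decay (`s = 0`). Negative
#' post-noise signals are clipped at 0 and flagged.
#'
#' @param n_converted,n_unconverted animals per arm.
#' @param half_life_hours true half-life (> 0).
#' @param init_red converted-pool signal at time 0 (above background).
#' @param background_red red background level.
#' @param green_synthesis_rate production rate s (signal units/h).
#' @param timepoints observation times in hours (must include 0).
#' @param noise_sd additive Normal noise SD (signal units).
#' @param fold_12h target noiseless total fold change at 12 h when `s > 0`.
#' @param group group label stamped on all animals.
#' @param seed integer seed.
#' @return List with `timecourse` (a [photo_timecourse]), `clipped` (count of
#'   clipped negative signals), and `truth` (true half-life, synthesis rate,
#'   `G0`, parameters).
#' @export
gen_decay_timecourse <- function(n_converted = 15L, n_unconverted = 15L,
                                 half_life_hours = 6, init_red = 100,
                                 background_red = 10,
                                 green_synthesis_rate = 10,
                                 timepoints = c(0, 2, 4, 6, 8, 12),
                                 noise_sd = 5, fold_12h = 1.5,
                                 group = "group1", seed = 1L) {
  n_converted <- check_count(n_converted, "n_converted")
  n_unconverted <- check_count(n_unconverted, "n_unconverted")
  half_life_hours <- check_positive(half_life_hours, "half_life_hours")
  if (!0 %in% timepoints) stop_bad_arg("timepoints must include 0")
  if (noise_sd < 0) stop_bad_arg("noise_sd must be >= 0")
  timepoints <- sort(unique(timepoints))
  k <- log(2) / half_life_hours
  s <- green_synthesis_rate
  G0 <- if (s > 0) {
    t_ref <- 12
    (s / k) * (1 - exp(-k * t_ref)) / (fold_12h - exp(-k * t_ref))
  } else init_red
  green_mean <- s / k + (G0 - s / k) * exp(-k * timepoints)

  with_seed(seed, {
    clipped <- 0L
    mk <- function(prefix, n, converted) {
      do.call(rbind, lapply(seq_len(n), function(i) {
        red_mean <- background_red +
          if (converted) init_red * 2^(-timepoints / half_life_hours) else 0
        red <- red_mean + stats::rnorm(length(timepoints), sd = noise_sd)
        green <- green_mean + stats::rnorm(length(timepoints), sd = noise_sd)
        neg <- red < 0 | green < 0
        clipped <<- clipped + sum(neg)
        data.frame(animal_id = sprintf("%s_%s%02d", group, prefix, i),
                   group = group,
                   converted = converted, time_h = timepoints,
                   red = pmax(red, 0), green = pmax(green, 0))
      }))
    }
    rec <- rbind(mk("conv", n_converted, TRUE),
                 mk("unconv", n_unconverted, FALSE))
    list(timecourse = photo_timecourse(rec), clipped = clipped,
         truth = list(true_half_life_hours = half_life_hours,
                      true_synthesis_rate = s, G0 = G0,
                      decay_constant = k, init_red = init_red,
                      background_red = background_red, noise_sd = noise_sd,
                      seed = seed))
  })
}

#' Generate two-group (or k-group) lifespan data
#'
#' Event times are Weibull with the given shape and a group-specific scale
#' solving the requested median (`scale = median / log(2)^(1/shape)`).
#' Censoring is independent of the death process: with probability
#' `censor_rate` an animal is censored at a uniform time before its death.
#'
#' @param n_per_group animals per group.
#' @param median_days named numeric vector: requested median lifespan (days)
#'   per group.
#' @param shape Weibull shape (> 0; larger = more deterministic deaths).
#' @param censor_rate per-animal censoring probability.
#' @param seed integer seed.
#' @return List with `table` (a [lifespan_table]) and `truth`
#'   (`true_median_lifespans`, parameters).
#' @export
gen_lifespans <- function(n_per_group = 100L,
                          median_days = c(control = 15, treated = 18),
                          shape = 4, censor_rate = 0.1, seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group")
  if (length(median_days) == 0L || is.null(names(median_days)))
    stop_bad_arg("`median_days` must be a named, non-empty vector")
  if (any(median_days <= 0)) stop_bad_arg("medians must be > 0")
  shape <- check_positive(shape, "shape")
  censor_rate <- check_proportion(censor_rate, "censor_rate")
  with_seed(seed, {
    rec <- do.call(rbind, lapply(names(median_days), function(g) {
      scale <- median_days[[g]] / log(2)^(1 / shape)
      t_death <- stats::rweibull(n_per_group, shape = shape, scale = scale)
      cens <- stats::runif(n_per_group) < censor_rate
      t_obs <- ifelse(cens, stats::runif(n_per_group, 0, t_death), t_death)
      data.frame(group = g, time = pmax(t_obs, .Machine$double.eps),
                 event = as.integer(!cens),
                 censor_reason = ifelse(cens, "censored", NA_character_))
    }))
    list(table = lifespan_table(rec),
         truth = list(true_median_lifespans = median_days, shape = shape,
                      censor_rate = censor_rate, seed = seed))
  })
}
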