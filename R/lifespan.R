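#' Per-animal lifespan table
#'
#' One row per animal: group label, days of adulthood at death or censoring,
#' and the event indicator. Animals removed from observation for reasons
#' unrelated to aging death (internal progeny hatching, bursting, loss) are
#' right-censored.
#'
#' @param records data.frame with columns `group`, `time` (> 0 days), `event`
#'   (1 = death, 0 = censored; logical accepted) and optionally
#'   `censor_reason`.
#' @return Object of class `lifespan_table` (the validated data.frame).
#' @export
lifespan_table <- function(records) {
  needed <- c("group", "time", "event")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L)
    stop_bad_arg("missing column(s): %s", paste(miss, collapse = ", "))
  if (any(records$time <= 0))
    stop_bad_arg("non-positive lifespan time(s) at row(s): %s",
                 paste(which(records$time <= 0), collapse = ", "))
  records$event <- as.integer(records$event)
  if (!all(records$event %in% c(0L, 1L)))
    stop_bad_arg("`event` must be 0 (censored) or 1 (death)")
  if (is.null(records$censor_reason)) records$censor_reason <- NA_character_
  empty <- table(records$group) == 0
  if (length(unique(records$group)) == 0L) stop_bad_arg("no groups")
  structure(records, class = c("lifespan_table", "data.frame"))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit survival curves with right-censoring (censored animals leave
#' the risk set after their time). The median lifespan uses the step-function
#' convention: the first observed event time at which `S(t) <= 0.5`; it is
#' flagged undefined when the curve never reaches 0.5.
#'
#' @param table a [lifespan_table].
#' @return Object of class `survival_result`: list with `curves` (data.frame
#'   `group`, `time`, `surv`, `n_risk`, `n_event`, `n_censor`), `medians`
#'   (named numeric, `NA` when undefined), `n` (animals per group), and
#'   `survfit` (the underlying [survival::survfit] object).
#' @export
km_estimate <- function(table) {
  stopifnot(inherits(table, "lifespan_table"))
  groups <- unique(as.character(table$group))
  no_event <- vapply(groups, function(g)
    sum(table$event[table$group == g]) == 0L, logical(1))
  if (any(no_event))
    warning("group(s) with no death events (median undefined): ",
            paste(groups[no_event], collapse = ", "), call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = table)
  strata_grp <- if (is.null(fit$strata)) groups else
    sub("^group=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(group = strata_grp, time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       n_censor = fit$n.censor, row.names = NULL)
  medians <- vapply(groups, function(g) {
    cg <- curves[curves$group == g & curves$n_event > 0, ]
    hit <- cg$time[cg$surv <= 0.5]
    if (length(hit) == 0L) NA_real_ else min(hit)
  }, numeric(1))
  structure(list(curves = curves, medians = medians,
                 n = table(factor(table$group, levels = groups)),
                 survfit = fit),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("survival_result:", paste(names(x$medians), collapse = ", "), "\n")
  for (g in names(x$medians)) {
    cat("  ", g, ": n = ", x$n[[g]], ", median = ",
        if (is.na(x$medians[[g]])) "undefined" else
          paste0(x$medians[[g]], " days"), "\n", sep = "")
  }
  invisible(x)
}

#' Log-rank comparison of two lifespan groups
#'
#' Standard observed-minus-expected chi-squared log-rank test over the pooled
#' event times of two groups, respecting censoring; tied event times
#' contribute jointly.
#'
#' @param table a [lifespan_table] containing both groups.
#' @param groups character vector of the two group labels to compare
#'   (default: the first two in the table).
#' @return List with `statistic` (chi-squared, 1 df), `p`, `groups`.
#' @export
logrank_test <- function(table, groups = NULL) {
  stopifnot(inherits(table, "lifespan_table"))
  all_groups <- unique(as.character(table$group))
  if (is.null(groups)) groups <- all_groups[1:2]
  if (length(groups) != 2L || !all(groups %in% all_groups))
    stop_bad_arg("`groups` must name two groups present in the table")
  sub <- table[table$group %in% groups, ]
  if (any(vapply(groups, function(g)
    sum(sub$event[sub$group == g]) == 0L, logical(1))))
    stop_bad_arg("both groups must contain at least one death event")
  # Degenerate but well-defined case: identical samples give statistic 0.
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = sub)
  stat <- sd_$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       groups = groups)
}

#' Percent change in median lifespan versus a reference group
#'
#' @param result a `survival_result` from [km_estimate()].
#' @param reference_group label of the reference group (its median must be
#'   defined).
#' @return data.frame `group`, `median`, `extension_pct`
#'   (`100 * (median - median_ref)/median_ref`); groups with undefined
#'   medians are flagged (`NA`) and a warning lists them.
#' @export
median_extension <- function(result, reference_group) {
  stopifnot(inherits(result, "survival_result"))
  med <- result$medians
  if (!reference_group %in% names(med))
    stop_bad_arg("unknown reference group '%s'", reference_group)
  ref <- med[[reference_group]]
  if (is.na(ref)) stop_bad_arg("reference group median is undefined")
  undef <- names(med)[is.na(med)]
  if (length(undef) > 0L)
    warning("median undefined for group(s): ", paste(undef, collapse = ", "),
            call. = FALSE)
  data.frame(group = names(med), median = unname(med),
             extension_pct = 100 * (unname(med) - ref) / ref,
             row.names = NULL)
}
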