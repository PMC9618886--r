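# Clinical statistics layer: Kaplan-Meier estimation with log-rank
# comparison (via the survival package), flow-cytometry subset proportions,
# and greedy 1:k case-control matching. The Fisher exact test lives in
# exact-tests.R.

#' Kaplan-Meier fit for one group
#'
#' Product-limit estimate of overall survival with log-log (complementary
#' log) confidence intervals. The median is the smallest time at which the
#' survival estimate drops to 0.5 or below; when the curve never reaches
#' 0.5, the median is "not reached" (`NA`).
#'
#' @param time follow-up times in months (>= 0).
#' @param event logical or 0/1; `TRUE`/1 = death, `FALSE`/0 = censored.
#' @return object of class `km_curve`: list with `time`, `surv` (stepwise
#'   S(t) at event times), `median`, `median_ci` (95% CI, `NA` = not
#'   reached), `n`, `n_events`, and the underlying `survival::survfit` fit.
#' @export
km_fit <- function(time, event) {
  time <- as.numeric(time)
  if (length(time) < 1L || anyNA(time) || any(time < 0))
    tmerep_error("survival times must be non-negative and non-missing",
                 "tmerep_argument_error")
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  structure(
    list(time = fit$time, surv = fit$surv,
         median = unname(tab["median"]),
         median_ci = unname(c(tab["0.95LCL"], tab["0.95UCL"])),
         n = length(time), n_events = sum(event), fit = fit),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else sprintf("%.1f months", x$median)
  ci <- vapply(x$median_ci, function(v)
    if (is.na(v)) "NR" else sprintf("%.1f", v), "")
  cat(sprintf("<km_curve> n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  median survival %s (95%% CI %s-%s)\n", med, ci[1], ci[2]))
  invisible(x)
}

#' Log-rank test between two survival groups
#'
#' One-degree-of-freedom chi-squared comparison of the survival functions.
#' When neither group has any event the curves are uninformative and p = 1
#' by convention.
#'
#' @param time_a,event_a,time_b,event_b times and event indicators per group.
#' @return list with `statistic` (chi-squared, 1 df) and `p.value`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) < 1L || length(time_b) < 1L)
    tmerep_error("both groups must be non-empty", "tmerep_argument_error")
  ev_a <- as.integer(as.logical(event_a)); ev_b <- as.integer(as.logical(event_b))
  if (sum(ev_a) + sum(ev_b) == 0L)
    return(list(statistic = 0, p.value = 1))
  dat <- data.frame(time = c(time_a, time_b), event = c(ev_a, ev_b),
                    group = rep(c("A", "B"), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  stat <- unname(sd$chisq)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Flow-cytometry subset proportions
#'
#' Each population's proportion is its event count divided by the total
#' lymphocyte count; the CD4/CD8 ratio is the ratio of the two TIL-T
#' compartments (undefined, `NA`, when the CD8 count is 0).
#'
#' @param counts named numeric vector/list of per-population event counts.
#'   Entries `cd4_til_t` and `cd8_til_t` feed the ratio when present.
#' @param total total lymphocyte count (> 0); every subset count must not
#'   exceed it.
#' @return list with `proportions` (named vector) and `cd4_cd8_ratio`.
#' @export
subset_proportions <- function(counts, total) {
  counts <- unlist(counts)
  if (is.na(total) || total <= 0)
    tmerep_error("total lymphocyte count must be positive", "tmerep_argument_error")
  if (any(counts < 0) || any(counts > total))
    tmerep_error("each subset count must lie in [0, total]", "tmerep_argument_error")
  ratio <- NA_real_
  if (all(c("cd4_til_t", "cd8_til_t") %in% names(counts)) &&
      counts[["cd8_til_t"]] > 0)
    ratio <- counts[["cd4_til_t"]] / counts[["cd8_til_t"]]
  list(proportions = counts / total, cd4_cd8_ratio = ratio)
}

#' Greedy 1:k case-control matching
#'
#' Matches each case to `k` controls, exactly on the categorical key and by
#' nearest neighbor on the continuous key within a caliper, without
#' replacement. Cases are processed in order of difficulty (fewest eligible
#' controls first); ties in distance are broken by the lexicographically
#' smaller control `sample_id`, so the result is deterministic.
#'
#' @param cases,pool data.frames with a `sample_id` column plus the key
#'   columns.
#' @param k controls per case (default 2).
#' @param continuous_key column name of the continuous matching variable.
#' @param categorical_key optional column name requiring an exact match.
#' @param caliper maximum allowed absolute difference on the continuous key
#'   (default `Inf`).
#' @return named list: for each case `sample_id`, the character vector of
#'   its `k` matched control ids (nearest first).
#' @export
match_controls <- function(cases, pool, k = 2L, continuous_key,
                           categorical_key = NULL, caliper = Inf) {
  stopifnot(is.data.frame(cases), "sample_id" %in% names(cases),
            continuous_key %in% names(cases))
  if (!is.data.frame(pool) || nrow(pool) == 0L)
    tmerep_error("control pool is empty", "tmerep_matching_error")
  eligible_for <- function(i, available) {
    ok <- available &
      abs(pool[[continuous_key]] - cases[[continuous_key]][i]) <= caliper
    if (!is.null(categorical_key))
      ok <- ok & pool[[categorical_key]] == cases[[categorical_key]][i]
    which(ok)
  }
  available <- rep(TRUE, nrow(pool))
  n_elig <- vapply(seq_len(nrow(cases)), function(i)
    length(eligible_for(i, available)), integer(1))
  order_cases <- order(n_elig, cases$sample_id)
  out <- vector("list", nrow(cases))
  names(out) <- cases$sample_id
  for (i in order_cases) {
    elig <- eligible_for(i, available)
    if (length(elig) < k)
      tmerep_error(sprintf("case '%s': only %d eligible control(s), need %d",
                           cases$sample_id[i], length(elig), k),
                   "tmerep_matching_error")
    dist <- abs(pool[[continuous_key]][elig] - cases[[continuous_key]][i])
    pick <- elig[order(dist, pool$sample_id[elig])][seq_len(k)]
    available[pick] <- FALSE
    out[[cases$sample_id[i]]] <- pool$sample_id[pick]
  }
  out
}
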