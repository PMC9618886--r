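# Two-group comparisons: per-metric Mann-Whitney tests, per-V-family usage
# tests with a global permutation test, shared (public) CDR3 detection, and
# per-clone differential frequency testing.

#' Compare one metric between two sample groups
#'
#' Two-sided Mann-Whitney test plus group medians and ranges. Direction is
#' the group with the higher median (`"A"`, `"B"`, or `"none"`).
#'
#' @param values_a,values_b numeric vectors of per-sample metric values.
#' @param metric label for printing.
#' @return object of class `metric_comparison`: list with `metric`,
#'   `median_a`, `range_a`, `median_b`, `range_b`, `statistic`, `p.value`,
#'   `direction`, `method`.
#' @export
compare_metric <- function(values_a, values_b, metric = "metric") {
  mw <- mann_whitney(values_a, values_b)
  med_a <- stats::median(values_a); med_b <- stats::median(values_b)
  structure(
    list(metric = metric,
         n_a = length(values_a), n_b = length(values_b),
         median_a = med_a, range_a = range(values_a),
         median_b = med_b, range_b = range(values_b),
         statistic = mw$statistic, p.value = mw$p.value,
         direction = if (med_a > med_b) "A" else if (med_b > med_a) "B" else "none",
         method = mw$method),
    class = "metric_comparison"
  )
}

#' @export
print.metric_comparison <- function(x, ...) {
  cat(sprintf("<metric_comparison> %s (%s Mann-Whitney)\n", x$metric, x$method))
  cat(sprintf("  A (n=%d): median %.4g (range %.4g-%.4g)\n",
              x$n_a, x$median_a, x$range_a[1], x$range_a[2]))
  cat(sprintf("  B (n=%d): median %.4g (range %.4g-%.4g)\n",
              x$n_b, x$median_b, x$range_b[1], x$range_b[2]))
  cat(sprintf("  U = %g, two-sided p = %.4g, higher in %s\n",
              x$statistic, x$p.value, x$direction))
  invisible(x)
}

harmonize_usage <- function(usage_list, families = NULL) {
  if (is.null(families))
    families <- sort(unique(unlist(lapply(usage_list, names))))
  t(vapply(usage_list, function(u) {
    out <- stats::setNames(numeric(length(families)), families)
    shared <- intersect(names(u), families)
    out[shared] <- u[shared]
    out
  }, numeric(length(families))))
}

#' Compare V-family usage between two groups
#'
#' Per family, a two-sided Mann-Whitney test on per-sample usage fractions
#' (families missing from a sample count as 0). A global test of the whole
#' usage vector is reported separately: a chi-squared-style distance between
#' group mean usage vectors, `sum_f (mean_a - mean_b)^2 / mean_pooled`, with
#' a permutation p-value over sample labels.
#'
#' @param usage_a,usage_b lists of named usage vectors (one per sample), as
#'   returned by [v_family_usage()].
#' @param n_perm permutations for the global test (default 1000).
#' @param seed seed for the permutation draw (default 1).
#' @return list with `per_family` (list of `metric_comparison`, one per
#'   family) and `global` (list with `statistic`, `p.value`, `n_perm`).
#' @export
compare_v_usage <- function(usage_a, usage_b, n_perm = 1000L, seed = 1L) {
  fams <- sort(unique(c(unlist(lapply(usage_a, names)),
                        unlist(lapply(usage_b, names)))))
  if (length(fams) == 0L)
    tmerep_error("no V families present in either group", "tmerep_annotation_error")
  mat_a <- harmonize_usage(usage_a, fams)
  mat_b <- harmonize_usage(usage_b, fams)
  per_family <- lapply(fams, function(f)
    compare_metric(mat_a[, f], mat_b[, f], metric = f))
  names(per_family) <- fams

  pooled <- rbind(mat_a, mat_b)
  na <- nrow(mat_a)
  usage_distance <- function(idx_a) {
    ma <- colMeans(pooled[idx_a, , drop = FALSE])
    mb <- colMeans(pooled[-idx_a, , drop = FALSE])
    mp <- (ma + mb) / 2
    keep <- mp > 0
    sum((ma[keep] - mb[keep])^2 / mp[keep])
  }
  obs <- usage_distance(seq_len(na))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    usage_distance(sample(nrow(pooled), na)), numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p_global <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(per_family = per_family,
       global = list(statistic = obs, p.value = p_global, n_perm = n_perm))
}

# Per-sample frequency matrix keyed on amino-acid CDR3 (sharing key):
# rows = samples, columns = cdr3_aa, absent = 0.
aa_frequency_matrix <- function(reps) {
  per_sample <- lapply(reps, function(tme) {
    stopifnot(inherits(tme, "tme_repertoire"))
    cl <- tme$clones[nzchar(tme$clones$cdr3_aa), , drop = FALSE]
    tapply(cl$frequency, cl$cdr3_aa, sum)
  })
  ids <- vapply(reps, function(r) r$sample_id, "")
  all_aa <- sort(unique(unlist(lapply(per_sample, names))))
  mat <- matrix(0, nrow = length(reps), ncol = length(all_aa),
                dimnames = list(ids, all_aa))
  for (i in seq_along(per_sample))
    mat[i, names(per_sample[[i]])] <- as.numeric(per_sample[[i]])
  mat
}

#' Find shared (public) CDR3 clones across samples
#'
#' Sharing is keyed on the amino-acid CDR3 sequence: the same amino-acid
#' junction counts as shared even when the nucleotide rearrangements differ.
#' A clone qualifies when present (frequency > 0) in at least `min_samples`
#' samples (`"all"` = every sample). Results are sorted by descending sample
#' count, then descending total frequency.
#'
#' @param reps list of `tme_repertoire` (at least 2).
#' @param min_samples integer, or `"all"`.
#' @return data.frame with `cdr3_aa`, `n_samples`, `total_frequency`,
#'   `samples_present` (comma-separated ids); the full sample-by-CDR3
#'   frequency matrix is attached as attribute `frequencies`.
#' @export
find_shared_clones <- function(reps, min_samples = 2L) {
  if (length(reps) < 2L)
    tmerep_error("need at least 2 repertoires to assess sharing",
                 "tmerep_argument_error")
  if (identical(min_samples, "all")) min_samples <- length(reps)
  if (min_samples > length(reps))
    tmerep_error("min_samples exceeds the number of samples",
                 "tmerep_argument_error")
  mat <- aa_frequency_matrix(reps)
  n_present <- colSums(mat > 0)
  keep <- n_present >= min_samples
  total <- colSums(mat)
  out <- data.frame(
    cdr3_aa = colnames(mat)[keep],
    n_samples = n_present[keep],
    total_frequency = total[keep],
    samples_present = vapply(which(keep), function(j)
      paste(rownames(mat)[mat[, j] > 0], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_samples, -out$total_frequency, out$cdr3_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frequencies") <- mat
  out
}

#' Differentially abundant CDR3 clones between two groups
#'
#' Candidate clones are amino-acid CDR3s present in at least `min_samples`
#' samples overall. For each candidate, a two-sided Mann-Whitney test on the
#' per-sample frequencies (absent = 0) compares the two groups; clones with
#' unadjusted `p < alpha` are returned, annotated with the direction (which
#' group has the higher mean frequency). A Benjamini-Hochberg column is
#' added when `adjust = TRUE`.
#'
#' @param reps_a,reps_b lists of `tme_repertoire`, one per group.
#' @param alpha significance threshold on the unadjusted p (default 0.05).
#' @param min_samples minimum samples a candidate must appear in (default 2).
#' @param adjust add a BH-adjusted p column (default `FALSE`).
#' @return data.frame of flagged clones (`cdr3_aa`, `p.value`, `direction`,
#'   `median_a`, `median_b`, `n_present`, optionally `p.adjusted`), sorted by
#'   p. The unfiltered candidate table is attached as attribute
#'   `all_candidates`.
#' @export
differential_clones <- function(reps_a, reps_b, alpha = 0.05,
                                min_samples = 2L, adjust = FALSE) {
  mat <- aa_frequency_matrix(c(reps_a, reps_b))
  grp_a <- seq_along(reps_a)
  n_present <- colSums(mat > 0)
  cand <- which(n_present >= min_samples)
  if (length(cand) == 0L) {
    out <- data.frame(cdr3_aa = character(), p.value = numeric(),
                      direction = character(), median_a = numeric(),
                      median_b = numeric(), n_present = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "all_candidates") <- out
    return(out)
  }
  res <- lapply(cand, function(j) {
    fa <- mat[grp_a, j]; fb <- mat[-grp_a, j]
    mw <- mann_whitney(fa, fb)
    data.frame(cdr3_aa = colnames(mat)[j], p.value = mw$p.value,
               direction = if (mean(fa) > mean(fb)) "A"
                           else if (mean(fb) > mean(fa)) "B" else "none",
               median_a = stats::median(fa), median_b = stats::median(fb),
               n_present = n_present[j], stringsAsFactors = FALSE)
  })
  all_cand <- do.call(rbind, res)
  rownames(all_cand) <- NULL
  if (adjust)
    all_cand$p.adjusted <- stats::p.adjust(all_cand$p.value, method = "BH")
  out <- all_cand[all_cand$p.value < alpha, , drop = FALSE]
  out <- out[order(out$p.value, out$cdr3_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_candidates") <- all_cand
  out
}
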