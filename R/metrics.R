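# Repertoire summary statistics on the TME repertoire: richness, Shannon
# entropy, clonality score, top-N clone proportion, V-family usage.
#
# All metrics operate on the renormalized TME frequencies (post tumor
# removal). Each frequency-based operation also accepts a bare numeric
# frequency vector, which the property tests use.

tme_frequencies <- function(x) {
  if (inherits(x, "tme_repertoire")) {
    f <- x$clones$frequency
  } else if (is.numeric(x)) {
    f <- x
  } else {
    tmerep_error("expected a tme_repertoire or a numeric frequency vector",
                 "tmerep_argument_error")
  }
  if (length(f) == 0L)
    tmerep_error("degenerate repertoire: no clones", "tmerep_degenerate_error")
  if (abs(sum(f) - 1) > 1e-9)
    tmerep_error(sprintf("frequencies do not sum to 1 (sum = %.12f)", sum(f)),
                 "tmerep_invariant_error")
  f
}

log_in_base <- function(x, base) if (base == "2") log2(x) else log(x)

#' Richness: number of unique productive rearrangements
#'
#' @param tme a `tme_repertoire`.
#' @return integer count of unique clone identity keys.
#' @export
richness <- function(tme) {
  stopifnot(inherits(tme, "tme_repertoire"))
  if (nrow(tme$clones) == 0L)
    tmerep_error("degenerate repertoire: no clones", "tmerep_degenerate_error")
  length(unique(clone_key(tme$clones)))
}

#' Shannon entropy of clone frequencies
#'
#' `H = -sum f_i log(f_i)`, with zero-frequency terms contributing 0.
#' Captures both richness and the unevenness of the clone-size distribution.
#'
#' @param tme a `tme_repertoire` or numeric frequency vector summing to 1.
#' @param base `"e"` (natural log, default) or `"2"`.
#' @return non-negative entropy, bounded by `log(n)` in the chosen base.
#' @export
shannon_entropy <- function(tme, base = c("e", "2")) {
  base <- match.arg(base)
  f <- tme_frequencies(tme)
  f <- f[f > 0]
  -sum(f * log_in_base(f, base))
}

#' Clonality score
#'
#' `C = 1 - H / log(n)` for `n >= 2` clones: 0 for a perfectly even
#' repertoire, 1 for a monoclonal one, independent of sample size. For
#' `n = 1` the score is defined as 1 (the limit of a single expanded clone).
#'
#' @inheritParams shannon_entropy
#' @return clonality in `[0, 1]`.
#' @export
clonality <- function(tme, base = c("e", "2")) {
  base <- match.arg(base)
  f <- tme_frequencies(tme)
  n <- length(f)
  if (n == 1L) return(1)
  H <- shannon_entropy(f, base)
  C <- 1 - H / log_in_base(n, base)
  min(max(C, 0), 1)
}

#' Summed frequency of the top N clones
#'
#' The proportion of the repertoire occupied by the `n_top` most abundant
#' clones (all clones, if fewer). Ties at the cutoff are resolved by the
#' deterministic clone ordering (descending frequency, then CDR3 nucleotide
#' sequence), so the result never depends on input order.
#'
#' @param tme a `tme_repertoire` or numeric frequency vector summing to 1.
#' @param n_top number of top clones (default 10).
#' @return a fraction in `(0, 1]`; 1 whenever `n <= n_top`.
#' @export
top_n_proportion <- function(tme, n_top = 10L) {
  if (n_top < 1) tmerep_error("n_top must be >= 1", "tmerep_argument_error")
  f <- tme_frequencies(tme)
  f <- sort(f, decreasing = TRUE)
  sum(f[seq_len(min(n_top, length(f)))])
}

#' V-family usage distribution
#'
#' Aggregates clone frequencies by V family (e.g. `TRBV7` pools `TRBV7-2`,
#' `TRBV7-9`, ...) and renormalizes over families that parse. Clones with
#' unparseable V calls are excluded from the denominator but remain in all
#' diversity metrics. When `reference_families` is supplied, families absent
#' from the repertoire are reported as 0 and the result is ordered by it.
#'
#' @param tme a `tme_repertoire`.
#' @param reference_families optional character vector of family names.
#' @return named numeric vector of fractions summing to 1.
#' @export
v_family_usage <- function(tme, reference_families = NULL) {
  stopifnot(inherits(tme, "tme_repertoire"))
  fam <- v_family(tme$clones$v_call)
  ok <- fam != "UNKNOWN"
  if (!any(ok))
    tmerep_error("no parseable V calls in repertoire", "tmerep_annotation_error")
  mass <- tapply(tme$clones$frequency[ok], fam[ok], sum)
  usage <- as.numeric(mass) / sum(mass)
  names(usage) <- names(mass)
  if (!is.null(reference_families)) {
    out <- stats::setNames(numeric(length(reference_families)), reference_families)
    shared <- intersect(names(usage), reference_families)
    out[shared] <- usage[shared]
    extra <- setdiff(names(usage), reference_families)
    if (length(extra)) out <- c(out, usage[extra])
    usage <- out
  }
  usage
}

#' All repertoire metrics for one sample
#'
#' @param tme a `tme_repertoire`.
#' @param base log base for entropy/clonality, `"e"` or `"2"`.
#' @param n_top top-clone cutoff (default 10).
#' @param reference_families optional family universe for V usage.
#' @return object of class `repertoire_metrics`: list with `sample_id`,
#'   `locus`, `base`, `richness`, `entropy`, `clonality`, `top10_proportion`,
#'   `v_family_usage`.
#' @export
repertoire_metrics <- function(tme, base = c("e", "2"), n_top = 10L,
                               reference_families = NULL) {
  base <- match.arg(base)
  structure(
    list(sample_id = tme$sample_id, locus = tme$locus, base = base,
         richness = richness(tme),
         entropy = shannon_entropy(tme, base),
         clonality = clonality(tme, base),
         top10_proportion = top_n_proportion(tme, n_top),
         v_family_usage = v_family_usage(tme, reference_families)),
    class = "repertoire_metrics"
  )
}

#' @export
print.repertoire_metrics <- function(x, ...) {
  cat(sprintf("<repertoire_metrics> sample '%s', locus %s (log base %s)\n",
              x$sample_id, x$locus, x$base))
  cat(sprintf("  richness %d, entropy %.4f, clonality %.4f, top-10 %.4f\n",
              x$richness, x$entropy, x$clonality, x$top10_proportion))
  top <- sort(x$v_family_usage, decreasing = TRUE)
  top <- top[seq_len(min(3, length(top)))]
  cat("  top V families:",
      paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "), "\n")
  invisible(x)
}

#' Metrics for many samples as a data.frame
#'
#' One row per sample: sample_id, locus, richness, entropy, clonality,
#' top10_proportion, plus one column per V family (harmonized across
#' samples, missing = 0).
#'
#' @param tmes list of `tme_repertoire`.
#' @inheritParams repertoire_metrics
#' @return data.frame.
#' @export
metrics_table <- function(tmes, base = c("e", "2"), n_top = 10L) {
  base <- match.arg(base)
  ms <- lapply(tmes, repertoire_metrics, base = base, n_top = n_top)
  fams <- sort(unique(unlist(lapply(ms, function(m) names(m$v_family_usage)))))
  rows <- lapply(ms, function(m) {
    u <- stats::setNames(numeric(length(fams)), fams)
    u[names(m$v_family_usage)] <- m$v_family_usage
    cbind(data.frame(sample_id = m$sample_id, locus = m$locus,
                     richness = m$richness, entropy = m$entropy,
                     clonality = m$clonality,
                     top10_proportion = m$top10_proportion,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(u), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
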