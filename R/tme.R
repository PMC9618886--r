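# Lymphoma-clone identification and TME repertoire construction.
#
# The neoplasm in AITL is a T-cell lymphoma: its clonal TRB rearrangement
# dominates the raw TRB repertoire and must be excluded before any statement
# about the reactive microenvironment. After exclusion, clone frequencies are
# renormalized as r_i / (R - r_L), where R is the total productive read mass
# and r_L the read mass of the lymphoma clone(s).

#' Keep only productive rearrangements
#'
#' Productive means in-frame, stop-free, with a non-empty amino-acid CDR3 —
#' the rearrangements that can encode a surface receptor. All diversity
#' metrics operate on productive clones only.
#'
#' @param rep a [repertoire].
#' @return a [repertoire] containing exactly the productive clones, with
#'   `total_reads` recomputed.
#' @export
filter_productive <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  keep <- rep$clones$productive
  if (!any(keep))
    tmerep_error(sprintf("sample '%s': no productive clones", rep$sample_id),
                 "tmerep_empty_error")
  out <- rep
  out$clones <- rep$clones[keep, , drop = FALSE]
  rownames(out$clones) <- NULL
  out$total_reads <- sum(out$clones$read_count)
  out
}

#' Criteria for calling the lymphoma-derived clone
#'
#' A clone is called tumor-derived when its frequency is at least
#' `min_top_frequency` of the repertoire AND at least `fold_over_background`
#' times the mean frequency of all other clones (excluding clones already
#' accepted as tumor). At most `max_clones` clones are called, which
#' accommodates biallelic TRB rearrangements. `manual_cdr3` overrides the
#' thresholds entirely: exactly the clones with those CDR3 nucleotide
#' sequences are returned.
#'
#' These defaults mimic common clinical clonality-assay conventions; the
#' thresholds are a package choice, fully configurable.
#'
#' @param min_top_frequency minimum repertoire frequency (default 0.025).
#' @param fold_over_background required fold over the background mean
#'   frequency (default 5).
#' @param max_clones maximum number of tumor clones (default 2).
#' @param manual_cdr3 optional character vector of CDR3 nucleotide sequences.
#' @return an object of class `tumor_criteria`.
#' @export
tumor_criteria <- function(min_top_frequency = 0.025, fold_over_background = 5,
                           max_clones = 2L, manual_cdr3 = NULL) {
  stopifnot(min_top_frequency > 0, min_top_frequency < 1,
            fold_over_background > 1, max_clones >= 1)
  structure(list(min_top_frequency = min_top_frequency,
                 fold_over_background = fold_over_background,
                 max_clones = as.integer(max_clones),
                 manual_cdr3 = manual_cdr3),
            class = "tumor_criteria")
}

#' Identify the lymphoma-derived clone(s) in a TRB repertoire
#'
#' Applies [tumor_criteria()] to a productive repertoire. Clones are examined
#' in order of descending frequency (ties broken lexicographically on the
#' CDR3 nucleotide sequence); for each candidate the background is every
#' clone that is neither the candidate nor already accepted. Acceptance stops
#' at the first clone failing either threshold or once `max_clones` are
#' accepted. The returned list may be empty (e.g. a polyclonal repertoire).
#'
#' IGH repertoires undergo no automatic calling (the neoplasm is a T-cell
#' lymphoma); they are only processed with `manual_cdr3`.
#'
#' @param rep a productive [repertoire].
#' @param criteria a [tumor_criteria()].
#' @return data.frame of tumor clone rows (possibly 0 rows), same columns as
#'   `rep$clones`.
#' @export
identify_tumor_clones <- function(rep, criteria = tumor_criteria()) {
  stopifnot(inherits(rep, "repertoire"), inherits(criteria, "tumor_criteria"))
  cl <- rep$clones
  if (!is.null(criteria$manual_cdr3)) {
    hit <- cl$cdr3_nt %in% criteria$manual_cdr3
    absent <- setdiff(criteria$manual_cdr3, cl$cdr3_nt)
    if (length(absent))
      tmerep_error(paste("manual tumor CDR3 not found in repertoire:",
                         paste(absent, collapse = ", ")),
                   "tmerep_notfound_error")
    return(cl[hit, , drop = FALSE])
  }
  if (rep$locus != "TRB")
    tmerep_error("automatic tumor-clone calling is TRB-only; use manual_cdr3 for other loci",
                 "tmerep_argument_error")
  f <- cl$read_count / rep$total_reads
  ord <- order(-f, cl$cdr3_nt)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) >= criteria$max_clones) break
    bg <- setdiff(seq_len(nrow(cl)), c(i, accepted))
    if (length(bg) == 0L) break
    bg_mean <- mean(f[bg])
    if (f[i] >= criteria$min_top_frequency &&
        f[i] >= criteria$fold_over_background * bg_mean) {
      accepted <- c(accepted, i)
    } else {
      break
    }
  }
  cl[accepted, , drop = FALSE]
}

#' Build the TME repertoire by excluding tumor clones and renormalizing
#'
#' Removes the given tumor clones and renormalizes every remaining clone's
#' frequency as `reads of clone / (total reads - reads of lymphoma clone)`.
#' With an empty tumor list this is plain normalization by total reads. TME
#' clones are ordered by descending frequency, ties broken lexicographically
#' on the CDR3 nucleotide sequence.
#'
#' @param rep a productive [repertoire].
#' @param tumor data.frame of tumor clone rows (as returned by
#'   [identify_tumor_clones()]), or `NULL`/0-row for none.
#' @return an object of class `tme_repertoire`: list with `sample_id`,
#'   `locus`, `tumor_clones`, `clones` (with a `frequency` column),
#'   `total_reads` (R), `tumor_reads` (r_L) and `denominator` (R - r_L).
#' @export
build_tme <- function(rep, tumor = NULL) {
  stopifnot(inherits(rep, "repertoire"))
  cl <- rep$clones
  if (is.null(tumor)) tumor <- cl[0, , drop = FALSE]
  key_all <- clone_key(cl)
  key_tum <- clone_key(tumor)
  if (!all(key_tum %in% key_all))
    tmerep_error("tumor clones are not members of the repertoire",
                 "tmerep_argument_error")
  is_tumor <- key_all %in% key_tum
  r_L <- sum(cl$read_count[is_tumor])
  denom <- rep$total_reads - r_L
  if (denom <= 0)
    tmerep_error(sprintf("sample '%s': tumor reads equal total reads; no TME left",
                         rep$sample_id), "tmerep_degenerate_error")
  tme <- cl[!is_tumor, , drop = FALSE]
  tme$frequency <- tme$read_count / denom
  ord <- order(-tme$frequency, tme$cdr3_nt)
  tme <- tme[ord, , drop = FALSE]
  rownames(tme) <- NULL
  structure(
    list(sample_id = rep$sample_id, locus = rep$locus,
         tumor_clones = cl[is_tumor, , drop = FALSE],
         clones = tme, total_reads = rep$total_reads,
         tumor_reads = r_L, denominator = denom),
    class = "tme_repertoire"
  )
}

#' Full TME construction from a raw repertoire
#'
#' Convenience chain: [filter_productive()], [identify_tumor_clones()] (TRB
#' only, unless manual CDR3s are given), [build_tme()].
#'
#' @param rep a [repertoire].
#' @param criteria a [tumor_criteria()].
#' @return a `tme_repertoire`.
#' @export
tme_repertoire <- function(rep, criteria = tumor_criteria()) {
  prod <- filter_productive(rep)
  tumor <- if (prod$locus == "TRB" || !is.null(criteria$manual_cdr3))
    identify_tumor_clones(prod, criteria)
  else
    prod$clones[0, , drop = FALSE]
  build_tme(prod, tumor)
}

#' @export
print.tme_repertoire <- function(x, ...) {
  cat(sprintf("<tme_repertoire> sample '%s', locus %s\n", x$sample_id, x$locus))
  cat(sprintf("  %d tumor clone(s) excluded: r_L = %s of R = %s reads\n",
              nrow(x$tumor_clones), format(x$tumor_reads, big.mark = ","),
              format(x$total_reads, big.mark = ",")))
  cat(sprintf("  TME: %d clones over denominator %s; top frequency %.4f\n",
              nrow(x$clones), format(x$denominator, big.mark = ","),
              if (nrow(x$clones)) x$clones$frequency[1] else NA_real_))
  invisible(x)
}
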