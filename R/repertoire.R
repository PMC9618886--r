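#' @keywords internal
"_PACKAGE"

# Columns every clone table carries internally. `clone_id` is opaque;
# identity for merging/metrics is the (gene-level V, CDR3 nt, gene-level J)
# key, computed by clone_key().
CLONE_COLUMNS <- c(
  "clone_id", "cdr3_nt", "cdr3_aa", "v_call", "j_call",
  "read_count", "productive", "frame_ok", "has_stop"
)

#' Gene-level call: strip allele suffix and alignment-score annotation
#'
#' `"TRBV7-2*01"` becomes `"TRBV7-2"`; MiXCR-style `"TRBV7-9*00(1234)"`
#' becomes `"TRBV7-9"`. Vectorized.
#'
#' @param call character vector of V/J gene calls.
#' @return character vector of gene-level calls.
#' @export
gene_call <- function(call) {
  call <- sub("\\([0-9.]+\\)$", "", call)
  sub("\\*[0-9]+$", "", call)
}

#' Extract the V-family prefix from a V call
#'
#' The family is the leading locus+segment+number block, e.g. `"TRBV7"` from
#' `"TRBV7-2*01"` or `"IGHV3"` from `"IGHV3-7*01"`. Calls that do not parse
#' are mapped to `"UNKNOWN"` (they stay in the repertoire and in diversity
#' metrics, but are excluded from V-usage denominators).
#'
#' @param v_call character vector of V calls.
#' @return character vector of family names.
#' @export
v_family <- function(v_call) {
  fam <- regmatches(v_call, regexpr("^(TR[ABGD]|IG[HKL])V[0-9]+", v_call))
  out <- rep("UNKNOWN", length(v_call))
  ok <- regexpr("^(TR[ABGD]|IG[HKL])V[0-9]+", v_call) > 0
  out[ok] <- fam
  out
}

# Identity key for merging and metrics: gene-level V + CDR3 nt + gene-level J.
clone_key <- function(clones) {
  paste(gene_call(clones$v_call), clones$cdr3_nt, gene_call(clones$j_call),
        sep = "|")
}

tmerep_error <- function(msg, class) {
  stop(structure(
    class = c(class, "tmerep_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Construct a repertoire from a clone table
#'
#' A repertoire is all clonotypes observed in one sample at one locus, with
#' their read counts. Duplicate identity keys (gene-level V call, CDR3
#' nucleotide sequence, gene-level J call) are merged by summing read counts.
#' Productivity is reconciled so that
#' `productive == frame_ok & !has_stop & nzchar(cdr3_aa)` holds row-wise:
#' when only a `productive` flag is available, `has_stop` is inferred from a
#' `*` in the amino-acid CDR3 and `frame_ok` set accordingly.
#'
#' @param clones data.frame with columns `cdr3_nt`, `cdr3_aa`, `v_call`,
#'   `j_call`, `read_count`, and at least one of `productive` or the pair
#'   `frame_ok`/`has_stop`. Optional `clone_id`.
#' @param sample_id sample identifier.
#' @param locus `"TRB"` or `"IGH"`.
#' @return an object of class `repertoire`: a list with `sample_id`, `locus`,
#'   `clones` (data.frame) and `total_reads`.
#' @export
repertoire <- function(clones, sample_id, locus = c("TRB", "IGH")) {
  locus <- match.arg(locus)
  if (!is.data.frame(clones) || nrow(clones) == 0L)
    tmerep_error(sprintf("sample '%s': empty repertoire (no clone rows)", sample_id),
                 "tmerep_empty_error")
  needed <- c("cdr3_nt", "cdr3_aa", "v_call", "j_call", "read_count")
  miss <- setdiff(needed, names(clones))
  if (length(miss))
    tmerep_error(paste("clone table missing column(s):", paste(miss, collapse = ", ")),
                 "tmerep_format_error")
  clones$cdr3_nt <- as.character(clones$cdr3_nt)
  clones$cdr3_aa <- as.character(clones$cdr3_aa)
  clones$cdr3_aa[is.na(clones$cdr3_aa)] <- ""
  clones$read_count <- as.numeric(clones$read_count)
  if (anyNA(clones$read_count) || any(clones$read_count < 0))
    tmerep_error("read_count must be a non-negative number for every clone",
                 "tmerep_format_error")

  if (!"has_stop" %in% names(clones))
    clones$has_stop <- grepl("*", clones$cdr3_aa, fixed = TRUE)
  if (!"frame_ok" %in% names(clones)) {
    if ("productive" %in% names(clones)) {
      p <- as.logical(clones$productive)
      p[is.na(p)] <- FALSE
      # non-productive without a stop codon must be out of frame
      clones$frame_ok <- p | clones$has_stop
    } else {
      clones$frame_ok <- nzchar(clones$cdr3_aa) & !grepl("_", clones$cdr3_aa, fixed = TRUE)
    }
  }
  clones$productive <- clones$frame_ok & !clones$has_stop & nzchar(clones$cdr3_aa)
  if (!"clone_id" %in% names(clones))
    clones$clone_id <- sprintf("%s_c%04d", sample_id, seq_len(nrow(clones)))
  clones$clone_id <- as.character(clones$clone_id)

  key <- clone_key(clones)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    merged <- clones[first, , drop = FALSE]
    merged$read_count <- as.numeric(tapply(clones$read_count, key, sum)[key[first]])
    # merged records are productive only if every member was
    merged$productive <- as.logical(tapply(clones$productive, key, all)[key[first]])
    clones <- merged
  }
  clones <- clones[, CLONE_COLUMNS, drop = FALSE]
  rownames(clones) <- NULL

  structure(
    list(sample_id = as.character(sample_id), locus = locus,
         clones = clones, total_reads = sum(clones$read_count)),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> sample '%s', locus %s\n", x$sample_id, x$locus))
  cat(sprintf("  %d clones, %s reads (%d productive clones)\n",
              nrow(x$clones), format(x$total_reads, big.mark = ","),
              sum(x$clones$productive)))
  invisible(x)
}

#' @export
summary.repertoire <- function(object, ...) {
  f <- object$clones$read_count / object$total_reads
  cat(sprintf("Repertoire %s [%s]: %d clones, %s reads\n", object$sample_id,
              object$locus, nrow(object$clones),
              format(object$total_reads, big.mark = ",")))
  cat(sprintf("  top clone frequency %.4f, productive fraction %.3f\n",
              max(f), mean(object$clones$productive)))
  invisible(object)
}
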