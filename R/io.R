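# Reading and writing clone tables (AIRR Rearrangement TSV and MiXCR-style
# clone exports) and the sample metadata sheet.

infer_locus <- function(v_call) {
  if (any(startsWith(v_call, "IGH"))) "IGH" else "TRB"
}

read_tsv_raw <- function(path) {
  if (!file.exists(path))
    tmerep_error(paste("file not found:", path), "tmerep_io_error")
  dat <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = c("NA", "")),
    error = function(e) tmerep_error(paste("cannot parse", path, ":",
                                           conditionMessage(e)),
                                     "tmerep_format_error"))
  dat
}

parse_logical_flag <- function(x) {
  toupper(trimws(ifelse(is.na(x), "", x))) %in% c("T", "TRUE", "1", "YES")
}

#' Read an AIRR Rearrangement TSV into a repertoire
#'
#' Consumes the AIRR Community Rearrangement format (tab-separated, header
#' row). The junction columns may be named `junction`/`junction_aa` or
#' `cdr3`/`cdr3_aa`. The clone count is taken from `duplicate_count`, falling
#' back to `consensus_count`; absence of both is a format error. Rows whose
#' count fails to parse or whose CDR3 nucleotide sequence is missing are
#' dropped with a message reporting how many (also available as attribute
#' `n_skipped` on the result).
#'
#' @param path path to the TSV file.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param locus `"TRB"`, `"IGH"`, or `NULL` to infer from the V calls.
#' @return a [repertoire].
#' @export
read_airr <- function(path, sample_id = NULL, locus = NULL) {
  dat <- read_tsv_raw(path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (nrow(dat) == 0L)
    tmerep_error(sprintf("sample '%s': empty repertoire (no rows in %s)",
                         sample_id, path), "tmerep_empty_error")

  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(dat)) return(nm)
    NULL
  }
  col_nt <- pick("junction", "cdr3")
  col_aa <- pick("junction_aa", "cdr3_aa")
  col_count <- pick("duplicate_count", "consensus_count")
  missing_cols <- c(
    if (is.null(col_nt)) "junction",
    if (is.null(col_aa)) "junction_aa",
    if (!"v_call" %in% names(dat)) "v_call",
    if (!"j_call" %in% names(dat)) "j_call",
    if (is.null(col_count)) "duplicate_count",
    if (!"productive" %in% names(dat)) "productive"
  )
  if (length(missing_cols))
    tmerep_error(paste("AIRR file missing required column(s):",
                       paste(missing_cols, collapse = ", ")),
                 "tmerep_format_error")

  count <- suppressWarnings(as.numeric(dat[[col_count]]))
  bad <- is.na(count) | is.na(dat[[col_nt]]) | !nzchar(ifelse(is.na(dat[[col_nt]]), "", dat[[col_nt]]))
  n_skipped <- sum(bad)
  if (n_skipped > 0L)
    message(sprintf("read_airr: %d of %d rows unparseable in %s; skipped",
                    n_skipped, nrow(dat), basename(path)))
  dat <- dat[!bad, , drop = FALSE]
  count <- count[!bad]
  if (nrow(dat) == 0L)
    tmerep_error(sprintf("sample '%s': no parseable clone rows in %s",
                         sample_id, path), "tmerep_empty_error")

  clones <- data.frame(
    clone_id = if ("sequence_id" %in% names(dat)) dat$sequence_id else
      sprintf("%s_c%04d", sample_id, seq_len(nrow(dat))),
    cdr3_nt = dat[[col_nt]],
    cdr3_aa = ifelse(is.na(dat[[col_aa]]), "", dat[[col_aa]]),
    v_call = ifelse(is.na(dat$v_call), "", dat$v_call),
    j_call = ifelse(is.na(dat$j_call), "", dat$j_call),
    read_count = count,
    productive = parse_logical_flag(dat$productive),
    stringsAsFactors = FALSE
  )
  if (is.null(locus)) locus <- infer_locus(clones$v_call)
  rep <- repertoire(clones, sample_id = sample_id, locus = locus)
  attr(rep, "n_skipped") <- n_skipped
  rep
}

#' Default column map for MiXCR-style clone exports
#'
#' Maps internal field names to the header names of a MiXCR `exportClones`
#' table. Any entry can be overridden through the `column_map` argument of
#' [read_mixcr()].
#'
#' @return named character vector (internal name -> file header).
#' @export
mixcr_default_columns <- function() {
  c(clone_id = "cloneId",
    read_count = "cloneCount",
    cdr3_nt = "nSeqCDR3",
    cdr3_aa = "aaSeqCDR3",
    v_call = "allVHitsWithScore",
    j_call = "allJHitsWithScore")
}

#' Read a MiXCR-style clone export into a repertoire
#'
#' Tab-separated clone export with clone count, CDR3 nucleotide/amino-acid
#' sequence and V/J hit columns. V/J hits may carry alignment-score
#' annotations (`"TRBV7-9*00(1234)"`) and comma-separated alternatives; the
#' first hit is kept and the score annotation stripped. Productivity is
#' derived from the amino-acid CDR3: non-empty, no stop (`*`), no frameshift
#' (`_`). The result is identical in contract to [read_airr()].
#'
#' @param path path to the export.
#' @param column_map optional named character vector overriding entries of
#'   [mixcr_default_columns()].
#' @param sample_id,locus as in [read_airr()].
#' @return a [repertoire].
#' @export
read_mixcr <- function(path, column_map = NULL, sample_id = NULL, locus = NULL) {
  dat <- read_tsv_raw(path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  cmap <- mixcr_default_columns()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  needed <- c("read_count", "cdr3_nt", "cdr3_aa", "v_call", "j_call")
  miss <- needed[!cmap[needed] %in% names(dat)]
  if (length(miss))
    tmerep_error(paste("MiXCR export missing required column(s):",
                       paste(cmap[miss], collapse = ", ")),
                 "tmerep_format_error")
  if (nrow(dat) == 0L)
    tmerep_error(sprintf("sample '%s': empty repertoire (no rows in %s)",
                         sample_id, path), "tmerep_empty_error")

  first_hit <- function(x) {
    x <- ifelse(is.na(x), "", x)
    sub("\\([0-9.]+\\)$", "", vapply(strsplit(x, ","), function(h)
      if (length(h)) h[[1]] else "", ""))
  }
  count <- suppressWarnings(as.numeric(dat[[cmap["read_count"]]]))
  nt <- dat[[cmap["cdr3_nt"]]]
  bad <- is.na(count) | is.na(nt) | !nzchar(ifelse(is.na(nt), "", nt))
  n_skipped <- sum(bad)
  if (n_skipped > 0L)
    message(sprintf("read_mixcr: %d of %d rows unparseable in %s; skipped",
                    n_skipped, nrow(dat), basename(path)))
  dat <- dat[!bad, , drop = FALSE]
  count <- count[!bad]
  if (nrow(dat) == 0L)
    tmerep_error(sprintf("sample '%s': no parseable clone rows in %s",
                         sample_id, path), "tmerep_empty_error")

  aa <- ifelse(is.na(dat[[cmap["cdr3_aa"]]]), "", dat[[cmap["cdr3_aa"]]])
  clones <- data.frame(
    clone_id = if (cmap["clone_id"] %in% names(dat)) dat[[cmap["clone_id"]]] else
      sprintf("%s_c%04d", sample_id, seq_len(nrow(dat))),
    cdr3_nt = nt,
    cdr3_aa = aa,
    v_call = first_hit(dat[[cmap["v_call"]]]),
    j_call = first_hit(dat[[cmap["j_call"]]]),
    read_count = count,
    productive = nzchar(aa) & !grepl("[*_]", aa),
    stringsAsFactors = FALSE
  )
  if (is.null(locus)) locus <- infer_locus(clones$v_call)
  rep <- repertoire(clones, sample_id = sample_id, locus = locus)
  attr(rep, "n_skipped") <- n_skipped
  rep
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Emits the columns `sequence_id`, `junction`, `junction_aa`, `v_call`,
#' `j_call`, `productive`, `duplicate_count`. The round trip
#' `read_airr(write_airr(rep))` reproduces clone identity keys, counts and
#' calls exactly.
#'
#' @param rep a [repertoire].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  cl <- rep$clones
  out <- data.frame(
    sequence_id = cl$clone_id,
    junction = cl$cdr3_nt,
    junction_aa = cl$cdr3_aa,
    v_call = cl$v_call,
    j_call = cl$j_call,
    productive = ifelse(cl$productive, "T", "F"),
    duplicate_count = format(cl$read_count, scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    tmerep_error(paste("cannot write", path), "tmerep_io_error")
  invisible(path)
}

#' Read the sample metadata sheet
#'
#' TSV with columns `sample_id`, `locus`, `group` and optionally
#' `tumor_fraction`, `survival_time` (months), `event` (1 = death), plus any
#' binary clinical covariates (values 0/1, blank = missing).
#'
#' @param path path to the metadata TSV.
#' @return data.frame, one row per sample+locus; `sample_id` must be unique
#'   within each locus.
#' @export
read_sample_metadata <- function(path) {
  dat <- read_tsv_raw(path)
  miss <- setdiff(c("sample_id", "locus", "group"), names(dat))
  if (length(miss))
    tmerep_error(paste("metadata missing required column(s):",
                       paste(miss, collapse = ", ")),
                 "tmerep_format_error")
  for (col in setdiff(names(dat), c("sample_id", "locus", "group")))
    dat[[col]] <- suppressWarnings(as.numeric(dat[[col]]))
  if (anyDuplicated(paste(dat$sample_id, dat$locus)))
    tmerep_error("metadata: sample_id must be unique within each locus",
                 "tmerep_format_error")
  dat
}
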