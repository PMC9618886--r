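# Small in-code fixture builders shared across test files.

# Clone table with given read counts; distinct CDR3s unless overridden.
make_clones <- function(counts, cdr3_nt = NULL, cdr3_aa = NULL,
                        v_call = "TRBV7-2*01", j_call = "TRBJ2-1*01",
                        productive = TRUE) {
  n <- length(counts)
  if (is.null(cdr3_nt)) cdr3_nt <- sprintf("TGTGCC%03dTTT", seq_len(n))
  if (is.null(cdr3_aa)) cdr3_aa <- sprintf("CASS%03dF", seq_len(n))
  data.frame(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
             v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
             read_count = counts, productive = rep_len(productive, n),
             stringsAsFactors = FALSE)
}

make_repertoire <- function(counts, ..., sample_id = "s1", locus = "TRB") {
  repertoire(make_clones(counts, ...), sample_id = sample_id, locus = locus)
}

# TME repertoire (no tumor exclusion) straight from counts.
make_tme <- function(counts, ..., sample_id = "s1", locus = "TRB") {
  build_tme(make_repertoire(counts, ..., sample_id = sample_id, locus = locus))
}

# Write an AIRR TSV from a data.frame of columns.
write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

airr_fixture <- function(counts = c(10, 5, 5), v_call = "TRBV7-2*01",
                         junction = NULL, junction_aa = NULL,
                         count_col = "duplicate_count") {
  n <- length(counts)
  if (is.null(junction)) junction <- sprintf("TGTGCC%03dTTT", seq_len(n))
  if (is.null(junction_aa)) junction_aa <- sprintf("CASS%03dF", seq_len(n))
  df <- data.frame(sequence_id = sprintf("sq%d", seq_len(n)),
                   junction = junction, junction_aa = junction_aa,
                   v_call = rep_len(v_call, n), j_call = "TRBJ2-1*01",
                   productive = "T", stringsAsFactors = FALSE)
  df[[count_col]] <- counts
  write_tsv_fixture(df)
}

# Exact two-sided Fisher oracle by integer-arithmetic margin enumeration:
# point probabilities share the denominator choose(n, c1), so comparing
# integer numerators choose(r1, a) * choose(r2, c1 - a) is exact (products
# stay below 2^53 for all margins <= 25).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  num <- choose(r1, support) * choose(r2, c1 - support)
  num_obs <- choose(r1, a) * choose(r2, c1 - a)
  sum(num[num <= num_obs]) / choose(n, c1)
}

# Exact two-sided Mann-Whitney oracle by full enumeration of all
# assignments of the pooled values to group A (tie-free data only).
mwu_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  ranks <- rank(pooled)
  n1 <- length(x)
  W_obs <- sum(ranks[seq_len(n1)])
  splits <- combn(length(pooled), n1)
  W_all <- apply(splits, 2, function(idx) sum(ranks[idx]))
  lower <- mean(W_all <= W_obs)
  upper <- mean(W_all >= W_obs)
  min(1, 2 * min(lower, upper))
}
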