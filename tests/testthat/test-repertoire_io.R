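test_that("read_airr sums counts, prefers duplicate_count, falls back to consensus_count", {
  rep <- read_airr(airr_fixture(c(10, 5, 5)))
  expect_s3_class(rep, "repertoire")
  expect_equal(rep$total_reads, 20)
  expect_equal(nrow(rep$clones), 3)

  rep2 <- read_airr(airr_fixture(c(7, 3), count_col = "consensus_count"))
  expect_equal(rep2$total_reads, 10)
})

test_that("rows sharing the identity key are merged by summing counts", {
  # same gene-level V (alleles differ), same CDR3 nt, same J -> one clone
  path <- airr_fixture(c(4, 6), v_call = c("TRBV7-2*01", "TRBV7-2*02"),
                       junction = c("TGTGCCAAATTT", "TGTGCCAAATTT"),
                       junction_aa = c("CAKF", "CAKF"))
  rep <- read_airr(path)
  expect_equal(nrow(rep$clones), 1)
  expect_equal(rep$clones$read_count, 10)
  expect_equal(rep$total_reads, 10)
})

test_that("missing mandatory columns raise a format error naming the column", {
  df <- data.frame(junction = "TGTTTT", junction_aa = "CF",
                   j_call = "TRBJ1-1*01", duplicate_count = 5, productive = "T")
  expect_error(read_airr(write_tsv_fixture(df)), "v_call",
               class = "tmerep_format_error")
  df2 <- data.frame(junction = "TGTTTT", junction_aa = "CF",
                    v_call = "TRBV2*01", j_call = "TRBJ1-1*01", productive = "T")
  expect_error(read_airr(write_tsv_fixture(df2)), "duplicate_count",
               class = "tmerep_format_error")
})

test_that("header-only and unreadable files give dedicated errors", {
  p <- write_tsv_fixture(data.frame(junction = character(),
                                    junction_aa = character(),
                                    v_call = character(), j_call = character(),
                                    duplicate_count = numeric(),
                                    productive = character()))
  expect_error(read_airr(p), class = "tmerep_empty_error")
  expect_error(read_airr(file.path(tempdir(), "nope.tsv")),
               class = "tmerep_io_error")
})

test_that("read_mixcr matches read_airr on equivalent content and honors column_map", {
  mx <- data.frame(cloneId = 0:1, cloneCount = c(12, 8),
                   nSeqCDR3 = c("TGTGCCAGCTTT", "TGTGCCTGGTTT"),
                   aaSeqCDR3 = c("CASF", "CAWF"),
                   allVHitsWithScore = c("TRBV7-9*00(1234)", "TRBV5-1*00(900.5)"),
                   allJHitsWithScore = c("TRBJ2-1*00(500)", "TRBJ2-1*00(500)"),
                   stringsAsFactors = FALSE)
  rep <- read_mixcr(write_tsv_fixture(mx), sample_id = "s1")
  expect_equal(nrow(rep$clones), 2)
  expect_equal(rep$total_reads, 20)
  # score annotation stripped from the stored call
  expect_setequal(rep$clones$v_call, c("TRBV7-9*00", "TRBV5-1*00"))

  # same content under a renamed count column, mapped back
  mx2 <- mx
  names(mx2)[names(mx2) == "cloneCount"] <- "readCount"
  rep2 <- read_mixcr(write_tsv_fixture(mx2),
                     column_map = c(read_count = "readCount"), sample_id = "s1")
  expect_equal(rep2$clones, rep$clones)

  # equivalent AIRR content parses to the same repertoire
  airr <- data.frame(junction = mx$nSeqCDR3, junction_aa = mx$aaSeqCDR3,
                     v_call = c("TRBV7-9*00", "TRBV5-1*00"),
                     j_call = "TRBJ2-1*00", duplicate_count = mx$cloneCount,
                     productive = "T", stringsAsFactors = FALSE)
  rep3 <- read_airr(write_tsv_fixture(airr), sample_id = "s1")
  for (col in c("cdr3_nt", "cdr3_aa", "v_call", "j_call", "read_count", "productive"))
    expect_equal(rep3$clones[[col]], rep$clones[[col]], label = col)
})

test_that("write_airr round-trips keys, counts and calls exactly", {
  sim <- simulate_repertoire(sim_config(seed = 21, clones_per_sample = 1000L), 1)
  rep <- sim$repertoire
  path <- tempfile(fileext = ".tsv")
  write_airr(rep, path)
  back <- read_airr(path, sample_id = rep$sample_id)
  expect_equal(back$total_reads, rep$total_reads)
  key <- function(r) sort(paste(gene_call(r$clones$v_call), r$clones$cdr3_nt,
                                gene_call(r$clones$j_call)))
  expect_identical(key(back), key(rep))
  ord <- order(rep$clones$clone_id); ord_b <- order(back$clones$clone_id)
  expect_equal(back$clones$read_count[ord_b], rep$clones$read_count[ord])
  expect_identical(back$clones$v_call[ord_b], rep$clones$v_call[ord])
})

test_that("v_family parses family prefixes and flags unparseable calls", {
  expect_identical(v_family(c("TRBV7-2*01", "IGHV3-7*01", "TRBV24-1", "weird")),
                   c("TRBV7", "IGHV3", "TRBV24", "UNKNOWN"))
  expect_identical(gene_call(c("TRBV7-2*01", "TRBV7-9*00(1234)")),
                   c("TRBV7-2", "TRBV7-9"))
})

test_that("sample metadata requires mandatory columns and unique ids", {
  md <- data.frame(sample_id = c("a", "b"), locus = "TRB",
                   group = c("case", "control"), survival_time = c(5, NA),
                   event = c(1, NA))
  got <- read_sample_metadata(write_tsv_fixture(md))
  expect_equal(got$survival_time, c(5, NA))
  bad <- rbind(md, md[1, ])
  expect_error(read_sample_metadata(write_tsv_fixture(bad)),
               class = "tmerep_format_error")
  expect_error(read_sample_metadata(write_tsv_fixture(md[, 1:2])), "group",
               class = "tmerep_format_error")
})
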