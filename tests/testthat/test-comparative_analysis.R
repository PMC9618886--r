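test_that("compare_metric reports medians, ranges and a symmetric p", {
  cmp <- compare_metric(c(1, 2, 3), c(4, 5, 6), metric = "toy")
  expect_s3_class(cmp, "metric_comparison")
  expect_equal(cmp$p.value, 0.1)
  expect_equal(cmp$median_a, 2)
  expect_equal(cmp$range_b, c(4, 6))
  expect_equal(cmp$direction, "B")
  rev <- compare_metric(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$p.value, cmp$p.value)
  expect_equal(rev$direction, "A")
})

test_that("compare_v_usage tests each family and a boosted family ranks low in p", {
  # Dirichlet usage vectors; group A has TRBV7 concentration doubled
  fams <- paste0("TRBV", c(2, 5, 6, 7, 9, 20, 24, 28))
  rdir <- function(conc) { g <- rgamma(length(conc), conc); setNames(g / sum(g), fams) }
  set.seed(202)
  conc_a <- ifelse(fams == "TRBV7", 20, 4)
  conc_b <- rep(4, length(fams))
  usage_a <- replicate(6, rdir(conc_a), simplify = FALSE)
  usage_b <- replicate(12, rdir(conc_b), simplify = FALSE)
  res <- compare_v_usage(usage_a, usage_b, n_perm = 300, seed = 5)
  ps <- vapply(res$per_family, `[[`, 1, "p.value")
  expect_lt(ps[["TRBV7"]], median(ps))
  expect_equal(res$per_family$TRBV7$direction, "A")
  expect_true(res$global$p.value > 0 && res$global$p.value <= 1)
})

test_that("identical usage in both groups gives p = 1 everywhere, absent families too", {
  u <- c(TRBV7 = 0.6, TRBV9 = 0.4, TRBV24 = 0)
  res <- compare_v_usage(replicate(3, u, simplify = FALSE),
                         replicate(3, u, simplify = FALSE),
                         n_perm = 100, seed = 1)
  for (f in names(res$per_family))
    expect_equal(res$per_family[[f]]$p.value, 1)
  expect_equal(res$per_family$TRBV24$median_a, 0)
})

test_that("shared clones are keyed on amino-acid CDR3 across samples", {
  # two samples share one aa CDR3 through different nucleotide sequences
  t1 <- make_tme(c(6, 4), cdr3_nt = c("TGTGCTAGCTTT", "TGTAAATTT"),
                 cdr3_aa = c("CASF", "CAKF"), sample_id = "s1")
  t2 <- make_tme(c(5, 5), cdr3_nt = c("TGCGCTAGTTTC", "TGTCCCTTT"),
                 cdr3_aa = c("CASF", "CAPF"), sample_id = "s2")
  sh <- find_shared_clones(list(t1, t2), min_samples = 2)
  expect_equal(sh$cdr3_aa, "CASF")
  expect_equal(sh$n_samples, 2)
  # private clones are excluded at min_samples = 2
  expect_false("CAKF" %in% sh$cdr3_aa)
  # "all" requires presence in every sample
  sh_all <- find_shared_clones(list(t1, t2), min_samples = "all")
  expect_equal(sh_all$cdr3_aa, "CASF")
  expect_error(find_shared_clones(list(t1, t2), min_samples = 3),
               class = "tmerep_argument_error")
})

test_that("a public clone forced into every simulated sample is reported in all", {
  cfg <- sim_config(seed = 51, n_cases = 3L, n_controls = 3L,
                    clones_per_sample = 300L, total_reads = 2e4,
                    public_pool = list(size = 1L, p_case = 1, p_control = 1,
                                       freq_scale = 50))
  co <- simulate_cohort(cfg)
  # no tumor exclusion here: the heavily scaled public clone must survive
  tmes <- lapply(co$repertoires, function(r) build_tme(filter_productive(r)))
  sh <- find_shared_clones(tmes, min_samples = "all")
  pub <- co$truth[[1]]$public_members
  expect_true(pub %in% sh$cdr3_aa)
  expect_equal(sh$n_samples[sh$cdr3_aa == pub], 6)
})

test_that("differential clones flag a group-restricted clone with direction", {
  set.seed(303)
  mk <- function(id, with_clone) {
    counts <- sample(50:100, 20)
    cl <- make_clones(counts,
                      cdr3_nt = sprintf("TGT%s%03dTTT", id, 1:20),
                      cdr3_aa = sprintf("C%s%03dF", id, 1:20))
    if (with_clone) {
      cl$cdr3_nt[1] <- "TGTGATTTT"; cl$cdr3_aa[1] <- "CDF"
      cl$read_count[1] <- round(0.1 * sum(cl$read_count[-1]) / 0.9)
    }
    build_tme(repertoire(cl, id, "TRB"))
  }
  reps_a <- lapply(sprintf("a%d", 1:5), mk, with_clone = TRUE)
  reps_b <- lapply(sprintf("b%d", 1:12), mk, with_clone = FALSE)
  dc <- differential_clones(reps_a, reps_b)
  hit <- dc[dc$cdr3_aa == "CDF", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$direction, "A")
  expect_lt(hit$p.value, 0.01)
})

test_that("a clone at identical frequency everywhere is not flagged", {
  mk <- function(id) make_tme(c(10, 10, 20, 40, 20), sample_id = id)
  dc <- differential_clones(lapply(c("a1", "a2", "a3"), mk),
                            lapply(c("b1", "b2", "b3"), mk))
  expect_equal(nrow(dc), 0)
  all_cand <- attr(dc, "all_candidates")
  expect_true(all(all_cand$p.value == 1))
})

test_that("differential testing with an empty candidate set returns an empty table", {
  t1 <- make_tme(c(5, 5), cdr3_aa = c("CAAF", "CABF"), sample_id = "x1")
  t2 <- make_tme(c(5, 5), cdr3_aa = c("CACF", "CADF"), sample_id = "x2")
  dc <- differential_clones(list(t1), list(t2))
  expect_equal(nrow(dc), 0)
})

test_that("BH adjustment adds a monotone adjusted column", {
  set.seed(304)
  mk <- function(id) make_tme(sample(10:50, 8), cdr3_aa = sprintf("CA%dF", 1:8),
                              sample_id = id)
  dc <- differential_clones(lapply(c("a1", "a2", "a3"), mk),
                            lapply(c("b1", "b2", "b3"), mk),
                            alpha = 1, adjust = TRUE)
  cand <- attr(dc, "all_candidates")
  expect_true(all(cand$p.adjusted >= cand$p.value - 1e-12))
  expect_equal(cand$p.adjusted, p.adjust(cand$p.value, "BH"))
})
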