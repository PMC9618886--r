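test_that("the generator is deterministic under a fixed seed, to the byte on disk", {
  cfg <- sim_config(seed = 71, n_cases = 1L, n_controls = 2L,
                    clones_per_sample = 200L, total_reads = 1e4)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_identical(simulate_repertoire(cfg, 2), simulate_repertoire(cfg, 2))
})

test_that("read mass is conserved exactly and the spike hits its target fraction", {
  cfg <- sim_config(seed = 72, tumor_fraction = 0.2, total_reads = 1e5)
  sim <- simulate_repertoire(cfg, 1)
  expect_equal(sim$repertoire$total_reads, 1e5)
  tumor_reads <- sim$truth$tumor_read_fraction * 1e5
  expect_lt(abs(tumor_reads - 2e4), 0.02 * 2e4)
  # largest-remainder rounding: every clone within 1 read of its exact mass
  expect_equal(sum(sim$repertoire$clones$read_count), 1e5)
})

test_that("ground-truth bookkeeping matches the emitted clone tables", {
  cfg <- sim_config(seed = 73, n_cases = 2L, n_controls = 2L,
                    clones_per_sample = c(300L, 500L), total_reads = 5e4)
  co <- simulate_cohort(cfg)
  for (id in names(co$repertoires)) {
    rep <- co$repertoires[[id]]
    tr <- co$truth[[id]]
    expect_equal(nrow(rep$clones), tr$n_clones_realized)
    expect_equal(rep$total_reads, tr$total_reads)
    expect_true(all(tr$public_members %in% rep$clones$cdr3_aa))
    if (!is.na(tr$tumor_cdr3_nt[1]))
      expect_true(all(tr$tumor_cdr3_nt %in% rep$clones$cdr3_nt))
  }
  expect_equal(nrow(co$metadata), 4)
  expect_setequal(co$metadata$group, c("case", "control"))
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(tumor_fraction = 1), class = "tmerep_config_error")
  expect_error(sim_config(clones_per_sample = 1L), class = "tmerep_config_error")
  expect_error(sim_config(public_pool = list(size = 2, p_case = 1.2,
                                             p_control = 0.5, freq_scale = 1)),
               class = "tmerep_config_error")
})

test_that("written cohorts round-trip through the AIRR reader", {
  cfg <- sim_config(seed = 74, n_cases = 1L, n_controls = 1L,
                    clones_per_sample = 150L, total_reads = 1e4)
  d <- tempfile()
  co <- simulate_cohort(cfg, dir = d)
  back <- read_airr(co$paths$clone_tables[["case01"]], sample_id = "case01")
  orig <- co$repertoires$case01
  expect_equal(back$total_reads, orig$total_reads)
  expect_setequal(back$clones$cdr3_nt, orig$clones$cdr3_nt)
  md <- read_sample_metadata(co$paths$metadata)
  expect_equal(md$sample_id, co$metadata$sample_id)
})

test_that("a heavier abundance tail yields higher mean clonality (monotone trend)", {
  mean_cl <- function(sigma) {
    mean(vapply(1:12, function(s) {
      cfg <- sim_config(seed = 7000 + s, sigma = sigma, sigma_shift = 0,
                        tumor_fraction = 0, clones_per_sample = 400L,
                        total_reads = 3e4)
      clonality(build_tme(filter_productive(simulate_repertoire(cfg, 1)$repertoire)))
    }, 1))
  }
  cls <- vapply(c(1.0, 1.6, 2.2), mean_cl, 1)
  expect_true(all(diff(cls) > 0))
})

test_that("survival under a unit hazard ratio gives uniform log-rank p over seeds", {
  ps <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, hazard_case = log(2) / 36,
                      hazard_control = log(2) / 36)
    md <- simulate_cohort(cfg, clone_tables = FALSE)$metadata
    logrank_test(md$survival_time[md$group == "case"],
                 md$event[md$group == "case"],
                 md$survival_time[md$group == "control"],
                 md$event[md$group == "control"])$p.value
  }, 1)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("a deterministic clinical feature reaches the closed-form Fisher minimum", {
  cfg <- sim_config(seed = 75, features = list(marker = c(1.0, 0.0)))
  md <- simulate_cohort(cfg, clone_tables = FALSE)$metadata
  tab <- matrix(c(sum(md$marker[md$group == "case"]),
                  sum(md$group == "case") - sum(md$marker[md$group == "case"]),
                  sum(md$marker[md$group == "control"]),
                  sum(md$group == "control") - sum(md$marker[md$group == "control"])),
                2, byrow = TRUE)
  expect_equal(tab, matrix(c(6, 0, 0, 12), 2, byrow = TRUE))
  # most extreme table at these margins: p = 1 / choose(18, 6)
  expect_equal(fisher_exact_2x2(tab), 1 / choose(18, 6), tolerance = 1e-12)
})

test_that("calibrate_sigma_shift hits the requested clonality difference", {
  cfg <- sim_config(seed = 76)
  sh <- calibrate_sigma_shift(cfg, 0.10)
  expect_gt(sh, 0.1); expect_lt(sh, 1.5)
  # realized difference on fresh cohorts is near the target
  cl_for <- function(shift, seeds) {
    vapply(seeds, function(s) {
      c2 <- sim_config(seed = s, sigma_shift = shift)
      clonality(tme_repertoire(simulate_repertoire(c2, 1)$repertoire))
    }, 1)
  }
  diff_real <- mean(cl_for(sh, 301:315)) - mean(cl_for(0, 301:315))
  expect_lt(abs(diff_real - 0.10), 0.04)
})
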