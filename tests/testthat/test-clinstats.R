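test_that("km_fit reproduces the hand product-limit computation", {
  km <- km_fit(1:5, rep(1, 5))
  expect_s3_class(km, "km_curve")
  # S drops by 1/5 at each event time; after t=3 the estimate is 0.4
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)

  all_cens <- km_fit(c(2, 4, 6), c(0, 0, 0))
  expect_true(is.na(all_cens$median))   # never reaches 0.5: not reached

  solo <- km_fit(5, 1)
  expect_equal(solo$median, 5)

  expect_error(km_fit(c(-1, 2), c(1, 1)), class = "tmerep_argument_error")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(61)
  t <- sort(sample(1:100, 20))
  km <- km_fit(t, rep(1, 20))
  ecdf_surv <- 1 - ecdf(t)(km$time)
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("log-rank: identical groups give statistic 0 / p 1; separated groups are detected", {
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p.value, 1)

  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(10, 11, 12), c(1, 1, 1))
  expect_lt(lr$p.value, 0.05)

  # label symmetry
  set.seed(62)
  ta <- rexp(8, 0.2); tb <- rexp(10, 0.1)
  ea <- rbinom(8, 1, 0.8); eb <- rbinom(10, 1, 0.8)
  l1 <- logrank_test(ta, ea, tb, eb)
  l2 <- logrank_test(tb, eb, ta, ea)
  expect_equal(l1$statistic, l2$statistic, tolerance = 1e-10)

  # no events anywhere: uninformative by convention
  none <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_equal(none$p.value, 1)
})

test_that("log-rank chi-squared p agrees with a label-permutation p", {
  set.seed(63)
  ta <- rexp(10, 0.15); ea <- rbinom(10, 1, 0.85)
  tb <- rexp(12, 0.15); eb <- rbinom(12, 1, 0.85)
  obs <- logrank_test(ta, ea, tb, eb)
  time <- c(ta, tb); ev <- c(ea, eb)
  perm <- vapply(1:1000, function(i) {
    idx <- sample(22, 10)
    logrank_test(time[idx], ev[idx], time[-idx], ev[-idx])$statistic
  }, 1)
  p_perm <- mean(perm >= obs$statistic)
  expect_equal(obs$p.value, p_perm, tolerance = 0.02)
})

test_that("subset proportions divide by total lymphocytes; CD8 = 0 leaves the ratio undefined", {
  got <- subset_proportions(c(cd4_til_t = 100, cd8_til_t = 1000, til_b = 200),
                            total = 2000)
  expect_equal(got$proportions[["cd4_til_t"]], 0.05)
  expect_equal(got$cd4_cd8_ratio, 0.1)

  zeros <- subset_proportions(c(cd4_til_t = 0, cd8_til_t = 0), total = 100)
  expect_equal(unname(zeros$proportions), c(0, 0))
  expect_true(is.na(zeros$cd4_cd8_ratio))

  full <- subset_proportions(c(til_t = 500), total = 500)
  expect_equal(full$proportions[["til_t"]], 1)

  expect_error(subset_proportions(c(x = 10), total = 5),
               class = "tmerep_argument_error")
})

test_that("greedy matching picks nearest controls within the caliper, deterministically", {
  cases <- data.frame(sample_id = "case1", tumor_pct = 13.0)
  pool <- data.frame(sample_id = c("p1", "p2", "p3"),
                     tumor_pct = c(12.1, 13.5, 40.0))
  m <- match_controls(cases, pool, k = 2, continuous_key = "tumor_pct",
                      caliper = 5)
  expect_equal(m$case1, c("p2", "p1"))   # 0.5 then 0.9; 40.0 outside caliper

  expect_error(match_controls(cases, pool[0, ], k = 2,
                              continuous_key = "tumor_pct"),
               class = "tmerep_matching_error")

  # exact distance tie: lexicographically smaller sample_id wins
  pool2 <- data.frame(sample_id = c("pB", "pA"), tumor_pct = c(14, 12))
  m2 <- match_controls(cases, pool2, k = 1, continuous_key = "tumor_pct")
  expect_equal(m2$case1, "pA")
})

test_that("matching is exact on the categorical key and without replacement", {
  cases <- data.frame(sample_id = c("c1", "c2"), pct = c(10, 11),
                      tx = c("chemo", "chemo"))
  pool <- data.frame(sample_id = sprintf("p%d", 1:5),
                     pct = c(10.2, 10.4, 11.1, 10.9, 50),
                     tx = c("chemo", "chemo", "chemo", "none", "chemo"))
  m <- match_controls(cases, pool, k = 2, continuous_key = "pct",
                      categorical_key = "tx", caliper = 50)
  expect_equal(sort(unname(unlist(m))), sort(c("p1", "p2", "p3", "p5")))
  expect_false("p4" %in% unlist(m))          # wrong stratum
  expect_equal(length(intersect(m$c1, m$c2)), 0)  # no reuse
  # a case that exhausts its stratum raises a matching error naming it
  expect_error(match_controls(cases, pool[1:3, ], k = 2,
                              continuous_key = "pct", categorical_key = "tx"),
               "c[12]", class = "tmerep_matching_error")
})
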