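test_that("contingency series enumerate patients per window", {
  f <- dplyr::bind_rows(
    make_firsts("P1", "E66", "2007-02-01"),
    make_firsts("P1", "F32", "2007-05-01"),
    make_firsts("P2", "E66", "2007-02-01"),
    make_firsts("P3", "F32", "2007-03-01")
  )
  s <- make_strata(c("P1", "P2", "P3", "P4"),
                   exposed = c(TRUE, TRUE, FALSE, FALSE))
  ser <- build_contingency_series(f, s, "E66", "F32")
  expect_identical(nrow(ser), 1L)
  expect_identical(c(ser$a, ser$b, ser$c, ser$d), c(1L, 1L, 1L, 1L))
  expect_error(build_contingency_series(f, s, "E66", "E66"), "differ")
})

test_that("patients contribute only to their own window's table", {
  f <- dplyr::bind_rows(
    make_firsts("P1", "E66", "2007-02-01"),
    make_firsts("P2", "E66", "2009-02-01")
  )
  s <- dplyr::bind_rows(
    make_strata("P1", exposed = TRUE, window = "2007-08"),
    make_strata("P2", exposed = TRUE, window = "2009-10",
                anchor_date = as.Date("2009-02-01"))
  )
  ser <- build_contingency_series(f, s, "E66", "F32")
  expect_identical(ser$window, c("2007-08", "2009-10"))
  expect_identical(ser$a + ser$b, c(1L, 1L))  # one exposed patient each
})

test_that("contingency series equal a brute-force double loop", {
  set.seed(7)
  n <- 300
  pats <- sprintf("P%03d", 1:n)
  has_a <- runif(n) < 0.3
  has_b <- runif(n) < 0.4
  windows <- sample(calendar_windows(), n, TRUE)
  decades <- sample(age_decades(), n, TRUE)
  f <- dplyr::bind_rows(
    make_firsts(pats[has_a], "E66", "2007-02-01"),
    make_firsts(pats[has_b], "F32", "2007-03-01")
  )
  s <- tibble::tibble(patient_id = pats, sex = "female", exposed = has_a,
                      anchor_date = as.Date("2007-02-01"),
                      age_decade = decades, window = windows)
  ser <- build_contingency_series(f, s, "E66", "F32")
  for (i in seq_len(nrow(ser))) {
    in_cell <- decades == ser$age_decade[i] & windows == ser$window[i]
    expect_identical(ser$a[i], sum(in_cell & has_a & has_b))
    expect_identical(ser$b[i], sum(in_cell & has_a & !has_b))
    expect_identical(ser$c[i], sum(in_cell & !has_a & has_b))
    expect_identical(ser$d[i], sum(in_cell & !has_a & !has_b))
  }
  expect_identical(sum(ser$a + ser$b + ser$c + ser$d), as.integer(n))
})

test_that("single-stratum MH equals the crude OR; replication leaves it fixed", {
  one <- tibble::tibble(a = 20, b = 10, c = 10, d = 20)
  expect_equal(mantel_haenszel_or(one)$or_mh, 4)
  two <- dplyr::bind_rows(one, one)
  expect_equal(mantel_haenszel_or(two)$or_mh, 4)
  # stratum order is irrelevant
  mixed <- tibble::tibble(a = c(10, 6), b = c(5, 8), c = c(4, 2),
                          d = c(10, 12))
  expect_equal(mantel_haenszel_or(mixed),
               mantel_haenszel_or(mixed[2:1, ]))
  expect_equal(cmh_test(mixed)$statistic,
               cmh_test(mixed[2:1, ])$statistic)
})

test_that("MH estimate and RBG interval match the formula transcription", {
  tab <- tibble::tibble(a = c(10, 6), b = c(5, 8), c = c(4, 2),
                        d = c(10, 12))
  oracle <- mh_oracle(tab)
  est <- mantel_haenszel_or(tab)
  expect_equal(est$or_mh, oracle$or, tolerance = 1e-12)
  expect_equal(c(est$ci_low, est$ci_high), oracle$ci, tolerance = 1e-12)
})

test_that("MH estimator and CMH test agree with stats::mantelhaen.test", {
  set.seed(11)
  for (k in 1:5) {
    n_strata <- sample(2:5, 1)
    tab <- tibble::tibble(
      a = sample(1:30, n_strata, TRUE), b = sample(1:30, n_strata, TRUE),
      c = sample(1:30, n_strata, TRUE), d = sample(1:30, n_strata, TRUE)
    )
    arr <- array(t(as.matrix(tab))[c(1, 3, 2, 4), ],
                 dim = c(2, 2, n_strata))
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    est <- mantel_haenszel_or(tab)
    tst <- cmh_test(tab)
    expect_equal(est$or_mh, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(c(est$ci_low, est$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-10)
    expect_equal(tst$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tst$p_raw, ref$p.value, tolerance = 1e-10)
  }
})

test_that("balanced tables give a zero CMH statistic", {
  tab <- tibble::tibble(a = 10, b = 10, c = 10, d = 10)
  tst <- cmh_test(tab)
  expect_equal(tst$statistic, 0)
  expect_equal(tst$p_raw, 1)
})

test_that("single-stratum CMH equals Pearson chi-square times (n-1)/n", {
  set.seed(3)
  for (k in 1:10) {
    tab <- tibble::tibble(a = sample(1:25, 1), b = sample(1:25, 1),
                          c = sample(1:25, 1), d = sample(1:25, 1))
    n <- tab$a + tab$b + tab$c + tab$d
    pearson <- suppressWarnings(stats::chisq.test(
      matrix(c(tab$a, tab$b, tab$c, tab$d), 2, byrow = TRUE),
      correct = FALSE
    ))
    expect_equal(cmh_test(tab)$statistic,
                 unname(pearson$statistic) * (n - 1) / n,
                 tolerance = 1e-12)
  }
})

test_that("degenerate series return sentinels, never crash", {
  zero <- tibble::tibble(a = 0, b = 0, c = 0, d = 0)
  est <- mantel_haenszel_or(zero)
  expect_identical(est$flag, "undefined")
  expect_true(is.na(est$or_mh))
  tst <- cmh_test(zero)
  expect_identical(tst$flag, "degenerate")
  expect_equal(tst$p_raw, 1)
  inf <- tibble::tibble(a = 10, b = 0, c = 0, d = 10)
  est2 <- mantel_haenszel_or(inf)
  expect_identical(est2$flag, "undefined")
  expect_identical(est2$or_mh, Inf)
})

test_that("screening applies the occurrence filter and conjunction rule", {
  drafts <- tibble::tibble(
    or_mh = c(2.0, 2.0, 1.4, 2.0),
    p_raw = c(0.004, 1e-6, 1e-6, 1e-9),
    n_cooccur = c(500, 99, 500, 500)
  )
  out <- screen_associations(drafts, m = 3)
  # occurrence filter: 99 co-occurrences are filtered, never significant
  expect_true(out$filtered[2])
  expect_false(out$significant[2])
  expect_identical(attr(out, "m"), 3)
  # p_corr = min(1, m p_raw): 3 * 0.004 = 0.012 >= 0.01 -> not significant
  expect_equal(out$p_corr[1], 0.012)
  expect_false(out$significant[1])
  # small p but OR <= 1.5 -> not significant
  expect_false(out$significant[3])
  expect_true(out$significant[4])
  # default family size counts unfiltered rows
  out2 <- screen_associations(drafts)
  expect_identical(attr(out2, "m"), 3L)
  # Bonferroni p is monotone, bounded by p_raw from below and capped at 1
  m_big <- screen_associations(drafts, m = 1e9)
  expect_true(all(m_big$p_corr <= 1))
  expect_true(all(out$p_corr >= out$p_raw))
  expect_error(screen_associations(drafts, m = 0), "positive")
})

test_that("stratified pooling removes the confounding the crude OR shows", {
  cfg <- confounded_scenario(
    generator_config(n_patients = 60000, theta = 1, rho = 1, seed = 19)
  )
  pp <- run_pair_pipeline(cfg)
  crude <- dplyr::summarise(pp$series, a = sum(a), b = sum(b), c = sum(c),
                            d = sum(d))
  crude_or <- crude$a * crude$d / (crude$b * crude$c)
  expect_gt(crude_or, 1.1)
  est <- mantel_haenszel_or(pp$series)
  expect_gt(est$ci_high, 1)
  expect_lt(est$ci_low, 1)
})

test_that("screen_comorbidities assembles per-decade and pooled results", {
  cfg <- confounded_scenario(
    generator_config(n_patients = 20000, theta = 2.5, rho = 1, seed = 23)
  )
  reg <- generate_registry(cfg)
  ev <- apply_washout(filter_chapters(reg))
  f <- first_occurrences(ev)
  s <- assign_strata(f, patient_profiles(ev), "E66")
  scr <- screen_comorbidities(f, s, comorbidity_codes = "F32",
                              min_occurrence = 10)
  res <- tidy(scr)
  expect_setequal(res$age_decade, c(age_decades(), "all"))
  pooled <- res[res$age_decade == "all", ]
  # point estimate within 4 standard errors of the injected theta
  se_log <- (log(pooled$ci_high) - log(pooled$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(log(pooled$or_mh) - log(2.5)), 4 * se_log)
  # pooled co-occurrence equals the sum over decades
  expect_identical(pooled$n_cooccur,
                   sum(res$n_cooccur[res$age_decade != "all"]))
  g <- glance(scr)
  expect_identical(g$m, scr$m)
  expect_identical(g$n_tested + g$n_filtered, 7L)
  p <- autoplot(scr)
  expect_s3_class(p, "ggplot")
})
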