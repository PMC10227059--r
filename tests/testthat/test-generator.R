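test_that("identical (config, seed) yields byte-identical registries", {
  cfg <- generator_config(n_patients = 400, theta = 2, rho = 2, seed = 99)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1, r2)
})

test_that("enlarging the cohort leaves earlier patients' events untouched", {
  cfg_small <- generator_config(n_patients = 250, theta = 2, rho = 2,
                                seed = 5)
  cfg_big <- generator_config(n_patients = 400, theta = 2, rho = 2, seed = 5)
  small <- generate_registry(cfg_small)
  big <- generate_registry(cfg_big)
  ids <- unique(small$patient_id)
  big_prefix <- big[big$patient_id %in% ids, ]
  attr(small, "truth") <- NULL
  attr(big_prefix, "truth") <- NULL
  expect_equal(as.data.frame(small), as.data.frame(big_prefix))
})

test_that("generated registries respect structural invariants", {
  cfg <- generator_config(n_patients = 1500, theta = 2, rho = 2, seed = 21)
  reg <- generate_registry(cfg)
  expect_true(all(reg$admission_date >= cfg$period_start))
  expect_true(all(reg$release_date <= cfg$period_end))
  expect_true(all(reg$admission_date <= reg$release_date))
  expect_true(all(grepl("^[A-Z][0-9]{2}$", reg$code)))
  # events sharing a stay share patient and dates
  per_stay <- reg |>
    dplyr::group_by(stay_id) |>
    dplyr::summarise(
      np = dplyr::n_distinct(patient_id),
      nd = dplyr::n_distinct(admission_date),
      .groups = "drop"
    )
  expect_true(all(per_stay$np == 1L & per_stay$nd == 1L))
  # exactly one first occurrence per (patient, code) by construction
  truth <- attr(reg, "truth")
  expect_identical(nrow(truth), 1500L)
})

test_that("washout share and sex ratio match their configured targets", {
  cfg <- generator_config(n_patients = 8000, washout_fraction = 0.3,
                          sex_ratio = 0.45, seed = 13)
  reg <- generate_registry(cfg)
  truth <- attr(reg, "truth")
  se_w <- sqrt(0.3 * 0.7 / 8000)
  expect_lt(abs(mean(truth$washout) - 0.3), 4 * se_w)
  se_s <- sqrt(0.45 * 0.55 / 8000)
  expect_lt(abs(mean(truth$sex == "female") - 0.45), 4 * se_s)
  retained <- apply_washout(reg)
  share <- dplyr::n_distinct(retained$patient_id) / 8000
  expect_lt(abs(share - 0.7), 4 * se_w)
})

test_that("a null configuration produces no association and symmetric order", {
  cfg <- generator_config(n_patients = 50000, theta = 1, rho = 1, seed = 7)
  pp <- run_pair_pipeline(cfg)
  crude <- dplyr::summarise(pp$series, a = sum(a), b = sum(b), c = sum(c),
                            d = sum(d))
  or <- crude$a * crude$d / (crude$b * crude$c)
  se <- sqrt(1 / crude$a + 1 / crude$b + 1 / crude$c + 1 / crude$d)
  expect_lt(abs(log(or)), 4 * se)
  op <- ordered_pairs(pp$firsts, "E66", "F32")
  tor <- compute_tor(op, by = NULL)
  n_dir <- tor$n_a_first + tor$n_b_first
  expect_lt(abs(tor$n_a_first / n_dir - 0.5), 4 * sqrt(0.25 / n_dir))
})

test_that("theta = 1 is calibrated: mean log-OR near 0 over replicates", {
  lor <- vapply(1:200, function(i) {
    cfg <- generator_config(n_patients = 1200, theta = 1, rho = 1,
                            seed = 5000 + i,
                            baseline_prevalence = dplyr::bind_rows(
                              prevalence_table("E66", 0.2),
                              prevalence_table("F32", 0.2)
                            ))
    pp <- run_pair_pipeline(cfg)
    log(mantel_haenszel_or(pp$series)$or_mh)
  }, numeric(1))
  expect_lt(abs(mean(lor)), 3 * sd(lor) / sqrt(length(lor)))
})

test_that("rho sets the exposure-first fraction among ordered pairs", {
  cfg <- tor_config(9000, rho = 2, seed = 31)
  pp <- run_pair_pipeline(cfg)
  op <- ordered_pairs(pp$firsts, "E66", "F32")
  tor <- compute_tor(op, by = NULL)
  n_dir <- tor$n_a_first + tor$n_b_first
  expect_gte(n_dir, 1000)
  # empirical ratio converges to rho (tolerance 15%)
  expect_lt(abs(tor$tor - 2) / 2, 0.15)
  # raw exposure-first fraction approximates rho / (1 + rho) = 2/3
  expect_lt(abs(tor$n_a_first / n_dir - 2 / 3), 4 * sqrt(2 / 9 / n_dir))
})

test_that("injected theta is recovered by the stratified estimator", {
  cfg <- confounded_scenario(
    generator_config(n_patients = 30000, theta = 2.5, rho = 1, seed = 17)
  )
  pp <- run_pair_pipeline(cfg)
  est <- mantel_haenszel_or(pp$series)
  expect_gt(est$ci_high, 2.5)
  expect_lt(est$ci_low, 2.5)
})

test_that("confounded_scenario changes only the prevalence map", {
  cfg <- generator_config(n_patients = 100, theta = 1, seed = 2)
  conf <- confounded_scenario(cfg)
  flds <- setdiff(names(unclass(cfg)), "baseline_prevalence")
  expect_identical(unclass(cfg)[flds], unclass(conf)[flds])
  expect_false(identical(cfg$baseline_prevalence, conf$baseline_prevalence))
  prev <- conf$baseline_prevalence |>
    dplyr::filter(code == "E66", sex == "female") |>
    dplyr::arrange(age_decade)
  expect_true(all(diff(prev$prev) > 0))
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(generator_config(100, washout_fraction = 1.3), "\\[0, 1\\]")
  expect_error(generator_config(100, theta = -1), "theta")
  expect_error(generator_config(100, rho = Inf), "rho")
  expect_error(generator_config(100, gap_breaks = c(1080, 360)), "ascending")
  # odds inflation hitting probability 1 names the offending stratum
  expect_error(
    generator_config(100, theta = 1e15,
                     baseline_prevalence = dplyr::bind_rows(
                       prevalence_table("E66", 0.1),
                       prevalence_table("F32", 0.9)
                     )),
    "code=F32"
  )
})

test_that("generator configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 120",
    "theta: 2.5",
    "rho: 2",
    "seed: 9",
    "baseline_prevalence:",
    "  E66: 0.1",
    "  F32: 0.05"
  ), path)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_identical(cfg$n_patients, 120L)
  expect_equal(cfg$theta, 2.5)
  expect_identical(generate_registry(cfg), generate_registry(cfg))
})
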