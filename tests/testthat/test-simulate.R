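test_that("normative simulation respects the cohort envelope and summation rule", {
  d <- simulate_normative(n = 219, seed = 42)
  expect_equal(nrow(d), 219)
  expect_true(all(d$pma_scan_weeks >= 37 & d$pma_scan_weeks <= 45))
  expect_true(all(d$pma_scan_weeks >= d$ga_birth_weeks))
  expect_true(all(d$postnatal_days >= 0))
  expect_true(all(d$sex %in% c("F", "M")))
  # total tissue is exactly the component sum in every row
  expect_equal(d$total_tissue, rowSums(d[, ttv_components()]),
               tolerance = 1e-12)
  # postnatal days consistent with GA and PMA (rounding only)
  expect_true(all(abs(d$postnatal_days -
                        7 * (d$pma_scan_weeks - d$ga_birth_weeks)) <= 3.6))
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  a <- simulate_normative(n = 40, seed = 7)
  b <- simulate_normative(n = 40, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_normative(n = 40, seed = 8)))
})

test_that("zero-noise simulation lies exactly on the mean curves", {
  params <- default_curve_params()
  params <- lapply(params, function(p) { p$sigma0 <- 0; p })
  d <- simulate_normative(params, n = 25, seed = 3)
  male <- as.numeric(d$sex == "M")
  for (r in setdiff(simulated_regions(), "total_tissue")) {
    p <- params[[r]]
    mu <- p$a + p$b * (d$pma_scan_weeks - 40) + p$c * (d$pma_scan_weeks - 40)^2 +
      p$s * male + p$d * d$postnatal_days
    expect_equal(d[[r]], mu, tolerance = 1e-12)
  }
})

test_that("parameter validation names the offending region", {
  params <- default_curve_params()
  expect_error(simulate_normative(params[setdiff(names(params), "brainstem")],
                                  n = 10),
               "brainstem")
  expect_error(growth_curve_params("ventricles", a = 0.5, b = -2, sigma0 = 0.1),
               "non-positive")
  expect_error(growth_curve_params("x", a = 10, b = 0, sigma0 = 1, kappa = -0.4),
               "SD non-positive")
})

test_that("surgical cohort has consistent paired scans and ground truth", {
  sim <- simulate_chd(n = 36, seed = 5)
  expect_equal(nrow(sim$scans), 72)
  expect_equal(nrow(sim$covariates), 36)
  pre <- sim$scans[sim$scans$timepoint == "pre", ]
  post <- sim$scans[sim$scans$timepoint == "post", ]
  cv <- sim$covariates[match(pre$subject_id, sim$covariates$subject_id), ]
  expect_true(all(pre$postnatal_days < cv$age_surgery_days))
  expect_true(all(post$postnatal_days > cv$age_surgery_days))
  expect_true(all(post$pma_scan_weeks > pre$pma_scan_weeks))
  expect_true(all(post$pma_scan_weeks < 46))
  expect_true(all(pre$pma_scan_weeks >= 37))
  expect_equal(sim$scans$total_tissue,
               rowSums(sim$scans[, ttv_components()]), tolerance = 1e-12)
  # ground-truth identity to machine precision
  expect_equal(sim$truth$delta_z, sim$truth$z_post - sim$truth$z_pre,
               tolerance = 1e-15)
  expect_setequal(unique(sim$truth$region), modelled_regions())
  expect_true(all(sim$covariates$chd_category %in%
                    c("streaming", "left", "right")))
})

test_that("generated volumes reproduce the injected true Z-scores exactly", {
  sim <- simulate_chd(n = 30, seed = 9)
  sc <- true_deviation_scores(default_curve_params(), sim$scans)
  pre <- sc[sc$timepoint == "pre", ]
  key <- paste(sim$truth$subject_id, sim$truth$region)
  expect_equal(pre$z[match(key, paste(pre$subject_id, pre$region))],
               sim$truth$z_pre, tolerance = 1e-10)
})

test_that("null effects give standard-normal true pre-op Z and zero delta", {
  null_fx <- list(effect_spec(simulated_regions(), baseline_dev = 0,
                              noise_sd = 0))
  sim <- simulate_chd(effects = null_fx, n = 2000, seed = 11)
  direct <- sim$truth[sim$truth$region != "total_tissue", ]
  expect_equal(unique(direct$delta_z), 0)
  # per-region calibration of the Z_pre draw
  for (r in c("brainstem", "csf", "caudate_l")) {
    z <- direct$z_pre[direct$region == r]
    expect_lt(abs(mean(z)), 0.05)
    expect_lt(abs(stats::sd(z) - 1), 0.05)
  }
})

test_that("effect-spec validation catches bad regions and covariates", {
  expect_error(effect_spec("nonexistent_region"), "not simulated")
  expect_error(effect_spec("csf", noise_sd = -1), "noise_sd")
  bad <- list(effect_spec("csf", beta = c(not_a_covariate = 1)))
  expect_error(simulate_chd(effects = bad, n = 5, seed = 1),
               "not_a_covariate")
})

test_that("an injected bypass effect is recovered in sign across replicates", {
  fx <- list(effect_spec(c("brainstem", "caudate_r"),
                         beta = c(bypass_min = -0.004), noise_sd = 0.2))
  hits <- vapply(1:100, function(k) {
    sim <- simulate_chd(effects = fx, n = 200, seed = 5000 + k)
    dz <- sim$truth$delta_z[sim$truth$region == "brainstem"]
    stats::cor(sim$covariates$bypass_min, dz, method = "spearman") < 0
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("clinical covariates track their target medians", {
  sim <- simulate_chd(n = 1500, seed = 21)
  cv <- sim$covariates
  expect_lt(abs(stats::median(cv$age_surgery_days) - 12), 2.5)
  expect_lt(abs(stats::median(cv$bypass_min) - 153), 12)
  expect_lt(abs(stats::median(cv$picu_days) - 4), 1)
  expect_lt(abs(stats::median(cv$creatinine_umol_l) - 39), 4)
  expect_lt(abs(mean(cv$rrt) - 6 / 36), 0.04)
  expect_lt(abs(mean(cv$chd_category == "streaming") - 20 / 36), 0.05)
})
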