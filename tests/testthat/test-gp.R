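test_that("fixed-hyperparameter predictions match the closed-form posterior", {
  for (n in c(5, 40)) {
    d <- grid_scans(n, seed = n, volume_fun = function(pma, pnd, male) {
      200 + 8 * (pma - 40) + 2 * male + rnorm(length(pma), 0, 2)
    })
    names(d)[names(d) == "vol"] <- "volume"
    m <- fit_region_model(d, "volume", gp_control(min_n = 1),
                          fixed = fixed_hp)
    nd <- data.frame(pma_scan_weeks = c(38.2, 40, 43.7, 44.9),
                     postnatal_days = c(4, 0, 28, 31),
                     sex = c("F", "M", "F", "M"))
    pr <- predict(m, nd)
    orc <- oracle_gp_posterior(fixed_hp, scan_design(d), d$volume,
                               scan_design(nd))
    expect_equal(pr$mu_pred, orc$mu, tolerance = 1e-8)
    expect_equal(pr$sigma_pred, orc$sigma, tolerance = 1e-8)
  }
})

test_that("a noise-free linear trend is recovered within 0.5%", {
  d <- grid_scans(50, seed = 2, volume_fun = function(pma, pnd, male) {
    200 + 10 * (pma - 40)
  })
  names(d)[names(d) == "vol"] <- "volume"
  m <- fit_region_model(d, "volume", gp_control(min_n = 1, seed = 4))
  pr <- predict(m, d)
  expect_lt(max(abs(pr$mu_pred - d$volume) / d$volume), 0.005)
})

test_that("constant training volumes predict the constant with near-zero Z", {
  d <- grid_scans(40, seed = 3, volume_fun = function(pma, pnd, male) {
    rep(300, length(pma))
  })
  names(d)[names(d) == "vol"] <- "volume"
  m <- fit_region_model(d, "volume", gp_control(min_n = 1, seed = 5))
  pr <- predict(m, d[c(1, 20, 40), ])
  expect_equal(pr$mu_pred, rep(300, 3), tolerance = 1e-6)
  z <- deviation_z(m, d)
  expect_lt(max(abs(z$z)), 1e-4)
})

test_that("deviation Z is exactly the standardised residual and handles missing volumes", {
  d <- grid_scans(30, seed = 6, volume_fun = function(pma, pnd, male) {
    100 + 5 * (pma - 40) + rnorm(length(pma))
  })
  names(d)[names(d) == "vol"] <- "volume"
  m <- fit_region_model(d, "volume", gp_control(min_n = 1),
                        fixed = fixed_hp)
  probe <- d[1:3, ]
  pr <- predict(m, probe)
  probe$volume <- pr$mu_pred + c(0, 2, -1.3) * pr$sigma_pred
  z <- deviation_z(m, probe)
  expect_equal(z$z, c(0, 2, -1.3), tolerance = 1e-10)
  probe$volume[2] <- NA
  z2 <- deviation_z(m, probe)
  expect_true(is.na(z2$z[2]) && !anyNA(z2$z[-2]))
})

test_that("predictive variance grows away from the data and shrinks with new points", {
  d <- grid_scans(25, seed = 8, volume_fun = function(pma, pnd, male) {
    50 + 3 * (pma - 40) + rnorm(length(pma), 0, 1)
  })
  d <- d[d$pma_scan_weeks < 42, ]  # leave 42+ unobserved
  names(d)[names(d) == "vol"] <- "volume"
  m <- fit_region_model(d, "volume", gp_control(min_n = 1, margin = 5),
                        fixed = fixed_hp)
  dense <- data.frame(pma_scan_weeks = 39, postnatal_days = 0, sex = "F")
  far <- data.frame(pma_scan_weeks = 44.9, postnatal_days = 34, sex = "F")
  expect_gt(predict(m, far)$sigma_pred, predict(m, dense)$sigma_pred)

  # monotone information: adding an observation at x cannot inflate var(x)
  x_new <- data.frame(pma_scan_weeks = 43.5, postnatal_days = 24, sex = "M")
  before <- predict(m, x_new)$sigma_pred
  d2 <- rbind(d, within(d[1, ], {
    pma_scan_weeks <- 43.5; postnatal_days <- 24; sex <- "M"; volume <- 60
  }))
  m2 <- fit_region_model(d2, "volume", gp_control(min_n = 1, margin = 5),
                         fixed = fixed_hp)
  expect_lte(predict(m2, x_new)$sigma_pred, before + 1e-10)
})

test_that("out-of-range prediction warns by default and errors under strict", {
  d <- grid_scans(30, seed = 9, volume_fun = function(pma, pnd, male) {
    100 + rnorm(length(pma))
  })
  names(d)[names(d) == "vol"] <- "volume"
  m <- fit_region_model(d, "volume", gp_control(min_n = 1),
                        fixed = fixed_hp)
  out <- data.frame(pma_scan_weeks = 46.8, postnatal_days = 50, sex = "F")
  expect_warning(predict(m, out), "outside the supported PMA range")
  ms <- fit_region_model(d, "volume", gp_control(min_n = 1, strict = TRUE),
                         fixed = fixed_hp)
  expect_error(predict(ms, out), "outside the supported PMA range")
})

test_that("refits are deterministic and region errors are aggregated", {
  d <- simulate_normative(n = 60, seed = 12)
  m1 <- fit_region_model(d, "cerebellum", gp_control(restarts = 3, seed = 2))
  m2 <- fit_region_model(d, "cerebellum", gp_control(restarts = 3, seed = 2))
  expect_identical(m1$hyperparams, m2$hyperparams)
  expect_error(fit_region_model(d[1:10, ], "cerebellum"), "complete rows")
  expect_error(fit_all_regions(d[setdiff(names(d), "brainstem")]),
               "brainstem")
})

test_that("with no sex offset in the generator, fitted curves agree across sex", {
  params <- default_curve_params()
  params <- lapply(params, function(p) { p$s <- 0; p })
  d <- simulate_normative(params, n = 150, seed = 13)
  m <- fit_region_model(d, "cortical_gm", gp_control(seed = 3))
  nd <- function(sx) data.frame(pma_scan_weeks = seq(38, 44, 1),
                                postnatal_days = 7, sex = sx)
  gap <- abs(predict(m, nd("M"))$mu_pred - predict(m, nd("F"))$mu_pred)
  # any apparent sex gap stays well inside the residual noise scale
  expect_lt(max(gap), 0.5 * params$cortical_gm$sigma0)
})

test_that("model JSON round-trips to identical predictions", {
  d <- simulate_normative(n = 60, seed = 14)
  m <- fit_all_regions(d, regions = c("brainstem", "csf"),
                       control = gp_control(restarts = 2, seed = 6))
  path <- tempfile(fileext = ".json")
  write_models_json(m, path)
  m2 <- read_models_json(path)
  nd <- d[1:10, ]
  for (r in c("brainstem", "csf")) {
    expect_equal(predict(m2[[r]], nd), predict(m[[r]], nd),
                 tolerance = 1e-10)
  }
})

test_that("the 13-region fit returns one model per region", {
  d <- simulate_normative(n = 80, seed = 15)
  ctl <- gp_control(restarts = 1, seed = 2, maxit = 60)
  models <- fit_all_regions(d, control = ctl)
  expect_named(models, modelled_regions(), ignore.order = TRUE)
  expect_s3_class(models, "gp_normative")
  expect_true(all(vapply(unclass(models), function(m) {
    all(m$hyperparams[c("sf", "sn")] > 0)
  }, logical(1))))
})
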