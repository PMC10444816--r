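test_that("the generator is deterministic under seed at every stage", {
  cells <- default_reef_cells(4)
  truth <- synthetic_truth(seed = 123)
  s1 <- generate_sst(cells, c(1990, 2000), truth)
  s2 <- generate_sst(cells, c(1990, 2000), truth)
  expect_identical(s1, s2)
  cl <- lapply(s1, compute_climatology, period = c(1990, 2000))
  dhw <- mapply(dhw_series, s1, cl,
                MoreArgs = list(scenario = build_offsets(0.1, c(1990, 2000))),
                SIMPLIFY = FALSE)
  dates <- as.Date(c("1998-10-01", "1999-10-01"))
  o1 <- generate_surveys(dhw, truth, 40, dates, cells, seed = 9)
  o2 <- generate_surveys(dhw, truth, 40, dates, cells, seed = 9)
  expect_identical(o1, o2)
  o3 <- generate_surveys(dhw, truth, 40, dates, cells, seed = 10)
  expect_false(identical(o1$severity, o3$severity))
})

test_that("noise-free generator settings reproduce the deterministic cycle", {
  cells <- default_reef_cells(1)
  truth <- synthetic_truth(sst_amplitude = 0, trend = 0, noise_sd = 0,
                           heatwaves = data.frame(year = integer(),
                                                  start_doy = integer(),
                                                  duration = integer(),
                                                  amplitude = numeric()),
                           seed = 2)
  s <- generate_sst(cells, c(1990, 1996), truth)[[1]]
  expect_equal(s$sst, rep(truth$sst$mean, length(s$sst)), tolerance = 1e-12)
})

test_that("AR(1) anomalies carry the requested lag-1 autocorrelation", {
  cells <- default_reef_cells(1)
  truth <- synthetic_truth(sst_amplitude = 0, trend = 0, ar1 = 0.8,
                           noise_sd = 0.3,
                           heatwaves = data.frame(year = integer(),
                                                  start_doy = integer(),
                                                  duration = integer(),
                                                  amplitude = numeric()),
                           seed = 4)
  s <- generate_sst(cells, c(1985, 2015), truth)[[1]]  # ~1.1e4 days
  anom <- s$sst - mean(s$sst)
  r1 <- cor(anom[-1], anom[-length(anom)])
  expect_equal(r1, 0.8, tolerance = 0.05)
})

test_that("a scheduled heatwave produces the DHW its construction implies", {
  cells <- default_reef_cells(1)
  # flat 28 C baseline; MMM = 28, so a square-ish pulse of known exceedance
  # can be checked against the brute-force DHW oracle
  truth <- synthetic_truth(sst_amplitude = 0, trend = 0, noise_sd = 0,
                           heatwaves = data.frame(year = 1998L,
                                                  start_doy = 200L,
                                                  duration = 60L,
                                                  amplitude = 2.5),
                           seed = 8)
  s <- generate_sst(cells, c(1990, 1999), truth)[[1]]
  cl <- compute_climatology(s, c(1990, 1997))
  expect_equal(cl$mmm, truth$sst$mean, tolerance = 1e-9)
  hs <- compute_hotspots(s, cl)
  d <- dhw_series(s, cl)
  expect_equal(max(d$dhw), max(naive_dhw(hs)), tolerance = 1e-9)
  # half-sine pulse of peak 2.5: days above the 1 C cutoff contribute
  expected_peak <- sum(hs[hs >= 1]) / 7
  expect_equal(max(d$dhw), expected_peak, tolerance = 1e-9)
  expect_gt(max(d$dhw), 5)
})

test_that("survey severities follow the beta-logit response in expectation", {
  cells <- default_reef_cells(2)
  truth <- synthetic_truth(beta0 = -3, beta1 = 0.8, theta = 15,
                           matern_sigma = 0, seed = 14)
  sst <- generate_sst(cells, c(1995, 2000), truth)
  cl <- lapply(sst, compute_climatology, period = c(1995, 2000))
  dhw <- mapply(dhw_series, sst, cl, SIMPLIFY = FALSE)
  dates <- as.Date(c("1998-10-01", "1996-10-01"))
  obs <- generate_surveys(dhw, truth, 4000, dates, cells, n_sites = 50,
                          seed = 15)
  for (dt in dates) {
    sel <- obs$date == dt
    if (!any(sel)) next
    expected <- mean(plogis(truth$beta0 + truth$beta1 * obs$dhw_true[sel]))
    expect_lt(abs(mean(obs$percent[sel]) / 100 - expected), 0.005)
  }
  # binning consistency with the observations module
  expect_identical(obs$severity, severity_from_percent(obs$percent))
})

test_that("null response model gives identical severity distributions", {
  cells <- default_reef_cells(2)
  truth <- synthetic_truth(beta0 = -1, beta1 = 0, theta = 400,
                           matern_sigma = 0, seed = 25)
  sst <- generate_sst(cells, c(1995, 2000), truth)
  cl <- lapply(sst, compute_climatology, period = c(1995, 2000))
  dhw <- mapply(dhw_series, sst, cl, SIMPLIFY = FALSE)
  dates <- as.Date(c("1998-10-01", "1996-10-01"))  # heatwave vs quiet year
  obs <- generate_surveys(dhw, truth, 3000, dates, cells, seed = 26)
  m <- tapply(obs$percent, obs$date, mean)
  expect_lt(abs(m[1] - m[2]), 1.5)
})

test_that("generated files round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  cells <- default_reef_cells(3)
  truth <- synthetic_truth(seed = 33)
  sst <- generate_sst(cells, c(1996, 2000), truth)
  cl <- lapply(sst, compute_climatology, period = c(1996, 2000))
  dhw <- mapply(dhw_series, sst, cl, SIMPLIFY = FALSE)
  obs <- generate_surveys(dhw, truth, 30, as.Date("1998-10-01"), cells,
                          seed = 34)
  write_synthetic_dataset(dir, sst, obs, truth)
  sst2 <- read_sst_csv(file.path(dir, "sst.csv"))
  expect_equal(length(sst2), 3)
  expect_equal(sst2[["cell01"]]$sst, sst[["cell01"]]$sst)
  expect_equal(sst2[["cell02"]]$dates, sst[["cell02"]]$dates)
  obs2 <- read_observations(file.path(dir, "observations.csv"))
  expect_equal(obs2$severity, obs$severity)
  expect_equal(obs2$date, obs$date)
  # attached DHW from the written series matches the generator's values
  att <- attach_dhw(obs2, dhw)
  expect_equal(att$dhw, obs$dhw_true, tolerance = 1e-9)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$rho_true, truth$rho_true)
})

test_that("generator rejects out-of-bounds configurations", {
  expect_error(synthetic_truth(rho_true = -0.1))
  expect_error(synthetic_truth(ar1 = 1.2))
  expect_error(synthetic_truth(sst_mean = 60), "sanity")
  cells <- default_reef_cells(2)
  expect_error(generate_sst(cells, c(2000, 2002)), "at least 5 years")
  truth <- synthetic_truth(seed = 1)
  sst <- generate_sst(cells, c(1996, 2000), truth)
  cl <- lapply(sst, compute_climatology, period = c(1996, 2000))
  dhw <- mapply(dhw_series, sst, cl, SIMPLIFY = FALSE)
  expect_error(generate_surveys(dhw, truth, 0, as.Date("1998-10-01"), cells),
               "n_obs")
  expect_error(generate_surveys(dhw, truth, 5, as.Date("2030-10-01"), cells),
               "outside SST coverage")
})
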