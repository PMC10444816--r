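test_that("constant series has a constant smoothed climatology", {
  s <- const_series(27.5, years = c(1985, 2010))
  cl <- smooth_daily_climatology(s, c(1985, 2010))
  expect_length(cl, 365)
  expect_equal(cl, rep(27.5, 365))
})

test_that("a period-365 sinusoid is damped by the 31-day boxcar factor", {
  d <- seq(as.Date("1985-01-01"), as.Date("2010-12-31"), by = "day")
  doy <- coraltol:::doy365(d)
  s <- daily_series("c", 7, 134, d, 28 + sin(2 * pi * doy / 365))
  cl <- smooth_daily_climatology(s, c(1985, 2010))
  # closed-form attenuation of a centred 31-day mean at period 365
  damp <- sin(31 * pi / 365) / (31 * sin(pi / 365))
  expected <- 28 + damp * sin(2 * pi * (1:365) / 365)
  expect_equal(cl, expected, tolerance = 1e-3)
})

test_that("a single-day spike spreads linearly over the 31-day window", {
  s <- const_series(28, years = c(2001, 2004))
  spike_day <- as.Date("2002-07-15")
  s$sst[s$dates == spike_day] <- 33
  cl <- smooth_daily_climatology(s, c(2001, 2004))
  doy <- coraltol:::doy365(spike_day)
  in_win <- abs(1:365 - doy) <= 15
  expect_equal(cl[in_win], rep(28 + 5 / (31 * 4), sum(in_win)),
               tolerance = 1e-12)
  expect_equal(cl[!in_win], rep(28, sum(!in_win)), tolerance = 1e-12)
})

test_that("delta correction is exact for identical series and removes constant bias", {
  truth <- synthetic_truth(seed = 5)
  obs <- generate_sst(default_reef_cells(1), c(1985, 2012), truth)[[1]]
  # identity
  adj <- delta_correct(obs, obs, c(1985, 2010))
  expect_identical(adj$sst, obs$sst)
  # constant bias removed
  gcm <- obs
  gcm$sst <- obs$sst + 2
  adj2 <- delta_correct(gcm, obs, c(1985, 2010))
  expect_equal(adj2$sst, obs$sst, tolerance = 1e-9)
  # post-correction baseline climatology equals the observational one
  c_adj <- smooth_daily_climatology(adj2, c(1985, 2010))
  c_obs <- smooth_daily_climatology(obs, c(1985, 2010))
  expect_equal(c_adj, c_obs, tolerance = 1e-9)
})

test_that("seasonal-only bias is removed over the baseline", {
  truth <- synthetic_truth(seed = 6)
  obs <- generate_sst(default_reef_cells(1), c(1985, 2012), truth)[[1]]
  gcm <- obs
  mon <- coraltol:::date_ymd(obs$dates)$month
  gcm$sst <- obs$sst + ifelse(mon %in% 6:9, 1.5, 0)
  adj <- delta_correct(gcm, obs, c(1985, 2010))
  c_adj <- smooth_daily_climatology(adj, c(1985, 2010))
  c_obs <- smooth_daily_climatology(obs, c(1985, 2010))
  # away from the bias step edges (> 30 days, twice the running-mean
  # half-width: the correction smooths the already-smoothed bias) the
  # seasonal bias cancels exactly through the filter
  interior <- c(20:80, 190:240, 320:360)
  expect_equal(c_adj[interior], c_obs[interior], tolerance = 1e-9)
  # at the edges the residual is bounded by the bias magnitude spread
  expect_lt(max(abs(c_adj - c_obs)), 1.5)
})

test_that("360-day model calendars are rejected, no-leap calendars accepted", {
  d <- seq(as.Date("1985-01-01"), as.Date("2010-12-31"), by = "day")
  keep <- unlist(tapply(seq_along(d), format(d, "%Y"),
                        function(i) i[seq_len(360)]))
  s360 <- daily_series("g", 7, 134, d[keep], rep(28, length(keep)))
  obs <- const_series(28, years = c(1985, 2010))
  expect_error(delta_correct(s360, obs, c(1986, 2009)), "360-day")
  # no-leap calendar (Feb 29 absent) passes
  noleap <- d[format(d, "%m-%d") != "02-29"]
  snl <- daily_series("g", 7, 134, noleap, rep(28, length(noleap)))
  expect_silent(delta_correct(snl, obs, c(1985, 2010)))
})

test_that("bleaching events trigger at 8 C-weeks inclusive", {
  am <- c("2030" = 8.0, "2031" = 7.99, "2032" = 0, "2033" = NA, "2034" = 12)
  ev <- detect_bleaching_years(am)
  expect_equal(unname(ev), c(TRUE, FALSE, FALSE, NA, TRUE))
})

test_that("high-frequency flags follow the centred y-4..y+5 decade window", {
  # events at y-1 and y+2 flag year y
  ev <- rep(FALSE, 11)
  ev[c(5, 8)] <- TRUE
  expect_true(high_frequency_flags(ev)[6])
  # a single isolated event flags nothing
  ev1 <- rep(FALSE, 30)
  ev1[15] <- TRUE
  expect_false(any(high_frequency_flags(ev1)))
  # events every year flag every year
  expect_true(all(high_frequency_flags(rep(TRUE, 20))))
  # truncation attribute marks the edges
  tr <- attr(high_frequency_flags(rep(FALSE, 20)), "truncated")
  expect_equal(which(tr), c(1:4, 16:20))
})

test_that("high-frequency flags match the brute-force window counter", {
  set.seed(77)
  for (rep in 1:50) {
    ev <- runif(100) < 0.15
    expect_identical(as.logical(high_frequency_flags(ev)), naive_hf(ev))
  }
})

test_that("flags ignore events outside the decade window", {
  ev <- rep(FALSE, 40)
  ev[c(1, 40)] <- TRUE
  flags <- high_frequency_flags(ev)
  expect_false(any(flags[10:30]))
})

test_that("ensemble trajectories average across GCMs with SE = sd/sqrt(G)", {
  tr <- ensemble_trajectory(cbind(c(0.2, 1), c(0.4, 1)))
  expect_equal(tr$mean, c(0.3, 1))
  expect_equal(tr$se, c(0.1, 0), tolerance = 1e-9)
  expect_warning(tr1 <- ensemble_trajectory(matrix(0.5, 3, 1)), "single GCM")
  expect_true(all(is.na(tr1$se)))
  # identical GCMs -> SE 0
  expect_equal(ensemble_trajectory(cbind(c(0.1, 0.9), c(0.1, 0.9)))$se,
               c(0, 0))
})

test_that("projected bleaching is non-increasing in the enhancement rate", {
  cells <- default_reef_cells(3)
  truth <- synthetic_truth(trend = 0.45, seed = 31)
  sst <- generate_sst(cells, c(1985, 2040), truth)
  clims <- lapply(sst, compute_climatology, period = c(1985, 2012))
  gcm_sst <- list(g1 = sst)
  prev_events <- Inf
  prev_prop <- rep(Inf, 56)
  for (r in c(0, 0.1, 0.2, 0.3)) {
    sc <- build_offsets(r, c(1985, 2040))
    suppressWarnings(pt <- project_bleaching(gcm_sst, clims, sc))
    ev <- sum(pt$cells$event, na.rm = TRUE)
    expect_lte(ev, prev_events)
    expect_true(all(pt$trajectory$mean <= prev_prop + 1e-12))
    prev_events <- ev
    prev_prop <- pt$trajectory$mean
  }
})

test_that("bilinear and nearest-neighbour regridding reproduce known fields", {
  lon <- seq(130, 136, by = 1)
  lat <- seq(4, 10, by = 1 / 3)
  # a linear field is reproduced exactly by bilinear interpolation
  z <- outer(lon, lat, function(x, y) 2 * x + 3 * y)
  p_lon <- c(130.5, 133.25, 135.9)
  p_lat <- c(4.1, 7.77, 9.9)
  expect_equal(regrid_field(lon, lat, z, p_lon, p_lat, "bilinear"),
               2 * p_lon + 3 * p_lat, tolerance = 1e-9)
  # nearest neighbour picks the closest node value
  expect_equal(regrid_field(lon, lat, z, 130.4, 4.1, "nearest"),
               2 * 130 + 3 * 4)
})
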