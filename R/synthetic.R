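#' Ground truth for the synthetic reef system
#'
#' Bundles every parameter of the synthetic-data generator: the true
#' tolerance-enhancement rate, the bleaching response model
#' (`beta0`, `beta1`, `theta`), the Matern field of spatially correlated
#' error, the daily SST process (seasonal cycle, warming trend, AR(1)
#' anomalies) and the heatwave schedule. Defaults emulate a west-Pacific
#' barrier-reef system: mean SST 28.5 degC, seasonal amplitude 0.9 degC
#' peaking mid-September, a 0.15 degC/decade warming trend, persistent
#' (AR 0.7) anomalies of sd 0.25 degC, and three ~2 degC regional marine
#' heatwaves in 1998, 2010 and 2017, so that divergent bleaching between
#' early and late events arises purely from `rho_true`.
#'
#' @param rho_true True tolerance-enhancement rate, degC/decade.
#' @param beta0,beta1,theta Bleaching response: intercept, DHW slope
#'   (per degC-week) and beta precision.
#' @param matern_range_km,matern_sigma Latent spatial field parameters.
#' @param sst_mean,sst_amplitude Seasonal cycle mean and amplitude (degC).
#' @param peak_doy Day of year of the seasonal SST maximum.
#' @param trend Warming trend, degC/decade.
#' @param ar1,noise_sd AR(1) coefficient and innovation sd of daily
#'   anomalies.
#' @param heatwaves `data.frame` with `year`, `start_doy`, `duration`
#'   (days), `amplitude` (degC, peak of a half-sine pulse).
#' @param seed Integer seed stored with the truth.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(rho_true = 0.1, beta0 = -3, beta1 = 0.8,
                            theta = 15, matern_range_km = 20,
                            matern_sigma = 0.5, sst_mean = 28.5,
                            sst_amplitude = 0.9, peak_doy = 258,
                            trend = 0.15, ar1 = 0.7, noise_sd = 0.25,
                            heatwaves = data.frame(
                              year = c(1998L, 2010L, 2017L),
                              start_doy = c(210L, 210L, 210L),
                              duration = c(60L, 60L, 60L),
                              amplitude = c(1.5, 1.45, 1.35)),
                            seed = 1L) {
  stopifnot(rho_true >= 0, theta > 0, matern_range_km > 0, matern_sigma >= 0,
            abs(ar1) < 1, noise_sd >= 0, sst_amplitude >= 0)
  if (sst_mean < 0 || sst_mean > 35 || trend < -1 || trend > 1)
    stop("SST process parameters outside sanity bounds")
  structure(list(rho_true = rho_true, beta0 = beta0, beta1 = beta1,
                 theta = theta,
                 matern = list(range_km = matern_range_km,
                               sigma = matern_sigma, nu = 1),
                 sst = list(mean = sst_mean, amplitude = sst_amplitude,
                            peak_doy = peak_doy, trend = trend, ar1 = ar1,
                            noise_sd = noise_sd),
                 heatwaves = heatwaves, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Default synthetic reef-cell geometry
#'
#' Cells on the 0.05-degree satellite grid arranged along a roughly
#' north-south barrier-reef axis spanning about 100 km, so a 20 km Matern
#' correlation range is meaningful.
#'
#' @param n Number of cells (default 20).
#' @return `data.frame` with `cell_id`, `lat`, `lon` (cell centres).
#' @export
default_reef_cells <- function(n = 20L) {
  iy <- seq(140L, 140L + (n - 1L) * 1L)          # 0.05 deg steps northward
  ix <- 2690L + rep(c(0L, 1L), length.out = n)   # slight east-west stagger
  data.frame(cell_id = sprintf("cell%02d", seq_len(n)),
             lat = iy * 0.05 + 0.025,
             lon = ix * 0.05 + 0.025)
}

#' Generate synthetic daily SST for a set of reef cells
#'
#' `sst(t) = mean + gradient(lat) + amplitude sin-cycle + trend (t - t0)
#'  + AR(1) anomalies + heatwave pulses`, with a half-sine pulse per
#' scheduled heatwave shared across cells (a regional event) and
#' independent per-cell AR(1) anomaly streams. A weak meridional gradient
#' (0.2 degC across the domain) distinguishes the cells' climatologies.
#' Fully reproducible from `truth$seed`.
#'
#' @param cells `data.frame` as from [default_reef_cells()].
#' @param years Integer `c(first, last)`; at least 5 years.
#' @param truth A [synthetic_truth()].
#' @return Named list of [daily_series()], one per cell.
#' @export
generate_sst <- function(cells, years = c(1985L, 2020L),
                         truth = synthetic_truth()) {
  stopifnot(nrow(cells) >= 1L, length(years) == 2L)
  if (years[2L] - years[1L] + 1L < 5L) stop("at least 5 years of SST required")
  p <- truth$sst
  dates <- seq(as.Date(sprintf("%d-01-01", years[1L])),
               as.Date(sprintf("%d-12-31", years[2L])), by = "day")
  nd <- length(dates)
  doy <- doy365(dates)
  yrs <- series_years(dates)
  seasonal <- p$amplitude * sin(2 * pi * (doy - (p$peak_doy - 365 / 4)) / 365)
  tdec <- as.numeric(dates - as.Date(sprintf("%d-07-01", years[1L]))) / 3652.5
  pulse <- numeric(nd)
  hw <- truth$heatwaves
  for (k in seq_len(nrow(hw))) {
    idx <- which(yrs == hw$year[k] & doy >= hw$start_doy[k] &
                   doy < hw$start_doy[k] + hw$duration[k])
    pulse[idx] <- pulse[idx] +
      hw$amplitude[k] * sin(pi * (doy[idx] - hw$start_doy[k]) / hw$duration[k])
  }
  grad <- 0.2 * (cells$lat - mean(cells$lat)) /
    max(diff(range(cells$lat)), 0.05)
  set.seed(truth$seed)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    eps <- stats::rnorm(nd, 0, p$noise_sd)
    anom <- as.numeric(stats::filter(eps, p$ar1, method = "recursive"))
    sst <- p$mean + grad[ci] + seasonal + p$trend * tdec + anom + pulse
    out[[ci]] <- daily_series(cells$cell_id[ci], cells$lat[ci], cells$lon[ci],
                              dates, sst)
  }
  names(out) <- cells$cell_id
  out
}

#' Generate bleaching survey records from the response model
#'
#' Draws a pool of survey sites (each placed uniformly inside a randomly
#' chosen reef cell -- real survey programmes revisit named reef sites
#' across years), one latent Matern field value per site, then for each
#' record a site and a survey date. The record's bleaching probability is
#' `pi = plogis(beta0 + beta1 DHW + u_site)` with DHW taken under the true
#' tolerance scenario on the survey date; percent bleached is drawn from
#' `Beta(pi theta, (1 - pi) theta)` and binned to a severity score. The
#' emitted table round-trips through [write_observations()] /
#' [read_observations()].
#'
#' @param dhw_true List of `dhw_series` computed under `truth$rho_true`.
#' @param truth A [synthetic_truth()].
#' @param n_obs Number of records (>= 1).
#' @param survey_dates `Date` vector of candidate survey dates (records are
#'   spread across them evenly at random); must be covered by `dhw_true`.
#' @param cells Cell geometry used to place sites.
#' @param n_sites Size of the survey-site pool (default 80).
#' @param seed Seed (default derived from `truth$seed`).
#' @return Observation `data.frame` with `record_id`, `date`, `day_known`,
#'   `lat`, `lon`, `severity`, `percent`, plus generator-truth columns
#'   `dhw_true` and `u_true`.
#' @export
generate_surveys <- function(dhw_true, truth, n_obs,
                             survey_dates, cells, n_sites = 80L,
                             seed = truth$seed + 1000L) {
  if (n_obs < 1L) stop("n_obs must be >= 1")
  set.seed(as.integer(seed))
  n_sites <- min(as.integer(n_sites), n_obs)
  site_cell <- sample.int(length(dhw_true), n_sites, replace = TRUE)
  site_lat <- vapply(dhw_true[site_cell], `[[`, 0, "lat") +
    stats::runif(n_sites, -0.025, 0.025)
  site_lon <- vapply(dhw_true[site_cell], `[[`, 0, "lon") +
    stats::runif(n_sites, -0.025, 0.025)
  u_site <- if (truth$matern$sigma > 0) {
    D <- distance_matrix_km(site_lat, site_lon)
    S <- matern_covariance(D, truth$matern$sigma, truth$matern$range_km,
                           truth$matern$nu)
    drop(crossprod(chol(S), stats::rnorm(n_sites)))
  } else numeric(n_sites)

  site <- sample(rep_len(seq_len(n_sites), n_obs))
  date_idx <- sample(rep_len(seq_along(survey_dates), n_obs))
  dd <- survey_dates[date_idx]
  dhw <- vapply(seq_len(n_obs), function(i) {
    s <- dhw_true[[site_cell[site[i]]]]
    j <- as.integer(dd[i]) - as.integer(s$dates[1L]) + 1L
    if (j < 1L || j > length(s$dates))
      stop("survey date outside SST coverage: ", format(dd[i]))
    s$dhw[j]
  }, numeric(1))
  if (anyNA(dhw)) stop("missing DHW at a sampled survey date")
  u <- u_site[site]
  pi_i <- stats::plogis(truth$beta0 + truth$beta1 * dhw + u)
  percent <- 100 * stats::rbeta(n_obs, pi_i * truth$theta,
                                (1 - pi_i) * truth$theta)
  percent <- pmin(pmax(percent, 0), 100)
  data.frame(record_id = sprintf("r%04d", seq_len(n_obs)),
             date = dd, day_known = TRUE,
             lat = site_lat[site], lon = site_lon[site],
             severity = severity_from_percent(percent), percent = percent,
             dhw_true = dhw, u_true = u)
}

#' Default survey calendar for the synthetic system
#'
#' A weighted multiset of survey dates (1 October, just after the seasonal
#' heat-stress peak): records are allocated proportionally to the calendar,
#' so the large-scale survey years -- the two historic mass-bleaching years
#' and four consecutive recent years including the third heatwave -- carry
#' the bulk of the records, while the sporadic low-bleaching years between
#' them contribute only a few records each, mirroring how large survey
#' programmes dominate compiled bleaching datasets.
#'
#' @param major Large-scale survey years (weight `major_weight` each).
#' @param sporadic Sporadic survey years (weight 1 each).
#' @param major_weight Relative record allocation of a major survey year.
#' @return `Date` vector (with repeats encoding the weights).
#' @export
default_survey_dates <- function(major = c(1998L, 2010L, 2014L, 2015L,
                                           2016L, 2017L),
                                 sporadic = c(2001L, 2002L, 2003L, 2006L),
                                 major_weight = 9L) {
  yy <- c(rep(major, each = major_weight), sporadic)
  as.Date(sprintf("%d-10-01", sort(yy)))
}

#' End-to-end rate-recovery experiment
#'
#' For each replicate: generate daily SST, compute the true-scenario DHW,
#' generate surveys from the response model, scan the candidate rate grid
#' and record the selected rate; also record whether the 95% intervals from
#' the fit at the rate nearest `rho_true` cover the true `beta0`, `beta1`.
#' The report's pass flag requires the modal selected rate to be within
#' `tol_steps` grid steps of `rho_true`.
#'
#' @param rho_true True enhancement rate (degC/decade).
#' @param n_obs Records per replicate (default 300).
#' @param replicates Number of replicates (default 20).
#' @param rates Candidate grid (default 0 to 0.3 by 0.025).
#' @param cells,years,truth_args Generator configuration; `truth_args` is a
#'   list of overrides passed to [synthetic_truth()].
#' @param seed Master seed; replicate seeds are fixed offsets from it.
#' @param tol_steps Allowed distance (grid steps) between the modal selected
#'   rate and `rho_true`.
#' @param ... Fit options forwarded to [run_rate_scan()].
#' @return List of class `recovery_report`: `selected` (per-replicate
#'   rates), `modal_rate`, `coverage` (beta0/beta1 CI coverage proportions),
#'   `flat_profiles`, `pass`, `rho_true`, `seed`.
#' @export
recovery_experiment <- function(rho_true = 0.1, n_obs = 300L,
                                replicates = 20L,
                                rates = seq(0, 0.3, by = 0.025),
                                cells = default_reef_cells(),
                                years = c(1985L, 2020L),
                                truth_args = list(), seed = 1L,
                                tol_steps = 1L, ...) {
  step <- stats::median(diff(sort(rates)))
  selected <- numeric(replicates)
  cov0 <- cov1 <- flat <- logical(replicates)
  for (r in seq_len(replicates)) {
    rs <- as.integer(seed) + 7919L * r
    truth <- do.call(synthetic_truth,
                     c(list(rho_true = rho_true, seed = rs), truth_args))
    sst <- generate_sst(cells, years, truth)
    clims <- lapply(sst, compute_climatology, period = c(1985L, 2012L))
    sc_true <- build_offsets(rho_true, years)
    dhw_true <- mapply(dhw_series, sst, clims,
                       MoreArgs = list(scenario = sc_true), SIMPLIFY = FALSE)
    obs <- generate_surveys(dhw_true, truth, n_obs, default_survey_dates(),
                            cells, seed = rs + 1L)
    scan <- run_rate_scan(sst, obs[c("record_id", "date", "day_known",
                                     "lat", "lon", "severity")],
                          rates = rates, seed = rs + 2L, ...)
    selected[r] <- scan$best_rate
    flat[r] <- scan$flat_profile
    k_true <- which.min(abs(rates - rho_true))
    fit_true <- scan$fits[[k_true]]
    if (!is.null(fit_true)) {
      ci <- fit_true$uncertainty
      cov0[r] <- ci["beta0", 1] <= truth$beta0 && truth$beta0 <= ci["beta0", 2]
      cov1[r] <- ci["beta1", 1] <= truth$beta1 && truth$beta1 <= ci["beta1", 2]
    }
  }
  tab <- table(selected)
  modal <- as.numeric(names(tab)[which.max(tab)])
  structure(list(selected = selected, modal_rate = modal,
                 coverage = c(beta0 = mean(cov0), beta1 = mean(cov1)),
                 flat_profiles = sum(flat),
                 pass = abs(modal - rho_true) <= tol_steps * step + 1e-9,
                 rho_true = rho_true, rates = rates, seed = as.integer(seed)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> rho_true = %.3f: modal selected rate %.3f (%s)\n",
              x$rho_true, x$modal_rate, if (x$pass) "PASS" else "FAIL"))
  print(table(x$selected))
  cat(sprintf("CI coverage: beta0 %.0f%%, beta1 %.0f%%; flat profiles: %d\n",
              100 * x$coverage["beta0"], 100 * x$coverage["beta1"],
              x$flat_profiles))
  invisible(x)
}

#' Write a synthetic dataset (SST, observations, truth) to a directory
#'
#' Emits the same file formats the pipeline reads: `sst.csv`
#' ([read_sst_csv()]), `observations.csv` ([read_observations()]) and
#' `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param sst List of [daily_series()].
#' @param obs Observation `data.frame`.
#' @param truth A [synthetic_truth()].
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dir, sst, obs, truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sst_csv(sst, file.path(dir, "sst.csv"))
  write_observations(obs, file.path(dir, "observations.csv"))
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
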