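# Fixture builders and independent oracles shared across the suite.

# constant-SST series covering whole calendar years
const_series <- function(value = 28, years = c(1985, 2012), cell = "c1",
                         lat = 7.3, lon = 134.5) {
  d <- seq(as.Date(sprintf("%d-01-01", years[1])),
           as.Date(sprintf("%d-12-31", years[2])), by = "day")
  daily_series(cell, lat, lon, d, rep(value, length(d)))
}

# sinusoidal series: sst(t) = mean + amp * sin(2*pi*doy/365)
sine_series <- function(mean = 29, amp = 1, years = c(2001, 2001),
                        cell = "c1", lat = 7.3, lon = 134.5) {
  d <- seq(as.Date(sprintf("%d-01-01", years[1])),
           as.Date(sprintf("%d-12-31", years[2])), by = "day")
  doy <- as.integer(format(d, "%j"))
  daily_series(cell, lat, lon, d, mean + amp * sin(2 * pi * doy / 365))
}

# naive O(n * window) double-loop DHW oracle: literal re-summation of every
# trailing window, independent of the rolling implementation
naive_dhw <- function(hotspots, window = 84L, cutoff = 1) {
  n <- length(hotspots)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in max(1L, i - window + 1L):i) {
      h <- hotspots[j]
      if (is.na(h)) { s <- NA_real_; break }
      if (h >= cutoff) s <- s + h
    }
    out[i] <- s / 7
  }
  out
}

# brute-force decadal window counter for high-frequency flags
naive_hf <- function(events, min_events = 2L) {
  n <- length(events)
  vapply(seq_len(n), function(y) {
    win <- max(1L, y - 4L):min(n, y + 5L)
    sum(events[win], na.rm = TRUE) >= min_events
  }, logical(1))
}

# random hotspot draws on a dyadic grid (multiples of 1/1024) so windowed
# sums are exact in double precision regardless of summation order
dyadic_hotspots <- function(n, max16ths = 4 * 1024) {
  sample(0:max16ths, n, replace = TRUE) / 1024
}

# simulate straight from the beta-logit response model (no severity binning)
simulate_beta_obs <- function(n, beta0, beta1, theta, dhw = NULL,
                              u = 0, seed = 1) {
  set.seed(seed)
  if (is.null(dhw)) dhw <- stats::runif(n, 0, 10)
  pi_i <- stats::plogis(beta0 + beta1 * dhw + u)
  y <- stats::rbeta(n, pi_i * theta, (1 - pi_i) * theta)
  y <- pmin(pmax(y, 1e-9), 1 - 1e-9)
  data.frame(dhw = dhw, proportion = y,
             lat = 7 + stats::runif(n), lon = 134 + stats::runif(n))
}
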