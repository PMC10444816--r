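#' Matern spatial correlation
#'
#' Correlation between sites a distance `d` apart under the Matern family
#' with smoothness `nu` (fixed at 1 by default, the usual latent-field
#' choice). The range is parameterised so that the correlation equals 0.1 at
#' distance `range_km` (the common geostatistical reading of "the range at
#' which spatial correlation diminishes"); the scale constant is solved
#' numerically once per smoothness.
#'
#' @param distance_km Non-negative distances in km (vector or matrix).
#' @param range_km Correlation range r in km (> 0).
#' @param nu Smoothness (> 0), default 1.
#' @return Correlations in `[0, 1]`, same shape as `distance_km`;
#'   `matern_correlation(0, r)` is exactly 1.
#' @examples
#' matern_correlation(c(0, 20, 200), range_km = 20)
#' @export
matern_correlation <- function(distance_km, range_km, nu = 1) {
  if (!is.numeric(range_km) || length(range_km) != 1L || is.na(range_km) ||
      range_km <= 0)
    stop("Matern range must be a single positive number (km)")
  if (any(distance_km < 0)) stop("distances must be non-negative")
  x <- .matern_scale(nu) * distance_km / range_km
  out <- distance_km
  out[] <- 1
  pos <- x > 0
  out[pos] <- 2^(1 - nu) / gamma(nu) * x[pos]^nu * besselK(x[pos], nu)
  # besselK underflows to 0 at large argument, which is the right limit
  out[pos & !is.finite(out)] <- 0
  out
}

# scale constant c(nu) with corr(c) = 0.1; cached per smoothness
.matern_cache <- new.env(parent = emptyenv())
.matern_scale <- function(nu) {
  key <- format(nu, digits = 12)
  if (!is.null(.matern_cache[[key]])) return(.matern_cache[[key]])
  f <- function(c) 2^(1 - nu) / gamma(nu) * c^nu * besselK(c, nu) - 0.1
  c0 <- stats::uniroot(f, c(1e-3, 50), tol = 1e-12)$root
  .matern_cache[[key]] <- c0
  c0
}

#' Great-circle distance matrix in kilometres
#'
#' @param lat,lon Decimal-degree coordinates (equal-length vectors).
#' @return Symmetric matrix of haversine distances in km.
#' @export
distance_matrix_km <- function(lat, lon) {
  geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
}

# Matern covariance among sites with a small diagonal jitter so the Cholesky
# factor exists even for near-coincident sites
matern_covariance <- function(dist_km, sigma, range_km, nu = 1,
                              jitter = 1e-8) {
  sigma^2 * matern_correlation(dist_km, range_km, nu) +
    diag(jitter, nrow(dist_km))
}
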