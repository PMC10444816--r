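#' Spatial beta regression of bleaching severity on heat stress
#'
#' Fits the model
#' \deqn{CB_i ~ Beta(mean = pi_i, precision = theta)}
#' \deqn{logit(pi_i) = beta0 + beta1 DHW_i + u_i}
#' where `u` is a zero-mean latent Gaussian field with Matern correlation
#' (range `r` km, standard deviation `sigma`) across the survey sites,
#' capturing spatially correlated prediction error. The beta variance is
#' `pi (1 - pi) / (1 + theta)`.
#'
#' Inference is maximum-a-posteriori with a Laplace approximation: for given
#' hyperparameters the conditional mode of `(beta, u)` is found by Fisher
#' scoring, and hyperparameters maximise the Laplace-approximate marginal
#' posterior. With `estimate_hyper = FALSE` (the default, used by the rate
#' scan) the Matern hyperparameters stay fixed at their prior medians and
#' only the beta precision `theta` is profiled; with `estimate_hyper = TRUE`
#' `(theta, sigma, r)` are optimised jointly by Nelder-Mead. Priors:
#' `beta ~ N(0, 10^2)`, `theta ~ Gamma(1, 0.01)`,
#' `log sigma ~ N(log sigma0, 1)`, `log r ~ N(log r0, 1)`.
#'
#' Uncertainty summaries and the DIC are computed from Gaussian posterior
#' draws of `(beta, u)` about the mode (conditional on the selected
#' hyperparameters), using the supplied seed.
#'
#' @param obs `data.frame` with columns `dhw`, `proportion` (response in the
#'   open interval (0,1); use [transform_scores()] first), and -- if the
#'   spatial field is enabled -- `lat`, `lon`.
#' @param spatial Enable the latent Matern field (default `TRUE`). The
#'   non-spatial fallback (`u = 0`) is flagged in the result.
#' @param estimate_hyper Optimise `sigma` and `r` as well as `theta`.
#' @param range_km,sigma Prior medians (and fixed values when
#'   `estimate_hyper = FALSE`) for the Matern range and field sd.
#' @param nu Matern smoothness, fixed (default 1).
#' @param nugget Observation-level iid latent noise sd added on the logit
#'   scale (0 disables it, the default); absorbs unstructured residual error.
#' @param beta_sd Prior sd of the regression coefficients.
#' @param n_draws Posterior draws used for intervals and DIC (default 200).
#' @param seed Integer seed for the posterior draws.
#' @return Object of class `spatial_beta_fit`: `beta0`, `beta1`, `theta`,
#'   `matern` (list `range_km`, `sigma`, `nu`), `field` (latent values at
#'   sites), `fitted` (per-observation `pi`), `dic` plus components,
#'   `uncertainty` (95% intervals for `beta0`, `beta1`), `draws`
#'   (coefficient draws), `spatial`, `converged`, `seed`.
#' @export
fit_spatial_beta <- function(obs, spatial = TRUE, estimate_hyper = FALSE,
                             range_km = 20, sigma = 1, nu = 1, nugget = 0,
                             beta_sd = 10, n_draws = 200L, seed = 1L) {
  y <- obs$proportion
  if (is.null(y)) stop("obs must carry a 'proportion' column; transform scores first")
  if (any(!is.finite(y)) || any(y <= 0 | y >= 1))
    stop("responses must lie strictly inside (0, 1); apply transform_scores()")
  dhw <- obs$dhw
  if (is.null(dhw) || any(!is.finite(dhw))) stop("obs must carry finite 'dhw'")
  n <- length(y)
  if (n < 10L) stop("at least 10 observations required")
  X <- cbind(1, dhw)

  if (spatial) {
    if (is.null(obs$lat) || is.null(obs$lon))
      stop("spatial fit requires lat/lon columns")
    loc <- paste(signif(obs$lat, 10), signif(obs$lon, 10))
    site <- match(loc, unique(loc))
    ns <- max(site)
    if (ns < 2L) stop("spatial field needs at least 2 distinct locations")
    first <- match(seq_len(ns), site)
    D <- distance_matrix_km(obs$lat[first], obs$lon[first])
    M <- Matrix_incidence(site, ns)
  } else {
    ns <- 0L
    D <- NULL
    M <- NULL
  }

  ystar <- stats::qlogis(y)
  logy <- log(y)
  log1my <- log1p(-y)

  # latent-prior precision for given Matern hyperparameters, cached so the
  # theta profile does not rebuild the (fixed) spatial factor each step
  prior_cache <- new.env(parent = emptyenv())
  latent_prior <- function(lsigma, lrange) {
    key <- paste(lsigma, lrange)
    got <- prior_cache[[key]]
    if (!is.null(got)) return(got)
    S <- matern_covariance(D, exp(lsigma), exp(lrange), nu)
    if (nugget > 0) S <- S + diag(nugget^2, ns)
    cS <- chol(S)
    got <- list(Q = chol2inv(cS),
                half_ldet = sum(log(diag(cS))) + ns / 2 * log(2 * pi))
    prior_cache[[key]] <- got
    got
  }

  # conditional log-posterior of z = (beta, u) given hyperparameters, its
  # mode by Fisher scoring, and the Laplace-approximate log marginal
  inner_fit <- function(ltheta, lsigma, lrange, z0 = NULL) {
    theta <- exp(ltheta)
    d <- 2L + ns
    P <- diag(c(rep(1 / beta_sd^2, 2), rep(0, ns)))
    half_ldet_prior <- 0
    if (ns > 0L) {
      lp <- latent_prior(lsigma, lrange)
      P[3:d, 3:d] <- lp$Q
      half_ldet_prior <- lp$half_ldet
    }
    z <- if (is.null(z0) || length(z0) != d) numeric(d) else z0
    eta_of <- function(z) {
      e <- drop(X %*% z[1:2])
      if (ns > 0L) e <- e + z[site + 2L]
      e
    }
    obj <- function(z) {
      eta <- eta_of(z)
      mu <- stats::plogis(eta)
      a <- mu * theta
      b <- (1 - mu) * theta
      ll <- sum(lgamma(theta) - lgamma(a) - lgamma(b) +
                  (a - 1) * logy + (b - 1) * log1my)
      ll - 0.5 * drop(crossprod(z, P %*% z)) - half_ldet_prior -
        log(beta_sd^2 * 2 * pi)  # beta-prior normaliser (2 coefficients)
    }
    # score and Fisher information of the joint log-posterior at z,
    # assembled blockwise over A = [X M]
    score_fisher <- function(z) {
      eta <- eta_of(z)
      mu <- stats::plogis(eta)
      w0 <- mu * (1 - mu)
      mustar <- digamma(mu * theta) - digamma((1 - mu) * theta)
      g_eta <- theta * (ystar - mustar) * w0
      w <- theta^2 * (trigamma(mu * theta) + trigamma((1 - mu) * theta)) * w0^2
      grad <- c(drop(crossprod(X, g_eta)),
                if (ns > 0L) rowsum_by(g_eta, site, ns)) - drop(P %*% z)
      H <- P
      H[1:2, 1:2] <- H[1:2, 1:2] + crossprod(X, X * w)
      if (ns > 0L) {
        XtWM <- crossprod(X, M * w)
        H[1:2, 3:d] <- H[1:2, 3:d] + XtWM
        H[3:d, 1:2] <- H[3:d, 1:2] + t(XtWM)
        H[3:d, 3:d] <- H[3:d, 3:d] + diag(rowsum_by(w, site, ns), ns)
      }
      list(grad = grad, H = H)
    }

    f <- obj(z)
    conv <- FALSE
    H <- NULL
    cH <- NULL
    for (it in 1:40) {
      sf <- score_fisher(z)
      grad <- sf$grad
      H <- sf$H
      cH <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(cH)) break
      step <- backsolve(cH, backsolve(cH, grad, transpose = TRUE))
      s <- 1
      repeat {
        z_new <- z + s * step
        f_new <- obj(z_new)
        if (is.finite(f_new) && f_new >= f - 1e-12) break
        s <- s / 2
        if (s < 1e-8) break
      }
      moved <- abs(f_new - f)
      z <- z_new
      f <- f_new
      if (moved < 1e-7 && max(abs(step)) * s < 1e-5) { conv <- TRUE; break }
    }
    if (is.null(cH)) return(list(ok = FALSE))
    if (conv) {  # curvature at the final iterate, for the Laplace terms
      H <- score_fisher(z)$H
      cH2 <- tryCatch(chol(H), error = function(e) NULL)
      if (!is.null(cH2)) cH <- cH2
    }
    lmarg <- f + d / 2 * log(2 * pi) - sum(log(diag(cH)))
    list(ok = TRUE, z = z, f = f, H = H, cH = cH, lmarg = lmarg,
         converged = conv, theta = theta)
  }

  lprior_hyper <- function(ltheta, lsigma, lrange) {
    lp <- stats::dgamma(exp(ltheta), shape = 1, rate = 0.01, log = TRUE) + ltheta
    if (ns > 0L) {
      lp <- lp + stats::dnorm(lsigma, log(sigma), 1, log = TRUE) +
        stats::dnorm(lrange, log(range_km), 1, log = TRUE)
    }
    lp
  }

  ls0 <- log(sigma)
  lr0 <- log(range_km)
  warm <- NULL
  if (estimate_hyper && ns > 0L) {
    neg <- function(p) {
      ft <- inner_fit(p[1], p[2], p[3], warm)
      if (!ft$ok) return(1e10)
      warm <<- ft$z
      -(ft$lmarg + lprior_hyper(p[1], p[2], p[3]))
    }
    op <- stats::optim(c(log(10), ls0, lr0), neg, method = "Nelder-Mead",
                       control = list(maxit = 300, reltol = 1e-7))
    ltheta_hat <- op$par[1]; ls0 <- op$par[2]; lr0 <- op$par[3]
  } else {
    neg1 <- function(lt) {
      ft <- inner_fit(lt, ls0, lr0, warm)
      if (!ft$ok) return(1e10)
      warm <<- ft$z
      -(ft$lmarg + lprior_hyper(lt, ls0, lr0))
    }
    ltheta_hat <- stats::optimize(neg1, c(log(0.3), log(2000)), tol = 1e-3)$minimum
  }

  final <- inner_fit(ltheta_hat, ls0, lr0, warm)
  if (!final$ok || !final$converged)
    stop(sprintf(paste0("spatial beta fit did not converge ",
                        "(theta=%.3g, sigma=%.3g, range=%.3g km); ",
                        "consider estimate_hyper=FALSE or a non-spatial fit"),
                 exp(ltheta_hat), exp(ls0), exp(lr0)))

  z_hat <- final$z
  d <- length(z_hat)
  theta_hat <- final$theta
  eta_hat <- drop(X %*% z_hat[1:2]) + if (ns > 0L) z_hat[site + 2L] else 0

  # Gaussian posterior draws about the mode, conditional on hyperparameters
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(d * n_draws), d, n_draws)
  draws <- z_hat + backsolve(final$cH, Z)
  eta_draws <- X %*% draws[1:2, , drop = FALSE] +
    if (ns > 0L) draws[site + 2L, , drop = FALSE] else 0

  dev_of_eta <- function(eta) {
    mu <- stats::plogis(eta)
    a <- mu * theta_hat
    b <- (1 - mu) * theta_hat
    -2 * sum(lgamma(theta_hat) - lgamma(a) - lgamma(b) +
               (a - 1) * logy + (b - 1) * log1my)
  }
  dev_draws <- apply(eta_draws, 2, dev_of_eta)
  dbar <- mean(dev_draws)
  dhat <- dev_of_eta(rowMeans(eta_draws))
  p_d <- dbar - dhat
  dic <- dbar + p_d

  ci <- t(apply(draws[1:2, , drop = FALSE], 1, stats::quantile,
                probs = c(0.025, 0.975)))
  rownames(ci) <- c("beta0", "beta1")

  structure(list(
    beta0 = z_hat[1], beta1 = z_hat[2], theta = theta_hat,
    matern = list(range_km = exp(lr0), sigma = exp(ls0), nu = nu,
                  estimated = isTRUE(estimate_hyper)),
    field = if (ns > 0L) z_hat[-(1:2)] else numeric(0),
    sites = if (ns > 0L) data.frame(lat = obs$lat[first], lon = obs$lon[first])
            else NULL,
    fitted = stats::plogis(eta_hat),
    dic = dic, dic_components = list(dbar = dbar, dhat = dhat, p_d = p_d),
    deviance_draws = dev_draws,
    uncertainty = ci,
    draws = draws[1:2, , drop = FALSE],
    spatial = ns > 0L, nugget = nugget,
    converged = final$converged, log_posterior = final$f,
    n = n, seed = as.integer(seed)),
    class = "spatial_beta_fit")
}

# dense incidence matrix mapping sites to observations (n x ns)
Matrix_incidence <- function(site, ns) {
  M <- matrix(0, length(site), ns)
  M[cbind(seq_along(site), site)] <- 1
  M
}

rowsum_by <- function(x, idx, ns) {
  out <- numeric(ns)
  rs <- rowsum(x, idx, reorder = FALSE)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' @export
print.spatial_beta_fit <- function(x, ...) {
  cat(sprintf("<spatial_beta_fit> n = %d, %s\n", x$n,
              if (x$spatial) sprintf("Matern field (r = %.1f km, sigma = %.2f)",
                                     x$matern$range_km, x$matern$sigma)
              else "non-spatial (u = 0)"))
  cat(sprintf("  beta0 = %.3f [%.3f, %.3f]\n", x$beta0,
              x$uncertainty["beta0", 1], x$uncertainty["beta0", 2]))
  cat(sprintf("  beta1 = %.3f [%.3f, %.3f]  (per C-week DHW)\n", x$beta1,
              x$uncertainty["beta1", 1], x$uncertainty["beta1", 2]))
  cat(sprintf("  theta = %.2f,  DIC = %.2f (pD = %.2f)\n",
              x$theta, x$dic, x$dic_components$p_d))
  invisible(x)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior mean)`, recomputed from
#' the fit's stored posterior deviance draws; lower is more parsimonious.
#'
#' @param fit A `spatial_beta_fit`.
#' @return Scalar DIC.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "spatial_beta_fit"))
  dbar <- mean(fit$deviance_draws)
  2 * dbar - fit$dic_components$dhat
}

#' Predicted bleaching probability over a grid of DHW values
#'
#' Posterior mean and 95% interval of `pi` at the latent field's zero level.
#'
#' @param object A `spatial_beta_fit`.
#' @param dhw Numeric vector of DHW values (degC-weeks).
#' @param ... Unused.
#' @return `data.frame` with `dhw`, `mean`, `lwr`, `upr`.
#' @export
predict.spatial_beta_fit <- function(object, dhw, ...) {
  eta <- cbind(1, dhw) %*% object$draws
  pi_draws <- stats::plogis(eta)
  q <- t(apply(pi_draws, 1, stats::quantile, probs = c(0.025, 0.975)))
  data.frame(dhw = dhw, mean = rowMeans(pi_draws), lwr = q[, 1], upr = q[, 2])
}

#' Write a fit summary to JSON
#'
#' @param fit A `spatial_beta_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    beta0 = fit$beta0, beta1 = fit$beta1, theta = fit$theta,
    matern = fit$matern[c("range_km", "sigma", "nu")],
    dic = fit$dic, p_d = fit$dic_components$p_d,
    ci = as.data.frame(fit$uncertainty),
    spatial = fit$spatial, converged = fit$converged,
    n = fit$n, seed = fit$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
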