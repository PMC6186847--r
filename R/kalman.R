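#' Forward Kalman filter for the rotating complex state-space model
#'
#' The narrow-bandpassed analytic signal is modelled as a complex
#' linear-Gaussian state space: the hidden denoised analytic signal advances
#' by one rotation step per sample, `s_{t+1} = e^{i omega0} s_t + eta_t` with
#' `eta_t ~ CN(0, sigma)`, and is observed through additive complex Gaussian
#' measurement noise, `x_t = s_t + W_t`, `W_t ~ CN(0, alpha)`. Written as a
#' two-dimensional real system the transition matrix is the rotation by
#' `omega0` and all covariances stay proportional to the identity, so the
#' filter reduces to scalar variance updates:
#' \deqn{p' = p_t + \sigma, \quad K_t = p'/(p' + \alpha), \quad
#'       p_{t+1} = p'\alpha/(p' + \alpha),}
#' with the mean updated by the innovation against the next observation.
#' The gain K_t in \[0, 1\] weighs the measurement against the model
#' prediction: small alpha (reliable measurements) pushes K toward 1.
#'
#' The filter is initialised from a data-anchored diffuse prior: `mu1` defaults
#' to the first observation and `p1` to `10 * (alpha + sigma)`; the prior is
#' assimilated with the first observation before the recursion starts.
#'
#' @param obs Complex vector of analytic-signal observations (or a two-column
#'   real matrix of real/imaginary parts).
#' @param omega0 Centre angular frequency in rad/sample (`2*pi*fc/fs`).
#' @param sigma Process-noise variance per real component, >= 0.
#' @param alpha Measurement-noise variance per real component, >= 0. `sigma`,
#'   `alpha` and `p1` must not all be zero.
#' @param mu1 Optional initial state mean (complex scalar or length-2 real).
#' @param p1 Optional initial per-component state variance, > 0.
#' @return A `kalman_filter` object: list with complex `filtered_means`,
#'   `filtered_vars` `p_t`, `gains` `K_t` (all of the observation length) and
#'   the parameters.
#' @seealso [backward_pass()], [smooth_phase()]
#' @export
forward_pass <- function(obs, omega0, sigma, alpha, mu1 = NULL, p1 = NULL) {
  obs <- as_complex_obs(obs)
  n <- length(obs)
  stopifnot(n >= 1, is.finite(omega0))
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (is.null(p1)) p1 <- if (alpha + sigma > 0) 10 * (alpha + sigma) else 1
  if (alpha == 0 && sigma == 0 && p1 <= 0) {
    stop("degenerate model: sigma, alpha and p1 are all zero", call. = FALSE)
  }
  if (p1 <= 0) stop("`p1` must be > 0", call. = FALSE)
  if (is.null(mu1)) mu1 <- obs[1L]
  mu1 <- if (is.complex(mu1)) mu1 else complex(real = mu1[1L], imaginary = mu1[2L])
  rot <- complex(argument = omega0) # e^{i omega0}; the 2-D rotation by omega0

  mu <- complex(n)
  p <- numeric(n)
  K <- numeric(n)
  if (alpha == 0) {
    # exact-measurement limit: the posterior collapses onto each observation
    mu <- obs
    K <- rep(1, n)
    # p stays 0
  } else {
    # assimilate the first observation into the prior
    K[1L] <- p1 / (p1 + alpha)
    mu[1L] <- mu1 + K[1L] * (obs[1L] - mu1)
    p[1L] <- p1 * alpha / (p1 + alpha)
    for (t in seq_len(n - 1L)) {
      pp <- p[t] + sigma
      pred <- rot * mu[t]
      K[t + 1L] <- pp / (pp + alpha)
      mu[t + 1L] <- pred + K[t + 1L] * (obs[t + 1L] - pred)
      p[t + 1L] <- pp * alpha / (pp + alpha)
    }
  }
  structure(
    list(filtered_means = mu, filtered_vars = p, gains = K,
         omega0 = omega0, sigma = sigma, alpha = alpha,
         mu1 = mu1, p1 = p1, obs = obs),
    class = "kalman_filter"
  )
}

#' Backward (smoothing) pass of the Kalman smoother
#'
#' Runs the Rauch-Tung-Striebel backward recursion over a [forward_pass()]
#' result, conditioning every state on the full record. In the
#' scalar-covariance form the smoother gain is `p_t/(p_t + sigma)` times the
#' inverse rotation, giving
#' \deqn{\bar\mu_t = \mu_t + \frac{p_t}{p_t+\sigma}(B^T \bar\mu_{t+1} - \mu_t),
#'       \quad
#'       \bar p_t = p_t + \frac{p_t^2(\bar p_{t+1} - p_t - \sigma)}{(p_t+\sigma)^2}.}
#' The last smoothed mean and variance equal the last filtered ones.
#'
#' @param fr A `kalman_filter` object from [forward_pass()].
#' @return A `kalman_smoother` object: list with complex `smoothed_means`,
#'   `smoothed_vars`, plus the filtered quantities and parameters.
#' @export
backward_pass <- function(fr) {
  if (!inherits(fr, "kalman_filter")) {
    stop("`fr` must be a `kalman_filter` from forward_pass()", call. = FALSE)
  }
  mu <- fr$filtered_means
  p <- fr$filtered_vars
  n <- length(mu)
  rot_back <- complex(argument = -fr$omega0) # B^T = rotation by -omega0
  sm <- complex(n)
  sp <- numeric(n)
  sm[n] <- mu[n]
  sp[n] <- p[n]
  if (n >= 2) {
    for (t in seq.int(n - 1L, 1L)) {
      denom <- p[t] + fr$sigma
      g <- if (denom > 0) p[t] / denom else 0
      sm[t] <- mu[t] + g * (rot_back * sm[t + 1L] - mu[t])
      sp[t] <- p[t] + g^2 * (sp[t + 1L] - p[t] - fr$sigma)
    }
  }
  structure(
    c(list(smoothed_means = sm, smoothed_vars = sp), unclass(fr)),
    class = "kalman_smoother"
  )
}

#' Estimate the process-noise variance from the differenced analytic signal
#'
#' Under the rotating state-space model the one-step difference
#' `x_{t+1} - e^{i omega0} x_t` equals the process noise plus a combination of
#' two measurement-noise draws, so its per-component variance is
#' `epsilon = sigma + 2*alpha`. The admissible range for sigma is therefore
#' `[max(epsilon - 2*alpha, 0), epsilon]`, with `epsilon` the upper bound
#' (alpha unknown or zero) and `epsilon - 2*alpha` the moment point estimate.
#'
#' The working value `sigma_point` is `beta * epsilon`: `beta` is the single
#' smoothing knob, with `beta = 0` removing all phase variation (sigma = 0
#' forces the smoothed instantaneous frequency to a constant) and large
#' `beta` (possibly far above 1) trusting the measurements. Note that after
#' narrow band-pass filtering the measurement noise is strongly
#' autocorrelated, so `epsilon` reflects the local increment variance rather
#' than `sigma + 2*alpha`; useful `beta` values can therefore exceed 1.
#'
#' @param obs Complex analytic-signal vector (length >= 3), typically the
#'   ensemble mean from [ensemble_filter()].
#' @param omega0 Centre angular frequency, rad/sample.
#' @param alpha Measurement-noise per-component variance used for the range
#'   and the moment estimate. Default 0.
#' @param beta Nonnegative smoothing factor. Default 0.5.
#' @return A `sigma_estimate` object: list with `epsilon`, `sigma_range`,
#'   `sigma_hat` (moment estimate `max(epsilon - 2*alpha, 0)`), `sigma_point`,
#'   `alpha`, `beta`.
#' @export
estimate_sigma <- function(obs, omega0, alpha = 0, beta = 0.5) {
  obs <- as_complex_obs(obs)
  if (length(obs) < 3) stop("`obs` must have length >= 3", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  d <- obs[-1L] - complex(argument = omega0) * obs[-length(obs)]
  epsilon <- (stats::var(Re(d)) + stats::var(Im(d))) / 2
  if (epsilon == 0) {
    warning("constant observation sequence: epsilon = 0, sigma range [0, 0]")
  }
  sigma_hat <- max(epsilon - 2 * alpha, 0)
  sigma_point <- beta * epsilon
  structure(
    list(epsilon = epsilon,
         sigma_range = c(sigma_hat, epsilon),
         sigma_hat = sigma_hat,
         sigma_point = sigma_point,
         alpha = alpha, beta = beta),
    class = "sigma_estimate"
  )
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat(sprintf(
    "<sigma_estimate> epsilon = %.4g, range = [%.4g, %.4g], point (beta = %g) = %.4g\n",
    x$epsilon, x$sigma_range[1L], x$sigma_range[2L], x$beta, x$sigma_point))
  invisible(x)
}

#' @method glance sigma_estimate
#' @export
glance.sigma_estimate <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, sigma_lower = x$sigma_range[1L],
                 sigma_upper = x$sigma_range[2L], sigma_hat = x$sigma_hat,
                 sigma_point = x$sigma_point, alpha = x$alpha, beta = x$beta)
}

#' Estimate the measurement-noise variance from a filter ensemble
#'
#' The measurement-noise variance alpha is taken from the spread of the M
#' analytic signals obtained under infinitesimal filter perturbations: the
#' per-sample cross-member variance of the real and imaginary components,
#' averaged over samples and components. A `"phase"` mode is also provided
#' that uses the cross-member variance of the wrapped instantaneous phases
#' (radians squared) instead; the analytic mode is the default because alpha
#' enters the model in signal units.
#'
#' @param ens A `filter_ensemble` from [ensemble_filter()] with `M >= 2`, or a
#'   complex samples-by-members matrix.
#' @param mode `"analytic"` (default) or `"phase"`.
#' @param exclude_edges Drop edge-transient samples (only when `ens` carries an
#'   `edge_mask`). Default TRUE.
#' @return The estimated per-component variance (a single number).
#' @export
estimate_alpha <- function(ens, mode = c("analytic", "phase"),
                           exclude_edges = TRUE) {
  mode <- match.arg(mode)
  if (inherits(ens, "filter_ensemble")) {
    members <- ens$members
    keep <- if (exclude_edges && !all(ens$edge_mask)) !ens$edge_mask
            else rep(TRUE, nrow(members))
    members <- members[keep, , drop = FALSE]
  } else if (is.matrix(ens)) {
    members <- ens
  } else {
    stop("`ens` must be a filter_ensemble or a complex matrix", call. = FALSE)
  }
  if (ncol(members) < 2) {
    stop("at least 2 ensemble members are required to estimate alpha",
         call. = FALSE)
  }
  if (mode == "analytic") {
    vr <- apply(Re(members), 1L, stats::var)
    vi <- apply(Im(members), 1L, stats::var)
    mean(c(vr, vi)) / 1 # average over samples and both components
  } else {
    ph <- apply(members, 2L, function(z) wrap_phase(Arg(z)))
    mean(apply(ph, 1L, stats::var))
  }
}

#' Riccati fixed point of the filtered variance
#'
#' Steady state of the scalar variance recursion
#' `p <- (p + sigma) * alpha / (p + sigma + alpha)`.
#'
#' @param sigma,alpha Per-component process and measurement noise variances.
#' @return `p* = (-sigma + sqrt(sigma^2 + 4*sigma*alpha)) / 2`.
#' @export
riccati_fixed_point <- function(sigma, alpha) {
  (-sigma + sqrt(sigma^2 + 4 * sigma * alpha)) / 2
}

as_complex_obs <- function(obs) {
  if (is.complex(obs)) return(obs)
  if (is.matrix(obs) && ncol(obs) == 2) {
    return(complex(real = obs[, 1L], imaginary = obs[, 2L]))
  }
  if (is.numeric(obs)) return(complex(real = obs, imaginary = 0))
  stop("observations must be complex or a two-column real matrix",
       call. = FALSE)
}
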