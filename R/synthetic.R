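#' Synthetic signal containers
#'
#' All generators return a tibble of class `phs_signal` with columns `time`
#' (seconds), `value` (the observed, possibly noisy signal) and `clean` (the
#' noiseless signal), plus attributes `fs` (sampling rate, Hz) and
#' `change_points` (1-based sample indices of the genuine phase shifts).
#' `change_points()` and `signal_fs()` read those attributes back.
#'
#' @param x A `phs_signal` tibble.
#' @name phs_signal
NULL

#' @rdname phs_signal
#' @export
change_points <- function(x) {
  cp <- attr(x, "change_points")
  if (is.null(cp)) integer() else cp
}

#' @rdname phs_signal
#' @export
signal_fs <- function(x) attr(x, "fs")

new_phs_signal <- function(time, value, clean, fs, change_points = integer()) {
  out <- tibble::tibble(time = time, value = value, clean = clean)
  attr(out, "fs") <- fs
  attr(out, "change_points") <- as.integer(change_points)
  class(out) <- c("phs_signal", class(out))
  out
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Amplitude-modulated tone with pi phase shifts
#'
#' Generates the piecewise test signal
#' `X(t) = [cos(2 pi f_env t)^2 + epsilon] * cos(2 pi f_carrier t + k(t) pi)`,
#' where `k(t)` counts the shift times already passed: after every time in
#' `shift_times` the carrier phase accumulates a further shift of pi. The
#' squared-cosine envelope periodically dips to its floor `epsilon`,
#' producing exactly the low-envelope episodes in which spurious phase
#' variations arise, while each pi shift is a genuine phase reset to be
#' preserved.
#'
#' @param fs Sampling rate, Hz. Default 500.
#' @param duration Record length, seconds. Default 4.
#' @param f_env Envelope modulation frequency, Hz (envelope dips occur where
#'   `cos(2 pi f_env t) = 0`, i.e. every `1/(2 f_env)` s). Default 0.5.
#' @param f_carrier Carrier frequency, Hz. Default 50.
#' @param epsilon Envelope floor (dimensionless), >= 0. Default 0.05.
#' @param shift_times Times (s) of the genuine pi phase shifts, each strictly
#'   inside (0, duration); duplicates rejected.
#' @param noise_sd Standard deviation of added white Gaussian noise.
#' @param seed Integer seed for the noise draw.
#' @return A [phs_signal] tibble; `change_points()` gives the first sample
#'   index at or after each shift time.
#' @examples
#' s <- simulate_am(shift_times = 2.18, noise_sd = 0.02, seed = 1)
#' change_points(s)
#' @export
simulate_am <- function(fs = 500, duration = 4, f_env = 0.5, f_carrier = 50,
                        epsilon = 0.05, shift_times = numeric(),
                        noise_sd = 0, seed = NULL) {
  stopifnot(fs > 0, duration > 0, epsilon >= 0, noise_sd >= 0)
  if (fs <= 2 * f_carrier) {
    stop("`fs` must exceed twice the carrier frequency", call. = FALSE)
  }
  if (anyDuplicated(shift_times)) {
    stop("duplicate shift times are not allowed", call. = FALSE)
  }
  if (length(shift_times) && any(shift_times <= 0 | shift_times >= duration)) {
    stop("shift times must lie strictly inside (0, duration)", call. = FALSE)
  }
  shift_times <- sort(shift_times)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  envelope <- cos(2 * pi * f_env * t)^2 + epsilon
  offset <- pi * findInterval(t, shift_times) # cumulative pi per passed shift
  clean <- envelope * cos(2 * pi * f_carrier * t + offset)
  noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, 0, noise_sd))
           else numeric(n)
  idx <- vapply(shift_times, function(u) which(t >= u)[1L], integer(1))
  new_phs_signal(t, clean + noise, clean, fs, idx)
}

#' Sinusoid with random phase shifts
#'
#' Generates a unit-amplitude sinusoid at `fc` with `n_shifts` cumulative
#' phase jumps at random, well-separated sample positions. Jump magnitudes are
#' drawn uniformly from `shift_range` (default \[pi/8, 7pi/8\]) with random
#' sign, so repeated shifts do not drift systematically. White Gaussian noise
#' of standard deviation `noise_sd` is added.
#'
#' @param fs Sampling rate, Hz. Default 250.
#' @param duration Record length, seconds. Default 6 (1500 samples).
#' @param fc Sinusoid frequency, Hz. Default 7.4.
#' @param n_shifts Number of genuine phase shifts, >= 0.
#' @param shift_range Magnitude range of the jumps, radians.
#' @param min_gap Minimum separation between shift positions, samples.
#'   Default 25, so the 10-sample scoring tolerance can never make two true
#'   shifts ambiguous.
#' @param t_range Fraction of the record within which shifts are placed
#'   (keeps shifts clear of filter edge transients). Default `c(0.3, 0.7)`.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return A [phs_signal] tibble with the shift sample indices in
#'   `change_points()`.
#' @export
simulate_random_shifts <- function(fs = 250, duration = 6, fc = 7.4,
                                   n_shifts = 0,
                                   shift_range = c(pi / 8, 7 * pi / 8),
                                   min_gap = 25, t_range = c(0.3, 0.7),
                                   noise_sd = 0, seed = NULL) {
  stopifnot(fs > 0, duration > 0, n_shifts >= 0, min_gap >= 1,
            length(shift_range) == 2, shift_range[1] <= shift_range[2])
  n <- round(duration * fs)
  lo <- max(2L, ceiling(t_range[1] * n))
  hi <- min(n - 1L, floor(t_range[2] * n))
  if (n_shifts > 0 && (hi - lo) < (n_shifts - 1) * min_gap) {
    stop("infeasible spacing: too many shifts for the allowed window",
         call. = FALSE)
  }
  with_seed(seed, {
    idx <- integer(0)
    if (n_shifts > 0) {
      # rejection-sample positions until all pairwise gaps are >= min_gap
      for (attempt in 1:1000) {
        cand <- sort(sample(lo:hi, n_shifts))
        if (n_shifts == 1 || all(diff(cand) >= min_gap)) { idx <- cand; break }
      }
      if (length(idx) == 0) {
        stop("could not place shifts with the requested separation",
             call. = FALSE)
      }
    }
    jumps <- if (n_shifts > 0) {
      stats::runif(n_shifts, shift_range[1], shift_range[2]) *
        sample(c(-1, 1), n_shifts, replace = TRUE)
    } else numeric(0)
    t <- (seq_len(n) - 1) / fs
    offset <- numeric(n)
    for (k in seq_along(idx)) {
      offset[idx[k]:n] <- offset[idx[k]:n] + jumps[k]
    }
    clean <- cos(2 * pi * fc * t + offset)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    new_phs_signal(t, clean + noise, clean, fs, idx)
  })
}

#' EEG-like superposition of sinusoids plus noise at a controlled SNR
#'
#' Generates a sum of sinusoidal components and white Gaussian noise scaled so
#' that the realized variance ratio `var(clean)/var(noise)` equals
#' `target_snr` exactly on the generated record. The default component table
#' spreads power over the delta/theta/alpha/beta range with an alpha-band
#' component at 7.6 Hz; component phases are drawn uniformly unless given.
#' The signal contains no genuine phase shifts (`change_points()` is empty).
#'
#' @param components Data frame with columns `freq` (Hz), `amplitude` and
#'   optionally `phase` (radians; `NA` entries are drawn uniformly). Default:
#'   frequencies \{2, 5, 7.6, 12, 20\} Hz with amplitudes
#'   \{1, 0.8, 1, 0.5, 0.3\}.
#' @param fs Sampling rate, Hz. Default 250.
#' @param duration Record length, seconds. Default 40.
#' @param target_snr Desired `var(clean)/var(noise)`, > 0.
#' @param seed Integer seed (component phases and noise).
#' @return A [phs_signal] tibble.
#' @export
simulate_eeg <- function(components = NULL, fs = 250, duration = 40,
                         target_snr = 1, seed = NULL) {
  if (is.null(components)) {
    components <- tibble::tibble(
      freq = c(2, 5, 7.6, 12, 20),
      amplitude = c(1, 0.8, 1, 0.5, 0.3)
    )
  }
  components <- tibble::as_tibble(components)
  if (nrow(components) == 0) {
    stop("`components` must contain at least one sinusoid", call. = FALSE)
  }
  stopifnot(all(c("freq", "amplitude") %in% names(components)),
            target_snr > 0, fs > 0)
  if (any(components$freq >= fs / 2)) {
    stop("component frequencies must lie below fs/2", call. = FALSE)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    phase <- if ("phase" %in% names(components)) components$phase
             else rep(NA_real_, nrow(components))
    phase[is.na(phase)] <- stats::runif(sum(is.na(phase)), 0, 2 * pi)
    clean <- rowSums(mapply(
      function(f, a, ph) a * sin(2 * pi * f * t + ph),
      components$freq, components$amplitude, phase))
    raw <- stats::rnorm(n)
    raw <- raw - mean(raw)
    noise <- raw * sqrt(stats::var(clean) / (target_snr * stats::var(raw)))
    new_phs_signal(t, clean + noise, clean, fs)
  })
}
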