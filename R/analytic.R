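#' Analytic signal via the Hilbert transform
#'
#' Converts a real-valued signal x into its analytic form x + i*H(x), where H
#' is the Hilbert transform, using the standard FFT half-spectrum construction
#' (negative frequencies zeroed, positive frequencies doubled). The real part
#' of the result equals the input; the imaginary part is the Hilbert transform.
#'
#' @param data A data frame with one sample per row (e.g. from
#'   [simulate_am()]), or a numeric vector.
#' @param col Column holding the signal values when `data` is a data frame.
#'   Defaults to `value`.
#' @return For a data-frame input, the input tibble with an added complex
#'   column `analytic`; for a vector input, a complex vector.
#' @examples
#' fs <- 100
#' x <- tibble::tibble(time = (0:499) / fs, value = cos(2 * pi * 5 * time))
#' compute_analytic(x)
#' @export
compute_analytic <- function(data, col = value) {
  if (is.numeric(data)) {
    return(analytic_signal(data))
  }
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ col }})
  dplyr::mutate(tibble::as_tibble(data), analytic = analytic_signal(x))
}

#' @rdname compute_analytic
#' @param x Real-valued numeric vector, length >= 2, all finite.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x)) stop("`x` must be a numeric vector", call. = FALSE)
  if (length(x) < 2) stop("signal must have at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) {
    stop("signal contains non-finite samples at position(s) ",
         paste(utils::head(which(!is.finite(x)), 5L), collapse = ", "),
         call. = FALSE)
  }
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# wrapped phase in [-pi, pi): Arg() returns (-pi, pi], fold +pi down
wrap_phase <- function(theta) {
  theta <- ((theta + pi) %% (2 * pi)) - pi
  theta[theta >= pi] <- theta[theta >= pi] - 2 * pi
  theta
}

#' Unwrap a wrapped phase sequence
#'
#' Adds multiples of 2*pi so that consecutive differences lie in (-pi, pi].
#' A jump of exactly +pi is left uncorrected (the correction threshold is
#' strictly greater than pi), matching the half-open [-pi, pi) convention of
#' the wrapped phase.
#'
#' @param theta Numeric vector of wrapped phase values (radians).
#' @return Numeric vector of the same length with a continuous trajectory.
#' @examples
#' unwrap_phase(c(3.0, -3.1)) # second value becomes -3.1 + 2*pi
#' @export
unwrap_phase <- function(theta) {
  stopifnot(is.numeric(theta))
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  dd <- ((d + pi) %% (2 * pi)) - pi
  # tie rule: a positive jump of exactly pi maps to +pi, not -pi
  dd[dd == -pi & d > 0] <- pi
  theta[1L] + c(0, cumsum(dd))
}

#' Decompose an analytic signal into envelope and phase quantities
#'
#' Computes, per sample: the instantaneous envelope A_t = |x_t + i u_t|, the
#' wrapped instantaneous phase theta(t) = atan2(u, x) in \[-pi, pi), the
#' unwrapped phase p(t), the residual r(t) = p(t) - omega0 * t (the phase
#' after removing the linear trend of the centre frequency; flat for a pure
#' tone, stepped at phase resets), and the instantaneous frequency
#' z(t) = (p_t - p_\{t-1\}) * fs in rad/s. The first instantaneous-frequency
#' value is copied from the second so all columns share one length.
#'
#' @param data A data frame containing a complex `analytic` column (e.g. from
#'   [compute_analytic()]) or a numeric signal column, or a complex/numeric
#'   vector.
#' @param fc Centre frequency of the band of interest, in Hz. Must lie in
#'   (0, fs/2).
#' @param fs Sampling rate in Hz. For data-frame input it is inferred from the
#'   `time` column (or a `fs` attribute) when not given.
#' @param col Signal column used when no `analytic` column is present.
#' @return A tibble with columns `time`, `envelope`, `wrapped_phase`,
#'   `unwrapped_phase`, `residual`, `inst_frequency`, carrying the centre
#'   angular frequency (rad/sample) as attribute `omega0`.
#' @examples
#' fs <- 200
#' x <- tibble::tibble(time = (0:999) / fs, value = cos(2 * pi * 10 * time))
#' d <- decompose_phase(x, fc = 10)
#' @export
decompose_phase <- function(data, fc, fs = NULL, col = value) {
  if (is.data.frame(data)) {
    if (is.null(fs)) fs <- infer_fs(data)
    a <- if ("analytic" %in% names(data)) data$analytic
         else analytic_signal(dplyr::pull(data, {{ col }}))
  } else if (is.complex(data)) {
    a <- data
  } else {
    a <- analytic_signal(data)
  }
  if (is.null(fs) || !is.finite(fs) || fs <= 0) {
    stop("a positive sampling rate `fs` is required", call. = FALSE)
  }
  if (!is.finite(fc) || fc <= 0 || fc >= fs / 2) {
    stop("`fc` must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  n <- length(a)
  omega0 <- 2 * pi * fc / fs # rad/sample
  envelope <- Mod(a)
  wrapped <- wrap_phase(Arg(a))
  unwrapped <- unwrap_phase(wrapped)
  residual <- unwrapped - omega0 * (seq_len(n) - 1)
  zf <- diff(unwrapped) * fs # rad/s
  inst_frequency <- c(zf[1L], zf)
  out <- tibble::tibble(
    time = (seq_len(n) - 1) / fs,
    envelope = envelope,
    wrapped_phase = wrapped,
    unwrapped_phase = unwrapped,
    residual = residual,
    inst_frequency = inst_frequency
  )
  attr(out, "omega0") <- omega0
  attr(out, "fs") <- fs
  out
}

#' Flag samples whose envelope falls below a noise threshold
#'
#' Phase values computed where the instantaneous envelope is close to zero are
#' dominated by noise (the arctangent of two small numbers) and should be
#' treated as unreliable.
#'
#' @param d A decomposition tibble from [decompose_phase()] (any data frame
#'   with an `envelope` column).
#' @param threshold Envelope threshold (signal units), >= 0. The conventional
#'   value for unit-amplitude EEG-like signals is 0.2.
#' @return The input tibble with an added logical column `low_envelope`, true
#'   exactly where `envelope < threshold`.
#' @export
flag_low_envelope <- function(d, threshold = 0.2) {
  stopifnot(is.data.frame(d), "envelope" %in% names(d))
  if (!is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a nonnegative number", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(d), low_envelope = .data$envelope < threshold)
}

# sampling rate from a time column or attribute
infer_fs <- function(data) {
  fs <- attr(data, "fs")
  if (!is.null(fs)) return(fs)
  if ("time" %in% names(data) && nrow(data) >= 2) {
    dt <- diff(data$time[1:2])
    if (is.finite(dt) && dt > 0) return(1 / dt)
  }
  NULL
}

# design the order-`order` zero-phase elliptic band-pass for one centre freq.
# signal::ellip(n, ...) with a two-element band returns an order-2n filter,
# so n = order/2.
design_bandpass <- function(fc, fs, bandwidth, order, stopband_atten,
                            passband_ripple) {
  lo <- fc - bandwidth / 2
  hi <- fc + bandwidth / 2
  if (lo <= 0 || hi >= fs / 2) {
    stop(sprintf("band [%.4g, %.4g] Hz infeasible for fc = %.4g Hz at fs = %g Hz",
                 lo, hi, fc, fs), call. = FALSE)
  }
  if (order %% 2 != 0) stop("`order` must be even for a band-pass design",
                            call. = FALSE)
  fl <- signal::ellip(order / 2, Rp = passband_ripple, Rs = stopband_atten,
                      W = c(lo, hi) / (fs / 2), type = "pass")
  r <- max(Mod(polyroot(rev(fl$a))))
  if (!is.finite(r) || r >= 1) {
    stop(sprintf("elliptic design unstable for fc = %.4g Hz (pole radius %.4g)",
                 fc, r), call. = FALSE)
  }
  fl
}

# zero-phase band-pass of a real signal, returned as analytic samples
bandpass_analytic <- function(x, fs, fc, bandwidth, order, stopband_atten,
                              passband_ripple) {
  fl <- design_bandpass(fc, fs, bandwidth, order, stopband_atten,
                        passband_ripple)
  analytic_signal(signal::filtfilt(fl, x))
}

#' Ensemble of perturbed narrow-band filtered analytic signals
#'
#' Applies a zero-phase (forward-backward) IIR elliptic band-pass filter to the
#' signal `M` times, each time with the centre frequency perturbed by a small
#' relative amount `fc_m = fc * (1 + delta_m)`,
#' `delta_m ~ Uniform(-perturbation_scale, +perturbation_scale)`, and computes
#' the analytic signal of each filtered copy. The ensemble mean is the robust
#' phase-estimation input; the cross-member spread feeds the measurement-noise
#' estimate [estimate_alpha()].
#'
#' Samples within `ceil(3 * fs / bandwidth)` of either end are flagged in
#' `edge_mask` as filter transients (kept in place, not deleted, so all series
#' stay aligned).
#'
#' @param data Data frame with the signal (or a numeric vector).
#' @param fc Centre frequency, Hz.
#' @param fs Sampling rate, Hz (inferred from `time` for data frames).
#' @param bandwidth Total passband width centred on `fc`, Hz. Default 0.5.
#' @param order Band-pass filter order (even). Default 6.
#' @param stopband_atten Stop-band attenuation, dB. Default 50.
#' @param passband_ripple Pass-band ripple, dB. Default 0.01.
#' @param M Ensemble size. Default 100.
#' @param perturbation_scale Relative half-width of the centre-frequency
#'   perturbation. Default 0.01. Zero gives M identical members.
#' @param seed Integer seed for reproducible perturbations.
#' @param col Signal column for data-frame input.
#' @return A `filter_ensemble` object: list with complex `members`
#'   (samples x M matrix), `mean_signal` (complex vector, elementwise member
#'   average), `fcs` (perturbed centre frequencies), `edge_mask`, `fs`, `time`
#'   and the design parameters in `spec`.
#' @export
ensemble_filter <- function(data, fc, fs = NULL, bandwidth = 0.5, order = 6,
                            stopband_atten = 50, passband_ripple = 0.01,
                            M = 100, perturbation_scale = 0.01, seed = NULL,
                            col = value) {
  if (is.data.frame(data)) {
    if (is.null(fs)) fs <- infer_fs(data)
    x <- dplyr::pull(data, {{ col }})
  } else {
    x <- data
  }
  if (is.null(fs)) stop("a sampling rate `fs` is required", call. = FALSE)
  stopifnot(M >= 1, perturbation_scale >= 0, bandwidth > 0)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  delta <- stats::runif(M, -perturbation_scale, perturbation_scale)
  fcs <- fc * (1 + delta)
  members <- vapply(
    fcs,
    function(f) bandpass_analytic(x, fs, f, bandwidth, order, stopband_atten,
                                  passband_ripple),
    complex(length(x))
  )
  members <- matrix(members, nrow = length(x), ncol = M)
  mean_signal <- rowMeans(members)
  w <- min(ceiling(3 * fs / bandwidth), length(x))
  edge_mask <- rep(FALSE, length(x))
  edge_mask[seq_len(w)] <- TRUE
  edge_mask[seq.int(max(length(x) - w + 1L, 1L), length(x))] <- TRUE
  structure(
    list(
      members = members,
      mean_signal = mean_signal,
      fcs = fcs,
      edge_mask = edge_mask,
      fs = fs,
      time = (seq_along(x) - 1) / fs,
      spec = list(fc = fc, bandwidth = bandwidth, order = order,
                  stopband_atten = stopband_atten,
                  passband_ripple = passband_ripple, M = M,
                  perturbation_scale = perturbation_scale, seed = seed)
    ),
    class = "filter_ensemble"
  )
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.filter_ensemble <- function(x, ...) {
  cat(sprintf(
    "<filter_ensemble> %d members, %d samples, fc = %g Hz (+/- %g%%), bandwidth = %g Hz\n",
    ncol(x$members), nrow(x$members), x$spec$fc,
    100 * x$spec$perturbation_scale, x$spec$bandwidth))
  invisible(x)
}

#' @method tidy filter_ensemble
#' @export
tidy.filter_ensemble <- function(x, ...) {
  tibble::tibble(
    member = rep(seq_len(ncol(x$members)), each = nrow(x$members)),
    fc = rep(x$fcs, each = nrow(x$members)),
    time = rep(x$time, ncol(x$members)),
    real = c(Re(x$members)),
    imag = c(Im(x$members))
  )
}
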