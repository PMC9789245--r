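#' Charge-balanced biphasic stimulus waveform
#'
#' Builds a cathodic-phase-first, charge-balanced biphasic current pulse on
#' a uniform time grid: \code{-amplitude} during the first (cathodic)
#' phase, zero during the inter-phase gap, \code{+amplitude} during the
#' anodic phase, zero elsewhere. The default timing follows the long
#' stimulus used throughout the package: 200 us phases, 40 us gap, 1 mA,
#' onset 280 us inside a 1 ms window sampled at 1 MHz.
#'
#' @param phase_duration duration of each phase in seconds
#' @param phase_gap inter-phase gap in seconds
#' @param amplitude current amplitude in A (> 0)
#' @param dt sample interval in seconds; must divide onset, phase duration
#'   and gap to within rounding
#' @param onset time of the cathodic-phase start in seconds
#' @param window total window length in seconds
#' @return object of class \code{stimulus_waveform} with fields
#'   \code{time}, \code{samples} (A), \code{dt}, \code{onset},
#'   \code{phase_duration}, \code{phase_gap}, \code{amplitude}
#' @export
#' @examples
#' w <- build_biphasic()
#' sum(w$samples) * w$dt   # charge balance
build_biphasic <- function(phase_duration = 200e-6, phase_gap = 40e-6,
                           amplitude = 1e-3, dt = 1e-6, onset = 280e-6,
                           window = 1e-3) {
  stopifnot(phase_duration > 0, phase_gap >= 0, amplitude > 0, dt > 0,
            onset >= 0, window > 0)
  divides <- function(x) abs(x / dt - round(x / dt)) < 1e-9
  if (!all(vapply(c(phase_duration, phase_gap, onset, window), divides,
                  logical(1L))))
    stop("dt must divide onset, phase_duration, phase_gap and window")
  if (onset + 2 * phase_duration + phase_gap > window + 1e-15)
    stop("stimulus does not fit in the window")
  n <- round(window / dt)
  time <- (seq_len(n) - 1L) * dt
  i0 <- round(onset / dt)
  np <- round(phase_duration / dt)
  ng <- round(phase_gap / dt)
  samples <- numeric(n)
  samples[(i0 + 1L):(i0 + np)] <- -amplitude
  samples[(i0 + np + ng + 1L):(i0 + 2L * np + ng)] <- amplitude
  structure(list(time = time, samples = samples, dt = dt, onset = onset,
                 phase_duration = phase_duration, phase_gap = phase_gap,
                 amplitude = amplitude, window = window),
            class = "stimulus_waveform")
}

#' @exportS3Method base::print
print.stimulus_waveform <- function(x, ...) {
  cat(sprintf(paste0("<stimulus_waveform: %g uA, phases %g us, gap %g us,",
                     " onset %g us, window %g ms @ dt %g us>\n"),
              x$amplitude * 1e6, x$phase_duration * 1e6, x$phase_gap * 1e6,
              x$onset * 1e6, x$window * 1e3, x$dt * 1e6))
  invisible(x)
}

#' One-sided DFT of a stimulus waveform
#'
#' Transforms the waveform to bins at integer multiples of
#' \code{df = 1/window} up to \code{f_max}, storing one-sided magnitude and
#' phase such that [inverse_dft()] reconstructs the signal. DC and (when
#' present) Nyquist bins carry weight 1, all others weight 2; the weight is
#' folded into the stored magnitude so that synthesis is a plain cosine sum.
#'
#' @param w a [build_biphasic()] waveform (or compatible list)
#' @param df frequency resolution in Hz; must equal \code{1/window}
#' @param f_max maximum retained frequency in Hz; sampling rate must be at
#'   least \code{2 * f_max}
#' @return object of class \code{stimulus_spectrum}: data frame-like list
#'   with \code{f} (Hz), \code{magnitude} (A, synthesis weight included),
#'   \code{phase} (rad), plus \code{df}, \code{f_max}
#' @export
forward_dft <- function(w, df = 1e3, f_max = 5e5) {
  stopifnot(inherits(w, "stimulus_waveform") || is.list(w))
  n <- length(w$samples)
  window <- n * w$dt
  if (abs(df * window - 1) > 1e-9)
    stop("df must equal 1/window (window = ", window, " s)")
  fs <- 1 / w$dt
  if (fs < 2 * f_max - 1e-9) stop("sampling rate below 2*f_max")
  X <- stats::fft(w$samples) / n
  kmax <- min(floor(f_max / df), floor(n / 2))
  k <- 0:kmax
  weight <- ifelse(k == 0L | (n %% 2L == 0L & k == n %/% 2L), 1, 2)
  coef <- X[k + 1L]
  structure(list(f = k * df, magnitude = weight * Mod(coef),
                 phase = Arg(coef), df = df, f_max = kmax * df,
                 window = window),
            class = "stimulus_spectrum")
}

#' @exportS3Method base::print
print.stimulus_spectrum <- function(x, ...) {
  cat(sprintf("<stimulus_spectrum: %d bins, df %g Hz, f_max %g kHz>\n",
              length(x$f), x$df, x$f_max / 1e3))
  invisible(x)
}

#' Inverse DFT synthesis at arbitrary times
#'
#' Synthesizes a real time series from one complex value per spectrum bin
#' (for example solver outputs at a probe point). The bin values are
#' interpreted on the same one-sided convention as [forward_dft()]: the
#' series is \eqn{\sum_i |c_i| \cos(2\pi f_i t + \arg c_i)} with the
#' one-sided weight already folded into \eqn{|c_i|}.
#'
#' @param values complex vector, one value per bin (weighted one-sided
#'   coefficients)
#' @param f bin frequencies in Hz
#' @param times times in seconds at which to synthesize
#' @return real numeric vector, one value per time
#' @export
inverse_dft <- function(values, f, times) {
  stopifnot(length(values) == length(f), is.numeric(times))
  if (length(values) == 0L) return(numeric(length(times)))
  # bins x times matrix stays small; one cosine sum per time point
  ph <- outer(f, times) * (2 * pi)
  colSums(Mod(values) * cos(ph + Arg(values)))
}

#' Spectrum bin values of the stimulus itself
#'
#' Convenience accessor returning the weighted complex coefficients
#' \code{magnitude * exp(1i*phase)} of a [forward_dft()] spectrum, the form
#' consumed by [inverse_dft()] and by the frequency sweep.
#'
#' @param spec a \code{stimulus_spectrum}
#' @return complex vector, one per bin
#' @export
spectrum_coefficients <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spectrum"))
  complex(modulus = spec$magnitude, argument = spec$phase)
}

#' Export a waveform or spectrum as tabular text
#'
#' @param x a \code{stimulus_waveform} or \code{stimulus_spectrum}
#' @param path file path; tab-separated with a header line
#' @return \code{path}, invisibly
#' @export
write_stimulus <- function(x, path) {
  if (inherits(x, "stimulus_waveform")) {
    d <- data.frame(time_s = x$time, current_A = x$samples)
  } else if (inherits(x, "stimulus_spectrum")) {
    d <- data.frame(f_Hz = x$f, magnitude = x$magnitude, phase_rad = x$phase)
  } else stop("x must be a stimulus_waveform or stimulus_spectrum")
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
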