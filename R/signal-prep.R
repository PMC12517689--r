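#' Regress the global signal out of a run
#'
#' Each region's time series is replaced by its residual after ordinary
#' least-squares regression on an intercept and the global signal (the mean
#' across regions at each time point). Residuals are exactly orthogonal to
#' the global regressor. If the global signal has (numerically) zero
#' variance the rank-deficient regressor is dropped with a warning and only
#' the intercept is removed (each row is centred), so a constant run maps
#' to zero residuals.
#'
#' @param run an [roi_run()].
#' @return an `roi_run` of residuals, same shape and metadata.
#' @export
regress_global_signal <- function(run) {
  stopifnot(inherits(run, "roi_run"))
  v <- run$values
  g <- colMeans(v)
  if (stats::sd(g) < .Machine$double.eps^0.5) {
    warning("global signal has zero variance; removing only the intercept")
    out <- run
    out$values <- v - rowMeans(v)
    return(out)
  }
  X <- cbind(1, g)
  ## one QR solve for all regions at once: residuals of t(v) on X
  beta <- qr.coef(qr(X), t(v))
  res <- t(t(v) - X %*% beta)
  out <- run
  out$values <- res
  out
}

## two-sided squared-magnitude gain of the zero-phase Butterworth band-pass
## plus fast-Fourier notch, evaluated on the DFT frequency grid
bandpass_gain <- function(freqs, low_cut, high_cut, notch, notch_width, order) {
  f <- abs(freqs)
  hp <- ifelse(f == 0, 0, 1 / (1 + (low_cut / pmax(f, .Machine$double.xmin))^(2 * order)))
  lp <- 1 / (1 + (f / high_cut)^(2 * order))
  g <- hp * lp
  if (!is.null(notch) && is.finite(notch)) {
    g[abs(f - notch) <= notch_width] <- 0
  }
  g
}

#' Zero-phase temporal band-pass and notch filtering
#'
#' Applies the squared magnitude response of a Butterworth band-pass
#' (defaults: 0.0025--0.05 Hz, 2nd order) in the frequency domain, together
#' with a fast-Fourier notch that zeroes the bins within `notch_width` of the
#' notch frequency (default 0.03 Hz +/- 0.002 Hz). The frequency-domain
#' realisation is the exact zero-phase equivalent of forward-backward
#' filtering: the gain is real and even, so no phase distortion is introduced
#' and filtering commutes exactly with time reversal. The DC bin is removed
#' (high-pass), so constant offsets vanish.
#'
#' @param run an [roi_run()].
#' @param low_cut,high_cut band edges in Hz; must satisfy
#'   `0 < low_cut < high_cut < 1/(2 tr_seconds)`.
#' @param notch notch centre frequency in Hz, or `NULL` to disable; must lie
#'   strictly inside the passband when given.
#' @param notch_width half-width of the zeroed band in Hz.
#' @param order Butterworth order per band edge.
#' @return a filtered `roi_run`.
#' @export
temporal_filter <- function(run, low_cut = 0.0025, high_cut = 0.05,
                            notch = 0.03, notch_width = 0.002, order = 2) {
  stopifnot(inherits(run, "roi_run"))
  nyq <- 1 / (2 * run$tr_seconds)
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < nyq)) {
    stop_invalid(sprintf(
      "cutoffs must satisfy 0 < low_cut < high_cut < Nyquist (%.4g Hz)", nyq))
  }
  if (!is.null(notch) && !(notch > low_cut && notch < high_cut)) {
    stop_invalid("notch frequency must lie strictly inside the passband")
  }
  n <- ncol(run$values)
  min_len <- 9L
  if (n < min_len) {
    stop_invalid(sprintf(
      "run too short for filtering: %d volumes, need at least %d", n, min_len))
  }
  fs <- 1 / run$tr_seconds
  freqs <- c(0, seq_len(n - 1)) / n * fs
  freqs[freqs > fs / 2] <- freqs[freqs > fs / 2] - fs
  g <- bandpass_gain(freqs, low_cut, high_cut, notch, notch_width, order)
  out <- run
  out$values <- t(apply(run$values, 1L, function(x) {
    Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  }))
  rownames(out$values) <- run$roi_names
  out
}

#' Z-score each region's time series
#'
#' Rows are centred and scaled to unit sample standard deviation (n-1
#' denominator). A zero-variance region is an error naming the region, since
#' its phase would be undefined downstream.
#'
#' @param run an [roi_run()].
#' @return a z-scored `roi_run`.
#' @export
zscore_run <- function(run) {
  stopifnot(inherits(run, "roi_run"))
  sds <- apply(run$values, 1L, stats::sd)
  bad <- which(sds < .Machine$double.eps^0.5)
  if (length(bad)) {
    stop_invalid("zero-variance region(s): ",
                 paste(run$roi_names[bad], collapse = ", "))
  }
  out <- run
  out$values <- (run$values - rowMeans(run$values)) / sds
  out
}

## analytic signal x + i H[x] via the one-sided FFT spectrum
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude via the analytic signal
#'
#' Computes the analytic representation `x + i H[x]` of each (already
#' filtered and z-scored) regional time series through the Hilbert transform,
#' and returns instantaneous amplitude and phase. Phases are wrapped to
#' `[-pi, pi)`. The first and last time point are dropped because the
#' transform of a finite record is least reliable at the edges, so a run of
#' `T` volumes yields `T - 2` phase columns. The retained samples satisfy
#' the reconstruction identity `A(t) cos(phi(t)) = x(t)` to numerical
#' precision.
#'
#' @param run a conditioned [roi_run()].
#' @return a `phase_run` with fields `phases` and `amplitudes`
#'   (regions x `T - 2`), the retained volume indices in `tr_index`, and the
#'   source metadata.
#' @export
analytic_phase <- function(run) {
  stopifnot(inherits(run, "roi_run"))
  n <- ncol(run$values)
  if (n < 3L) stop_invalid("run too short: need at least 3 volumes")
  z <- t(apply(run$values, 1L, analytic_signal))
  keep <- 2:(n - 1L)
  amp <- Mod(z)[, keep, drop = FALSE]
  ph <- Arg(z)[, keep, drop = FALSE]
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi  # convention: half-open [-pi, pi)
  rownames(amp) <- rownames(ph) <- run$roi_names
  new_phase_run(ph, amp, run$roi_names, run$tr_seconds, run$metadata,
                tr_index = keep)
}

#' Standard conditioning pipeline for one run
#'
#' Fixed order: global-signal regression (optional), zero-phase band-pass and
#' notch filtering, per-region z-scoring, then phase extraction with edge
#' trimming.
#'
#' @param run an [roi_run()].
#' @param gsr logical, regress out the global signal first.
#' @param ... passed to [temporal_filter()].
#' @return a `phase_run`.
#' @export
prepare_phases <- function(run, gsr = TRUE, ...) {
  if (gsr) run <- regress_global_signal(run)
  run <- temporal_filter(run, ...)
  run <- zscore_run(run)
  analytic_phase(run)
}
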