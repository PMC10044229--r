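#' Audio segment container
#'
#' A numeric amplitude vector tagged with its sample rate, a start-time
#' offset within the parent recording, and (optionally) a hydrophone
#' calibration. All segment times are half-open `[start, end)` seconds from
#' the start of the recording.
#'
#' @param samples numeric vector of dimensionless amplitudes
#' @param rate sample rate, Hz
#' @param start_time offset of the first sample within the recording, s
#' @param calibration optional [hydrophone_cal()]
#' @return object of class `audio_segment`
#' @export
audio_segment <- function(samples, rate, start_time = 0, calibration = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio_segment needs at least one sample")
  if (!all(is.finite(samples))) stop("audio_segment samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) stop("rate must be > 0")
  structure(samples, rate = rate, start_time = start_time,
            calibration = calibration, class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %d samples @ %g Hz (%.3f s), start %.3f s%s>\n",
              length(x), seg_rate(x), length(x) / seg_rate(x),
              attr(x, "start_time") %||% 0,
              if (is.null(attr(x, "calibration"))) "" else ", calibrated"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seg_rate <- function(segment) {
  r <- attr(segment, "rate")
  if (is.null(r)) stop("segment carries no sample rate")
  r
}

#' Cut a sub-segment by time interval
#'
#' @param segment an [audio_segment()]
#' @param start,end interval in seconds from recording start, half-open
#' @return an [audio_segment()] covering `[start, end)`
#' @export
cut_segment <- function(segment, start, end) {
  if (end <= start) stop("end must exceed start")
  rate <- seg_rate(segment)
  t0 <- attr(segment, "start_time") %||% 0
  i0 <- max(1L, floor((start - t0) * rate) + 1L)
  i1 <- min(length(segment), ceiling((end - t0) * rate))
  if (i1 < i0) stop("interval lies outside the segment")
  audio_segment(unclass(segment)[i0:i1], rate = rate,
                start_time = t0 + (i0 - 1L) / rate,
                calibration = attr(segment, "calibration"))
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * seq_len(n) / (n + 1))
hann_window    <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

get_window <- function(name, n) {
  switch(match.arg(name, c("hamming", "hann", "rectangular")),
         hamming = hamming_window(n),
         hann = hann_window(n),
         rectangular = rep(1, n))
}

# Short-time power matrix (frames x bins). Power is normalized so a
# full-scale unit-amplitude sine reads its mean-square power (0.5)
# independent of fft_size: scale = 2 / sum(w)^2 (one-sided; DC and Nyquist
# bins are not doubled).
stft_power <- function(x, rate, fft_size, overlap, window) {
  n <- length(x)
  if (n < fft_size) stop("segment shorter than one analysis frame")
  hop <- max(1L, as.integer(round(fft_size * (1 - overlap))))
  starts <- seq(1L, n - fft_size + 1L, by = hop)
  w <- get_window(window, fft_size)
  nb <- fft_size %/% 2L + 1L
  p <- matrix(0, nrow = nb, ncol = length(starts))
  # frame blocks cap the mvfft intermediate on long recordings
  block <- 256L
  for (b0 in seq(1L, length(starts), by = block)) {
    jj <- b0:min(length(starts), b0 + block - 1L)
    frames <- matrix(0, nrow = fft_size, ncol = length(jj))
    for (k in seq_along(jj)) {
      s <- starts[jj[k]]
      frames[, k] <- x[s:(s + fft_size - 1L)] * w
    }
    spec <- stats::mvfft(frames)
    p[, jj] <- Mod(spec[seq_len(nb), , drop = FALSE])^2
  }
  p <- p * (2 / sum(w)^2)
  p[1, ] <- p[1, ] / 2
  if (fft_size %% 2L == 0L) p[nb, ] <- p[nb, ] / 2
  list(power = t(p),                        # frames x bins
       freq = (seq_len(nb) - 1L) * rate / fft_size,
       times = (starts - 1L + fft_size / 2) / rate,
       hop = hop, window_energy_scale = sum(w^2) / sum(w)^2 * fft_size)
}

#' Spectrogram of an audio segment
#'
#' Magnitude-squared short-time Fourier transform. Defaults mirror common
#' bioacoustic practice for pinniped repertoires: 1024-point FFT, 75%
#' overlap, Hamming window. Power is scaled so a full-scale unit sine reads
#' its mean-square power (0.5) independent of `fft_size`.
#'
#' @param segment an [audio_segment()]
#' @param fft_size FFT length in points
#' @param overlap fractional frame overlap in `[0, 1)`
#' @param window `"hamming"`, `"hann"` or `"rectangular"`
#' @return object of class `spectrogram`: list with `power` (time x
#'   frequency matrix), `freq` (Hz), `times` (s), `time_step`, `freq_step`
#' @export
spectrogram <- function(segment, fft_size = 1024L, overlap = 0.75,
                        window = "hamming") {
  rate <- seg_rate(segment)
  s <- stft_power(as.numeric(segment), rate, fft_size, overlap, window)
  structure(list(power = s$power, freq = s$freq,
                 times = s$times + (attr(segment, "start_time") %||% 0),
                 time_step = s$hop / rate, freq_step = rate / fft_size,
                 fft_size = fft_size, overlap = overlap, window = window,
                 rate = rate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frames x %d bins, dt=%.4g s, df=%.4g Hz, %s>\n",
              nrow(x$power), ncol(x$power), x$time_step, x$freq_step, x$window))
  invisible(x)
}

#' Average power spectrum of a segment
#'
#' Time-averaged (linear power mean across STFT frames) spectral profile,
#' zeroed outside the analysis band. All spectral call features (Fmax,
#' energy quartiles, fundamental frequency) are measured on this profile.
#'
#' @param segment an [audio_segment()]
#' @param band `c(lo, hi)` Hz; power outside is zeroed
#' @param fft_size,overlap,window forwarded to [spectrogram()]
#' @return object of class `average_spectrum`: list with `freq`, `power`,
#'   `band`, and `silent` flag (TRUE when in-band power is negligible
#'   relative to total power)
#' @export
average_spectrum <- function(segment, band = c(20, seg_rate(segment) / 2),
                             fft_size = 1024L, overlap = 0.75,
                             window = "hamming") {
  rate <- seg_rate(segment)
  if (band[2] <= band[1]) stop("inverted band")
  if (band[1] < 0 || band[2] > rate / 2 + 1e-9) stop("band outside (0, Nyquist]")
  x <- as.numeric(segment)
  # short segments: shrink the frame rather than refuse
  fft_size <- min(fft_size, 2^floor(log2(length(x))))
  if (fft_size < 16L) stop("segment too short for spectral analysis")
  s <- stft_power(x, rate, fft_size, overlap, window)
  p <- colMeans(s$power)
  total <- sum(p)
  in_band <- s$freq >= band[1] & s$freq <= band[2]
  p[!in_band] <- 0
  # window sidelobes leak ~1e-4 of an out-of-band tone into the band;
  # the silence threshold sits well above that
  structure(list(freq = s$freq, power = p, band = band,
                 freq_step = rate / fft_size,
                 silent = total <= 0 || sum(p) < 1e-3 * total),
            class = "average_spectrum")
}

#' Amplitude envelope
#'
#' Full-wave rectification followed by FFT low-pass smoothing, mirroring
#' how pulse structure is read off an oscillogram.
#'
#' @param segment an [audio_segment()]
#' @param smoothing smoothing constant, s; the low-pass cutoff is
#'   `1/smoothing` Hz (default 0.02 s, i.e. 50 Hz)
#' @return numeric envelope, same length as the segment, with attributes
#'   `rate` and `times`
#' @export
envelope <- function(segment, smoothing = 0.02) {
  rate <- seg_rate(segment)
  n <- length(segment)
  if (smoothing >= n / rate) stop("smoothing must be shorter than the segment")
  cutoff <- 1 / smoothing
  env <- fft_lowpass(abs(as.numeric(segment)), rate, cutoff)
  env <- pmax(env, 0)
  structure(env, rate = rate,
            times = (seq_len(n) - 1L) / rate + (attr(segment, "start_time") %||% 0))
}

# zero-phase FFT brick-wall filters (adequate here: offline, whole-segment).
# Inputs are zero-padded to a fast composite length: R's fft is O(n^2) when
# n has a large prime factor, which arbitrary call durations regularly hit.
fft_lowpass <- function(x, rate, cutoff) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * rate / m
  X[abs(f) > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
}

fft_bandpass <- function(x, rate, lo, hi) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  f <- abs(c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * rate / m)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
}

# FFT-domain resampling to an arbitrary new length (band-limited sinc
# interpolation); used by merge_and_resample for anti-aliased conversion.
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nh <- min(n_in, n_out) %/% 2L
  Y[1] <- X[1]
  if (nh >= 1) {
    Y[2:(nh + 1)] <- X[2:(nh + 1)]
    Y[(n_out - nh + 1):n_out] <- X[(n_in - nh + 1):n_in]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Merge recordings and resample
#'
#' Concatenates an ordered list of same-rate recordings into one segment
#' and converts the rate with an anti-aliased (band-limited) method —
#' the standard preparation of day-long files for spectrogram screening.
#'
#' @param files character vector of WAV paths, or list of [audio_segment()]s
#' @param target_rate output rate, Hz
#' @return a single [audio_segment()] at `target_rate`
#' @export
merge_and_resample <- function(files, target_rate = 11025) {
  segs <- lapply(files, function(f) if (is.character(f)) read_wav(f) else f)
  rates <- vapply(segs, seg_rate, 0)
  if (length(unique(rates)) != 1L) stop("all inputs must share one sample rate")
  src_rate <- rates[1]
  x <- unlist(lapply(segs, as.numeric), use.names = FALSE)
  if (target_rate == src_rate) {
    return(audio_segment(x, rate = src_rate,
                         calibration = attr(segs[[1]], "calibration")))
  }
  if (target_rate > src_rate) {
    warning("upsampling from ", src_rate, " to ", target_rate, " Hz")
  }
  n_out <- as.integer(round(length(x) * target_rate / src_rate))
  audio_segment(fft_resample(x, n_out), rate = target_rate,
                calibration = attr(segs[[1]], "calibration"))
}
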