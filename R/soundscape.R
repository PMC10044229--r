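#' Hydrophone calibration metadata
#'
#' @param sensitivity dB re V/uPa (negative for real hydrophones, e.g.
#'   -168.5)
#' @param gain recording-chain gain, dB
#' @param adc_full_scale voltage corresponding to digital full scale, V
#' @return object of class `hydrophone_cal`
#' @export
hydrophone_cal <- function(sensitivity, gain = 0, adc_full_scale = 1) {
  if (!all(is.finite(c(sensitivity, gain, adc_full_scale)))) {
    stop("calibration values must be finite")
  }
  if (sensitivity >= 0) stop("hydrophone sensitivity must be negative (dB re V/uPa)")
  structure(list(sensitivity = sensitivity, gain = gain,
                 adc_full_scale = adc_full_scale),
            class = "hydrophone_cal")
}

#' Convert a recorded segment to absolute pressure
#'
#' Digital counts map to volts through the ADC full-scale voltage, and
#' volts to micropascal through the hydrophone sensitivity and chain gain:
#' `p = v * 10^(-(sensitivity + gain)/20)`.
#'
#' @param segment an [audio_segment()] (dimensionless full-scale fraction)
#' @param cal a [hydrophone_cal()]; defaults to the segment's own
#' @return an [audio_segment()] in uPa (attribute `units = "uPa"`)
#' @export
calibrate <- function(segment, cal = attr(segment, "calibration")) {
  if (is.null(cal)) stop("no calibration available")
  stopifnot(inherits(cal, "hydrophone_cal"))
  p <- as.numeric(segment) * cal$adc_full_scale *
    10^(-(cal$sensitivity + cal$gain) / 20)
  out <- audio_segment(p, rate = seg_rate(segment),
                       start_time = attr(segment, "start_time") %||% 0,
                       calibration = cal)
  attr(out, "units") <- "uPa"
  out
}

#' Long-term spectrogram average
#'
#' Spectrogram frames power-averaged within coarse time-frequency bins —
#' the day-scale visualization that exposes diel patterns of biological
#' (snapping shrimp) and anthropogenic (vessel) noise.
#'
#' @param recording an [audio_segment()] (calibrated for absolute levels)
#' @param time_bin bin width, s
#' @param freq_bin bin width, Hz
#' @return list with `db` (time x frequency matrix, dB), `times`, `freq`
#' @export
ltsa <- function(recording, time_bin = 5, freq_bin = 5) {
  rate <- seg_rate(recording)
  dur <- length(recording) / rate
  if (time_bin > dur) stop("time bin exceeds the recording span")
  if (freq_bin > rate / 2) stop("frequency bin exceeds Nyquist")
  # spectral line spacing must not exceed freq_bin or some LTSA cells
  # would stay empty
  fft_size <- 2^ceiling(log2(rate / freq_bin))
  s <- stft_power(as.numeric(recording), rate, fft_size, overlap = 0,
                  window = "hann")
  t_idx <- pmin(floor(s$times / time_bin) + 1L, ceiling(dur / time_bin))
  f_idx <- floor(s$freq / freq_bin) + 1L
  nt <- max(t_idx)
  nf <- max(f_idx)
  acc <- matrix(0, nt, nf)
  cnt <- matrix(0, nt, nf)
  for (j in seq_along(s$freq)) {
    tp <- tapply(s$power[, j], t_idx, mean)
    acc[as.integer(names(tp)), f_idx[j]] <- acc[as.integer(names(tp)), f_idx[j]] + tp
    cnt[as.integer(names(tp)), f_idx[j]] <- cnt[as.integer(names(tp)), f_idx[j]] + 1
  }
  avg <- acc / pmax(cnt, 1)
  list(db = 10 * log10(pmax(avg, 1e-30)),
       times = (seq_len(nt) - 0.5) * time_bin,
       freq = (seq_len(nf) - 0.5) * freq_bin,
       power = avg)
}

# Welch density estimate per analysis window: matrix windows x freq,
# density in (input units)^2 / Hz, 1/window_s Hz resolution
welch_density_windows <- function(x, rate, window_s = 1, overlap = 0.5) {
  nw <- round(window_s * rate)
  if (length(x) < nw) stop("recording shorter than one analysis window")
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  w <- hann_window(nw)
  scale <- 2 / (rate * sum(w^2))
  nb <- nw %/% 2L + 1L
  d <- matrix(0, nb, length(starts))
  block <- 128L
  for (b0 in seq(1L, length(starts), by = block)) {
    jj <- b0:min(length(starts), b0 + block - 1L)
    frames <- matrix(0, nw, length(jj))
    for (k in seq_along(jj)) frames[, k] <- x[starts[jj[k]]:(starts[jj[k]] + nw - 1L)] * w
    spec <- stats::mvfft(frames)
    d[, jj] <- Mod(spec[seq_len(nb), , drop = FALSE])^2
  }
  d <- d * scale
  d[1, ] <- d[1, ] / 2
  if (nw %% 2L == 0L) d[nb, ] <- d[nb, ] / 2
  list(density = t(d), freq = (seq_len(nb) - 1L) * rate / nw,
       times = (starts - 1L + nw / 2) / rate)
}

#' PSD percentile curves
#'
#' Per-frequency percentiles of windowed power-spectral-density estimates
#' (Hann windows, default 1 s / 50% overlap, 1 Hz bins), in dB re
#' 1 uPa^2/Hz for calibrated input.
#'
#' @param recording an [audio_segment()]
#' @param percentiles percent points of the per-frequency distribution
#' @param window analysis window, s
#' @param overlap fractional window overlap
#' @return list with `freq`, `db` (matrix percentiles x freq), `percentiles`
#' @export
psd_percentiles <- function(recording, percentiles = c(10, 25, 50, 75, 90),
                            window = 1, overlap = 0.5) {
  wd <- welch_density_windows(as.numeric(recording), seg_rate(recording),
                              window, overlap)
  if (nrow(wd$density) < 10L) stop("need at least 10 analysis windows")
  qs <- apply(wd$density, 2, stats::quantile, probs = percentiles / 100,
              names = FALSE)
  qs <- matrix(qs, nrow = length(percentiles),
               dimnames = list(paste0("P", percentiles), NULL))
  list(freq = wd$freq, db = 10 * log10(pmax(qs, 1e-30)),
       percentiles = percentiles, n_windows = nrow(wd$density))
}

#' Octave band edges
#'
#' Base-2 one-octave band around a nominal center: `[fc/sqrt(2), fc*sqrt(2))`.
#'
#' @param fc center frequency, Hz
#' @return `c(lo, hi)` Hz
#' @export
octave_band <- function(fc) c(fc / sqrt(2), fc * sqrt(2))

#' Broadband and octave-band level time series
#'
#' Per time bin, the RMS pressure level integrated over each band (bands
#' are half-open `[lo, hi)` so disjoint covering bands sum exactly to the
#' broadband level). Defaults follow soundscape practice around shallow
#' coastal sites: broadband 20 Hz-5.5 kHz plus octave bands centered at
#' 125, 500 and 2000 Hz.
#'
#' @param recording an [audio_segment()] (calibrated -> dB re 1 uPa)
#' @param bands named list of `c(lo, hi)` bands, Hz
#' @param time_bin averaging bin, s
#' @param window,overlap Welch settings within each bin
#' @return data.frame: `time` plus one dB column per band
#' @export
band_levels <- function(recording,
                        bands = list(BB = c(20, 5500),
                                     OL125 = octave_band(125),
                                     OL500 = octave_band(500),
                                     OL2000 = octave_band(2000)),
                        time_bin = 5, window = 1, overlap = 0.5) {
  rate <- seg_rate(recording)
  for (b in bands) {
    if (b[2] > rate / 2 + 1e-9) stop("band above Nyquist: ", b[1], "-", b[2], " Hz")
  }
  wd <- welch_density_windows(as.numeric(recording), rate, window, overlap)
  df <- wd$freq[2] - wd$freq[1]
  t_idx <- floor(wd$times / time_bin) + 1L
  nt <- max(t_idx)
  out <- data.frame(time = (seq_len(nt) - 0.5) * time_bin)
  for (nm in names(bands)) {
    sel <- wd$freq >= bands[[nm]][1] & wd$freq < bands[[nm]][2]
    msq <- rowSums(wd$density[, sel, drop = FALSE]) * df
    lvl <- tapply(msq, t_idx, mean)
    out[[nm]] <- 10 * log10(pmax(as.numeric(lvl), 1e-30))
  }
  out
}
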