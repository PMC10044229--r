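#' Soundscape mixing specification
#'
#' Components of the synthetic sonic environment around a pupping site:
#' snapping-shrimp crackle (broadband transients, 1.5-5.5 kHz), vessel
#' noise (band noise plus engine tonal lines, 20-200 Hz) and low-frequency
#' flow noise (< 30 Hz). Component gains are RMS levels in dB relative to
#' digital full scale; `-Inf` disables a component.
#'
#' @param shrimp_band,boat_band `c(lo, hi)` Hz
#' @param shrimp_snap_rate mean snap rate, snaps/s
#' @param boat_tonal_lines engine harmonics, Hz
#' @param flow_cutoff low-pass edge of flow noise, Hz
#' @param gains named numeric: `shrimp`, `boat`, `flow` in dBFS (RMS)
#' @param boat_events optional data.frame(start, end) s: intervals with
#'   vessel noise (default: the whole file when the boat gain is finite)
#' @param seed default seed used by [synth_soundscape()]
#' @return object of class `soundscape_mix`
#' @export
soundscape_mix <- function(shrimp_band = c(1500, 5500), shrimp_snap_rate = 60,
                           boat_band = c(20, 200),
                           boat_tonal_lines = c(60, 120, 180),
                           flow_cutoff = 30,
                           gains = c(shrimp = -26, boat = -30, flow = -36),
                           boat_events = NULL, seed = 1L) {
  stopifnot(all(c("shrimp", "boat", "flow") %in% names(gains)))
  if (any(is.na(gains)) || any(gains == Inf)) stop("gains must be finite or -Inf")
  for (b in list(shrimp_band, boat_band)) {
    if (b[1] <= 0 || b[2] <= b[1]) stop("invalid band edges")
  }
  structure(list(shrimp_band = shrimp_band, shrimp_snap_rate = shrimp_snap_rate,
                 boat_band = boat_band, boat_tonal_lines = boat_tonal_lines,
                 flow_cutoff = flow_cutoff, gains = gains,
                 boat_events = boat_events, seed = seed),
            class = "soundscape_mix")
}

set_rms <- function(x, rms) {
  r <- sqrt(mean(x^2))
  if (r <= 0) x else x * rms / r
}

#' Synthesize a mixed soundscape with inserted calls
#'
#' Additively mixes the background components of a [soundscape_mix()] with
#' call waveforms placed at given times, and returns the waveform plus an
#' annotation track (one row per inserted call and per noise-event
#' interval).
#'
#' @param mix a [soundscape_mix()]
#' @param calls list of `list(time = s, spec = synthesis_spec)` placements
#'   (or NULL)
#' @param duration file length, s
#' @param seed integer seed (defaults to `mix$seed`)
#' @param rate sample rate, Hz
#' @param snr_db per-call gain applied on top of the spec amplitude, dB
#' @return list with `wave` ([audio_segment()]), `labels` (data.frame
#'   start/end/label) and `truth` (per-call ground-truth data.frame)
#' @export
synth_soundscape <- function(mix, calls = NULL, duration = 60,
                             seed = NULL, rate = 22050, snr_db = 0) {
  stopifnot(inherits(mix, "soundscape_mix"))
  if (duration < 0) stop("duration must be non-negative")
  if (!is.null(seed)) set.seed(seed) else set.seed(mix$seed)
  nyq <- rate / 2
  if (mix$shrimp_band[2] >= nyq && is.finite(mix$gains["shrimp"])) {
    stop("shrimp band exceeds Nyquist")
  }
  n <- round(duration * rate)
  x <- numeric(n)
  labels <- data.frame(start = numeric(0), end = numeric(0),
                       label = character(0), stringsAsFactors = FALSE)

  if (n > 0 && is.finite(mix$gains["shrimp"])) {
    n_snaps <- stats::rpois(1, mix$shrimp_snap_rate * duration)
    snaps <- numeric(n)
    if (n_snaps > 0) {
      at <- sort(stats::runif(n_snaps, 0, duration))
      nc <- max(8L, round(0.0025 * rate))
      decay <- exp(-seq_len(nc) / (nc / 4))
      for (t0 in at) {
        i0 <- floor(t0 * rate) + 1L
        i1 <- min(n, i0 + nc - 1L)
        amp <- stats::rexp(1, 1)
        snaps[i0:i1] <- snaps[i0:i1] + amp * stats::rnorm(i1 - i0 + 1L) * decay[seq_len(i1 - i0 + 1L)]
      }
      snaps <- fft_bandpass(snaps, rate, mix$shrimp_band[1], mix$shrimp_band[2])
      x <- x + set_rms(snaps, 10^(mix$gains["shrimp"] / 20))
    }
    labels <- rbind(labels, data.frame(start = 0, end = duration,
                                       label = "noise:shrimp"))
  }

  if (n > 0 && is.finite(mix$gains["boat"])) {
    ev <- mix$boat_events %||% data.frame(start = 0, end = duration)
    if (any(ev$start < 0 | ev$end > duration)) stop("boat event outside file")
    boat_rms <- 10^(mix$gains["boat"] / 20)
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$start[i] * rate) + 1L
      i1 <- min(n, ceiling(ev$end[i] * rate))
      m <- i1 - i0 + 1L
      if (m < 8L) next
      b <- fft_bandpass(stats::rnorm(m), rate, mix$boat_band[1], mix$boat_band[2])
      tt <- (seq_len(m) - 1L) / rate
      for (fl in mix$boat_tonal_lines) {
        if (fl < nyq) b <- b + 0.5 * sd(b) * sin(2 * pi * fl * tt + stats::runif(1, 0, 2 * pi))
      }
      x[i0:i1] <- x[i0:i1] + set_rms(b, boat_rms)
      labels <- rbind(labels, data.frame(start = ev$start[i], end = ev$end[i],
                                         label = "noise:boat"))
    }
  }

  if (n > 0 && is.finite(mix$gains["flow"])) {
    fl <- fft_lowpass(stats::rnorm(n), rate, mix$flow_cutoff)
    x <- x + set_rms(fl, 10^(mix$gains["flow"] / 20))
    labels <- rbind(labels, data.frame(start = 0, end = duration,
                                       label = "noise:flow"))
  }

  truth <- NULL
  if (!is.null(calls) && length(calls)) {
    for (cl in calls) {
      if (cl$time < 0 || cl$time >= duration) {
        stop("call placement at ", cl$time, " s lies beyond the file")
      }
      out <- synth_call(cl$spec, seed = NULL, rate = rate)
      w <- as.numeric(out$wave) * 10^(snr_db / 20)
      i0 <- floor(cl$time * rate) + 1L
      i1 <- min(n, i0 + length(w) - 1L)
      if (i1 >= i0) x[i0:i1] <- x[i0:i1] + w[seq_len(i1 - i0 + 1L)]
      end_t <- cl$time + length(w) / rate
      labels <- rbind(labels, data.frame(start = cl$time, end = min(end_t, duration),
                                         label = cl$spec$call_type))
      tr <- out$truth
      tr$start <- cl$time
      tr$end <- min(end_t, duration)
      truth <- rbind(truth, tr)
    }
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak * 0.99
  list(wave = audio_segment(if (n > 0) x else 0, rate = rate),
       labels = labels[order(labels$start), , drop = FALSE], truth = truth)
}

#' Sample a labelled feature table from the published marginals
#'
#' Draws rows from independent truncated-normal distributions per variable
#' per call type, using the published per-type means/SDs — the sampling
#' route for Random-Forest validation tests (no audio involved). Columns
#' follow the category availability mask; for single-band harmonic types
#' (scream, whine, whoo) energy quartiles are synthesized as small jitter
#' around the sampled f0, mirroring spectra whose energy sits in the
#' fundamental band (needed so the six-variable harmonic classifier has a
#' complete design matrix).
#'
#' @param category `"harmonic"`, `"noisy"` or `"pulsative"`
#' @param n_per_type named integer vector of rows per type (defaults to
#'   the published sample sizes)
#' @param seed integer seed
#' @return data.frame with `type`, `category` and the category's variables
#' @export
sample_feature_table <- function(category = c("harmonic", "noisy", "pulsative"),
                                 n_per_type = NULL, seed = NULL) {
  category <- match.arg(category)
  if (!is.null(seed)) set.seed(seed)
  p <- repertoire_params()
  p <- p[p$category == category, , drop = FALSE]
  if (is.null(n_per_type)) {
    n_per_type <- stats::setNames(p$n, p$name)
  }
  unknown <- setdiff(names(n_per_type), p$name)
  if (length(unknown)) stop("unknown type(s): ", paste(unknown, collapse = ", "))
  if (any(n_per_type < 1)) stop("n_per_type must be >= 1")

  rows <- lapply(names(n_per_type), function(ty) {
    pp <- p[p$name == ty, ]
    n <- n_per_type[[ty]]
    draw <- function(m, s, lo = 0) {
      if (is.na(m)) rep(NA_real_, n) else rtrunc_norm(n, m, s, lo)
    }
    f0 <- draw(pp$f0_mean, pp$f0_sd, 25)
    single_band <- ty %in% c("scream", "whine", "whoo")
    jit <- function(scale) if (single_band) f0 * rtrunc_norm(n, scale, 0.03, 0.5)
    data.frame(
      type = ty, category = category,
      dur = pmax(0.05, draw(pp$dur_mean, pp$dur_sd, 0.05)),
      f0 = f0,
      excF = draw(pp$excF_mean, pp$excF_sd),
      Fmax = if (single_band) f0 * rtrunc_norm(n, 1, 0.02, 0.5)
             else draw(pp$fmax_mean, pp$fmax_sd, 25),
      Q25 = if (single_band) jit(0.97) else draw(pp$q25_mean, pp$q25_sd, 25),
      Q50 = if (single_band) jit(1.00) else draw(pp$q50_mean, pp$q50_sd, 25),
      Q75 = if (single_band) jit(1.03) else draw(pp$q75_mean, pp$q75_sd, 25),
      PR = draw(pp$pr_mean, pp$pr_sd),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  keep <- switch(category,
                 harmonic = c("type", "category", "dur", "f0", "excF",
                              "Fmax", "Q25", "Q50", "Q75"),
                 noisy = c("type", "category", "dur", "Fmax", "Q25", "Q50", "Q75"),
                 pulsative = c("type", "category", "dur", "Fmax", "PR"))
  out[, keep, drop = FALSE]
}
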