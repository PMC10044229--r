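#' Measure call duration from the amplitude envelope
#'
#' Time between the first and last crossings of the envelope threshold
#' `peak - threshold_db`, the oscillogram reading of total call duration.
#'
#' @param segment an [audio_segment()]
#' @param threshold_db threshold below the envelope peak, dB (default -20)
#' @param smoothing envelope smoothing constant, s
#' @return duration, s
#' @export
measure_duration <- function(segment, threshold_db = -20, smoothing = 0.005) {
  env <- envelope(segment, smoothing = smoothing)
  peak <- max(env)
  if (peak <= 0 || stats::sd(as.numeric(segment)) == 0) {
    stop("silent segment: no duration measurable")
  }
  thr <- peak * 10^(threshold_db / 20)
  above <- which(env >= thr)
  (above[length(above)] - above[1]) / seg_rate(segment)
}

# Per-frame fundamental track around a reference f0. Small analysis
# frames keep the contour edges covered; each frame is scored with a log
# harmonic comb (teeth up to band[2]) so neither harmonics nor
# subharmonics of the true fundamental can capture the track, then the
# fundamental tooth is refined by parabolic interpolation.
f0_track <- function(segment, f_ref, band, fft_size = NULL, overlap = 0.75,
                     pad_factor = 8L, n_comb = 6L) {
  rate <- seg_rate(segment)
  x <- as.numeric(segment)
  n_sig <- length(x)
  if (is.null(fft_size)) {
    # at least ~6 cycles of the fundamental per frame so the harmonic
    # stack is resolved, bounded by the segment length
    fft_size <- 2^ceiling(log2(6 * rate / f_ref))
    fft_size <- max(256L, min(4096L, fft_size))
  }
  fft_size <- min(fft_size, 2^floor(log2(n_sig)))
  if (fft_size < 32L) stop("segment too short for an f0 track")
  # half-frame zero padding keeps frame centers covering the whole call,
  # so contour extremes at the call edges stay in the track
  x <- c(numeric(fft_size %/% 2L), x, numeric(fft_size %/% 2L))
  hop <- max(1L, as.integer(round(fft_size * (1 - overlap))))
  starts <- seq(1L, length(x) - fft_size + 1L, by = hop)
  if (length(starts) < 3L) stop("f0 track needs at least 3 frames")
  w <- hamming_window(fft_size)
  nfft <- fft_size * pad_factor
  nb <- nfft %/% 2L + 1L
  df <- rate / nfft
  grid <- seq(max(band[1], 0.4 * f_ref), min(band[2], 1.8 * f_ref), by = df)
  if (length(grid) < 3L) stop("empty f0 search band")
  # same comparably-normalized comb as comb_f0(): fixed tooth count, 1/k
  # weights, out-of-band teeth at the floor
  n_in_band <- floor(band[2] / df) + 1L
  wk <- 1 / seq_len(n_comb)
  tooth_idx <- lapply(grid, function(f) {
    ii <- round(f * seq_len(n_comb) / df) + 1L
    ii[ii > min(nb, n_in_band)] <- nb + 1L
    ii
  })
  est <- vapply(starts, function(s) {
    fr <- c(x[s:(s + fft_size - 1L)] * w, numeric(nfft - fft_size))
    p <- Mod(stats::fft(fr)[seq_len(nb)])^2
    pk <- max(p)
    if (pk <= 0) return(c(NA_real_, 0))
    floor_p <- 1e-5 * pk
    lp <- log(c(p, floor_p) + floor_p)
    score <- vapply(tooth_idx, function(ii) sum(wk * lp[ii]), 0)
    f_hat <- grid[which.max(score)]
    i <- round(f_hat / df) + 1L
    if (i > 1L && i < nb && p[i - 1L] > 0 && p[i + 1L] > 0) {
      lp <- log(p[(i - 1L):(i + 1L)])
      den <- lp[1] - 2 * lp[2] + lp[3]
      d <- if (den < 0) 0.5 * (lp[1] - lp[3]) / den else 0
      f_hat <- f_hat + max(-1, min(1, d)) * df
    }
    c(f_hat, p[i])
  }, c(0, 0))
  # drop near-empty frames (tapered edges, padding)
  keep <- is.finite(est[1, ]) & est[2, ] >= 0.02 * max(est[2, ], na.rm = TRUE)
  if (sum(keep) < 3L) stop("f0 track needs at least 3 usable frames")
  tr <- est[1, keep]
  # a 3-point running median removes isolated mis-tracked frames (the
  # half-empty first/last frames are the usual offenders)
  if (length(tr) >= 3L) tr <- stats::runmed(tr, 3L, endrule = "median")
  structure(as.numeric(tr),
            times = ((starts[keep] - 1L) + fft_size / 2) / rate -
              (fft_size %/% 2L) / rate)
}

#' Estimate the fundamental frequency
#'
#' Two-stage automation of the manual harmonic-cursor measurement: a
#' harmonic-comb (log harmonic-product) score over the average spectrum
#' localizes the fundamental in the search range, then the per-frame
#' fundamental track is averaged to remove the bias a frequency-modulated
#' contour would leave on a single spectrum peak. For single-band calls
#' the comb reduces to the dominant-peak frequency.
#'
#' @param segment an [audio_segment()]
#' @param band analysis band `c(lo, hi)` Hz
#' @param search f0 search range `c(f_min, f_max)` Hz
#' @param n_comb maximum number of comb teeth
#' @param snr_min minimum in-band peak-to-median power ratio; below it the
#'   call has no harmonic structure and an undefined-f0 error is raised
#' @return f0, Hz
#' @export
estimate_f0 <- function(segment, band = c(20, 1000), search = c(40, 400),
                        n_comb = 6L, snr_min = 8) {
  avg <- average_spectrum(segment, band = band)
  f_hat <- comb_f0(avg, band, search, n_comb, snr_min)
  # refine with the fundamental track mean (unbiased under FM); a second
  # pass re-centers the track band when the comb latched onto a contour
  # extreme
  for (it in 1:2) {
    f_new <- tryCatch(mean(f0_track(segment, f_hat, band)),
                      error = function(e) f_hat)
    converged <- abs(f_new - f_hat) < 0.05 * f_hat
    f_hat <- f_new
    if (converged) break
  }
  f_hat
}

# dominant harmonic of a stack: argmax over k of the mean in-band power
# within half a harmonic spacing of k*f0
harmonic_fmax <- function(avg, f0) {
  k_max <- max(1L, floor(max(avg$freq[avg$power > 0], 0) / f0))
  if (k_max < 1L || !is.finite(f0) || f0 <= 0) return(NULL)
  w <- 0.45 * f0
  pk <- vapply(seq_len(k_max), function(k) {
    sel <- abs(avg$freq - k * f0) <= w
    if (!any(sel)) 0 else mean(avg$power[sel])
  }, 0)
  if (all(pk == 0)) return(NULL)
  which.max(pk) * f0
}

# coarse harmonic-comb f0 on a precomputed average spectrum
comb_f0 <- function(avg, band, search, n_comb = 6L, snr_min = 8) {
  p <- avg$power
  in_band <- p > 0
  if (!any(in_band)) stop("undefined f0: no in-band energy")
  med <- stats::median(p[in_band])
  if (med <= 0 || max(p) / med < snr_min) {
    stop("undefined f0: no spectral peak above the noise floor")
  }
  floor_p <- 1e-4 * max(p)
  grid <- seq(max(search[1], avg$freq_step), min(search[2], band[2]),
              by = avg$freq_step / 4)
  if (length(grid) < 2L) stop("empty f0 search range")
  # fixed tooth count and 1/k weights keep candidate scores comparable:
  # out-of-band teeth read the floor, so a lone strong harmonic cannot
  # outscore the full stack and exact subharmonics lose on tooth 1
  wk <- 1 / seq_len(n_comb)
  lp <- log(c(p, rep(floor_p, n_comb)) + floor_p)
  score <- vapply(grid, function(f) {
    idx <- round(f * seq_len(n_comb) / avg$freq_step) + 1L
    idx[idx > length(p)] <- length(p) + 1L
    sum(wk * lp[idx]) / sum(wk)
  }, 0)
  grid[which.max(score)]
}

#' Excursion of the fundamental-frequency contour
#'
#' Absolute difference between the highest and lowest frequency of the
#' fundamental band over the call.
#'
#' The highest and lowest track frequencies are read as 2% / 98% track
#' quantiles: a smooth contour dwells near its extremes long enough that
#' the trim costs almost nothing, while a single mis-tracked frame cannot
#' inflate the excursion.
#'
#' @param segment an [audio_segment()]
#' @param f0 fundamental estimate, Hz (from [estimate_f0()]); used to
#'   restrict the track band
#' @param band analysis band, Hz
#' @param trim one-sided trimmed fraction of track frames
#' @return excF, Hz (non-negative)
#' @export
excursion_frequency <- function(segment, f0, band = c(20, 1000), trim = 0.02) {
  tr <- f0_track(segment, f0, band)
  if (length(tr) < 3L) stop("f0 track shorter than 3 frames")
  track_span(tr, trim)
}

track_span <- function(tr, trim = 0.02) {
  q <- stats::quantile(tr, c(trim, 1 - trim), names = FALSE, type = 7)
  max(0, q[2] - q[1])
}

#' Spectral peak and energy quartiles
#'
#' `Fmax` is the frequency of the highest in-band peak of the average
#' spectrum (optionally after light smoothing, which stabilizes the argmax
#' on modulated or stochastic spectra); `Q25`/`Q50`/`Q75` are the lowest
#' frequencies at which the cumulative in-band power reaches 25/50/75% of
#' the total in-band power.
#'
#' @param avg_spectrum an [average_spectrum()], or an [audio_segment()]
#'   (then the spectrum is computed over `band`)
#' @param band optional band restriction `c(lo, hi)` Hz
#' @param smooth_hz moving-average width applied before peak picking, Hz
#'   (0 = none; quartiles always use the raw spectrum)
#' @return named numeric: `Fmax`, `Q25`, `Q50`, `Q75` (Hz)
#' @export
peak_and_quartiles <- function(avg_spectrum, band = NULL, smooth_hz = 0) {
  if (inherits(avg_spectrum, "audio_segment")) {
    avg_spectrum <- average_spectrum(avg_spectrum,
                                     band = band %||% c(20, seg_rate(avg_spectrum) / 2))
  }
  p <- avg_spectrum$power
  freq <- avg_spectrum$freq
  if (!is.null(band)) p[freq < band[1] | freq > band[2]] <- 0
  if (sum(p) <= 0) stop("zero in-band energy")
  ps <- p
  if (smooth_hz > 0) {
    k <- max(1L, round(smooth_hz / avg_spectrum$freq_step))
    if (k %% 2L == 0L) k <- k + 1L
    ps <- stats::filter(p, rep(1 / k, k), sides = 2)
    ps[is.na(ps)] <- 0
    ps[p == 0] <- 0                       # keep the argmax in band
  }
  i <- which.max(ps)
  fmax <- freq[i]
  if (i > 1L && i < length(ps) && ps[i - 1L] > 0 && ps[i + 1L] > 0) {
    y <- as.numeric(ps[(i - 1L):(i + 1L)])
    d <- 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
    if (is.finite(d) && abs(d) < 1) fmax <- freq[i] + d * avg_spectrum$freq_step
  }
  cs <- cumsum(p) / sum(p)
  qf <- vapply(c(0.25, 0.5, 0.75), function(q) freq[which(cs >= q)[1]], 0)
  c(Fmax = fmax, Q25 = qf[1], Q50 = qf[2], Q75 = qf[3])
}

#' Pulse rate of a pulsative call
#'
#' Discrete mode (click series): pulses are segmented as contiguous
#' regions of the amplitude envelope above a fraction of its peak and the
#' rate is `(n_pulses - 1) / (t_last - t_first)` — the pulse-train
#' reading. AM mode (fast amplitude modulation): the rate is the peak of
#' the envelope spectrum within `search`.
#'
#' @param segment an [audio_segment()]
#' @param mode `"discrete"` or `"am"`
#' @param smoothing envelope smoothing, s
#' @param threshold fraction of the envelope peak segmenting pulses
#'   (discrete mode)
#' @param search modulation-rate search range, Hz (AM mode)
#' @return pulse rate, pulses/s
#' @export
pulse_rate <- function(segment, mode = c("discrete", "am"), smoothing = 0.02,
                       threshold = 0.4, search = c(2, 50)) {
  mode <- match.arg(mode)
  env <- as.numeric(envelope(segment, smoothing = smoothing))
  rate <- seg_rate(segment)
  if (mode == "discrete") {
    above <- env >= threshold * max(env)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (sum(keep) < 2L) stop("fewer than 2 pulses detected")
    centers <- vapply(which(keep), function(i) {
      seg <- starts[i]:ends[i]
      seg[which.max(env[seg])]
    }, 0L)
    (length(centers) - 1L) / ((centers[length(centers)] - centers[1]) / rate)
  } else {
    n <- length(env)
    e <- env - mean(env)
    nfft <- 2^ceiling(log2(n * 8))
    P <- Mod(stats::fft(c(e * hann_window(n), numeric(nfft - n)))[1:(nfft %/% 2 + 1)])^2
    freq <- (seq_len(nfft %/% 2 + 1) - 1) * rate / nfft
    sel <- freq >= search[1] & freq <= search[2]
    if (!any(sel)) stop("empty modulation search range")
    Pb <- P
    Pb[!sel] <- 0
    i <- which.max(Pb)
    f_am <- freq[i]
    if (i > 1L && i < length(Pb) && Pb[i - 1] > 0 && Pb[i + 1] > 0) {
      y <- log(Pb[(i - 1):(i + 1)])
      d <- 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
      if (is.finite(d) && abs(d) < 1) f_am <- freq[i] + d * rate / nfft
    }
    if (f_am * n / rate < 2) stop("fewer than 2 modulation cycles")
    f_am
  }
}

#' Extract the feature vector of one labelled call segment
#'
#' Dispatches per call category with the type's analysis band and fills
#' the availability mask: harmonic calls get dur/f0/excF/Fmax plus energy
#' quartiles; noisy calls dur/Fmax/quartiles; pulsative calls dur/PR plus
#' the masked-on spectral variables. Only good-quality segments are
#' measured and moans are refused as not measurable. Quartiles of
#' single-band harmonic types are computed (the classifier needs them) but
#' flagged for suppression in repertoire-style reports via the `mask`
#' attribute.
#'
#' @param segment an [audio_segment()] covering exactly the call
#' @param type call-type name (see [call_type_registry()])
#' @param quality `"good"` or `"degraded"`; degraded calls are refused
#' @param smooth_hz peak-picking smoothing passed to [peak_and_quartiles()]
#' @return named numeric feature vector (NA for unavailable variables)
#'   with attribute `mask` (logical: reported in a repertoire table)
#' @export
extract_features <- function(segment, type, quality = "good", smooth_hz = 30) {
  ct <- call_type(type)
  if (!identical(quality, "good")) {
    stop("segment quality '", quality, "': only good-quality calls are measured")
  }
  if (!ct$measurable) stop("call type '", ct$name, "' is not measurable")
  band <- c(ct$band_lo, ct$band_hi)
  out <- c(dur = NA_real_, f0 = NA_real_, excF = NA_real_, Fmax = NA_real_,
           Q25 = NA_real_, Q50 = NA_real_, Q75 = NA_real_, PR = NA_real_)
  maybe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  out["dur"] <- maybe(measure_duration(segment))
  if (ct$category == "harmonic") {
    avg <- maybe(average_spectrum(segment, band = band))
    if (!is.list(avg)) return(finish_features(out, ct))
    f0 <- NA_real_
    tr <- NULL
    coarse <- maybe(comb_f0(avg, band, f0_search_range(ct$name)))
    if (!is.na(coarse)) {
      # one fundamental track serves both f0 (its mean) and excF (its
      # span); re-track once if the coarse comb was far off
      tr <- tryCatch(f0_track(segment, coarse, band), error = function(e) NULL)
      if (!is.null(tr) && abs(mean(tr) - coarse) > 0.05 * coarse) {
        tr2 <- tryCatch(f0_track(segment, mean(tr), band), error = function(e) NULL)
        if (!is.null(tr2)) tr <- tr2
      }
      f0 <- if (is.null(tr)) coarse else mean(tr)
    }
    out["f0"] <- f0
    if (ct$m_excF && !is.null(tr) && length(tr) >= 3L) {
      out["excF"] <- track_span(tr)
    }
    pq <- maybe(peak_and_quartiles(avg, smooth_hz = smooth_hz))
    if (length(pq) == 4L) {
      out[c("Fmax", "Q25", "Q50", "Q75")] <- pq
      if (!is.na(f0)) {
        # on a harmonic stack the energy peak is a harmonic: compare band
        # power around each harmonic of f0 directly (robust to the smear
        # a modulated contour leaves on the raw argmax)
        out["Fmax"] <- harmonic_fmax(avg, f0) %||% pq[["Fmax"]]
      }
    }
  } else if (ct$category == "noisy") {
    pq <- maybe(peak_and_quartiles(segment, band = band, smooth_hz = smooth_hz))
    if (length(pq) == 4L) out[c("Fmax", "Q25", "Q50", "Q75")] <- pq
  } else {
    mode <- if (identical(ct$pr_mode, "am")) "am" else "discrete"
    out["PR"] <- maybe(pulse_rate(segment, mode = mode))
    if (ct$m_Fmax || ct$m_Q25) {
      pq <- maybe(peak_and_quartiles(segment, band = band, smooth_hz = smooth_hz))
      if (length(pq) == 4L) {
        out["Fmax"] <- if (ct$m_Fmax) pq["Fmax"] else NA_real_
        if (ct$m_Q25) out[c("Q25", "Q50", "Q75")] <- pq[c("Q25", "Q50", "Q75")]
      }
    }
  }
  finish_features(out, ct)
}

finish_features <- function(out, ct) {
  mask <- c(dur = ct$m_dur, f0 = ct$m_f0, excF = ct$m_excF, Fmax = ct$m_Fmax,
            Q25 = ct$m_Q25, Q50 = ct$m_Q50, Q75 = ct$m_Q75, PR = ct$m_PR)
  structure(out, mask = mask, type = ct$name, category = ct$category)
}

# per-type f0 search range from the published marginals (mean +- 3.5 SD,
# clipped to the analysis band); unlisted types get the low-pitched
# default 40-400 Hz
f0_search_range <- function(type) {
  if (tolower(type) == "scream") return(c(500, 2000))
  p <- repertoire_params()
  p <- p[p$name == tolower(type), , drop = FALSE]
  if (nrow(p) == 0L || is.na(p$f0_mean)) return(c(40, 400))
  reg <- call_type(type)
  c(max(25, p$f0_mean - 3.5 * p$f0_sd),
    min(reg$band_hi * 0.98, p$f0_mean + 3.5 * p$f0_sd))
}

#' Extract a feature table from audio plus a label track
#'
#' Cuts each labelled interval out of the recording, applies the quality
#' gate (labels may carry a `|degraded` suffix) and measures the
#' category-specific features. Moans and degraded calls are skipped with
#' a reason.
#'
#' @param wave an [audio_segment()] (a whole recording)
#' @param labels data.frame start/end/label as from [read_label_track()];
#'   rows whose label starts with `noise:` are ignored
#' @param report if TRUE, apply the per-type availability mask (NA out
#'   internally-computed variables not reported for the type)
#' @return data.frame with one row per measured call (columns `call_id`,
#'   `type`, `category`, the 8 variables) and attribute `skipped`
#'   (data.frame of call_id/reason)
#' @export
extract_feature_table <- function(wave, labels, report = FALSE) {
  labels <- labels[!startsWith(labels$label, "noise:"), , drop = FALSE]
  rows <- vector("list", nrow(labels))
  skipped <- list()
  for (i in seq_len(nrow(labels))) {
    lab <- strsplit(labels$label[i], "|", fixed = TRUE)[[1]]
    type <- lab[1]
    quality <- if (length(lab) > 1L) lab[2] else "good"
    res <- tryCatch({
      seg <- cut_segment(wave, labels$start[i], labels$end[i])
      fv <- extract_features(seg, type, quality = quality)
      if (report) fv[!attr(fv, "mask")] <- NA_real_
      data.frame(call_id = i, type = attr(fv, "type"),
                 category = attr(fv, "category"),
                 as.list(unclass(fv)[1:8]), stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        call_id = i, type = type, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(call_id = integer(0), type = character(0),
                      category = character(0))
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(call_id = integer(0), type = character(0), reason = character(0))
  out
}
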