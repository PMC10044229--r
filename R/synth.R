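#' Synthesis specification for one call type
#'
#' Per-call-type generative parameters mirroring the published repertoire
#' statistics: truncated-normal marginals for duration, fundamental
#' frequency, frequency excursion, spectral peak, energy quartiles and
#' pulse rate. Variables are sampled independently (only marginals are
#' published). Category decides which fields are used:
#' * `harmonic`: `dur`, `f0`, `excF`, `fmax` (picks the emphasized
#'   harmonic), `n_harmonics`, `rolloff_db`
#' * `noisy`: `dur`, `fmax`, quartile targets (or a flat `spectral_band`)
#' * `pulsative`: `dur`, `pr` (+ spectral fields for AM calls)
#'
#' @param call_type name (free text; registry types get sensible defaults
#'   via [type_spec()])
#' @param category `"harmonic"`, `"noisy"` or `"pulsative"`
#' @param dur_mean,dur_sd duration, s
#' @param f0_mean,f0_sd fundamental frequency, Hz (harmonic)
#' @param excF_mean,excF_sd excursion of the f0 contour, Hz (harmonic)
#' @param n_harmonics number of synthesized harmonics (harmonic)
#' @param fmax_mean,fmax_sd target spectral peak, Hz
#' @param q_mean,q_sd length-3 targets for Q25/Q50/Q75, Hz (noisy, AM)
#' @param spectral_band `c(lo, hi)` Hz flat shaping band (noisy fallback)
#' @param pr_mean,pr_sd pulse rate, pulses/s (pulsative)
#' @param pr_mode `"discrete"` (click series) or `"am"` (amplitude
#'   modulated carrier)
#' @param amplitude linear full-scale peak fraction
#' @param min_dur floor applied to sampled durations, s
#' @param rolloff_db harmonic amplitude roll-off per harmonic step away
#'   from the emphasized harmonic, dB (default -6)
#' @return object of class `synthesis_spec`
#' @export
synthesis_spec <- function(call_type, category,
                           dur_mean, dur_sd = 0,
                           f0_mean = NA, f0_sd = 0,
                           excF_mean = 0, excF_sd = 0,
                           n_harmonics = 4L,
                           fmax_mean = NA, fmax_sd = 0,
                           q_mean = NULL, q_sd = NULL,
                           spectral_band = NULL,
                           pr_mean = NA, pr_sd = 0,
                           pr_mode = c("discrete", "am"),
                           amplitude = 0.3, min_dur = 0.05,
                           rolloff_db = -6) {
  category <- match.arg(category, c("harmonic", "noisy", "pulsative"))
  if (min_dur <= 0) stop("min_dur must be > 0")
  if (dur_mean <= 0 || dur_sd < 0) stop("duration parameters must be positive")
  if (category == "harmonic" && (is.na(f0_mean) || f0_mean <= 0)) {
    stop("harmonic spec needs f0_mean > 0")
  }
  if (category == "pulsative" && (is.na(pr_mean) || pr_mean <= 0)) {
    stop("pulsative spec needs pr_mean > 0")
  }
  if (!is.null(q_mean) && (length(q_mean) != 3L || any(diff(q_mean) < 0))) {
    stop("q_mean must be 3 non-decreasing quartile targets")
  }
  structure(list(call_type = call_type, category = category,
                 dur_mean = dur_mean, dur_sd = dur_sd,
                 f0_mean = f0_mean, f0_sd = f0_sd,
                 excF_mean = excF_mean, excF_sd = excF_sd,
                 n_harmonics = as.integer(n_harmonics),
                 fmax_mean = fmax_mean, fmax_sd = fmax_sd,
                 q_mean = q_mean, q_sd = q_sd,
                 spectral_band = spectral_band,
                 pr_mean = pr_mean, pr_sd = pr_sd,
                 pr_mode = match.arg(pr_mode),
                 amplitude = amplitude, min_dur = min_dur,
                 rolloff_db = rolloff_db),
            class = "synthesis_spec")
}

#' Build the synthesis spec of a registry call type
#'
#' Fills a [synthesis_spec()] from the published per-type statistics
#' ([repertoire_params()]) and the registry's analysis bands. Moans (too
#' faint to be measured in the field) get a nominal faint parameterization
#' and are excluded from [repertoire_params()].
#'
#' @param name call-type name
#' @return a `synthesis_spec`
#' @export
type_spec <- function(name) {
  name <- tolower(name)
  if (name == "moan") {
    return(synthesis_spec("moan", "harmonic", dur_mean = 0.4, dur_sd = 0.15,
                          f0_mean = 150, f0_sd = 40, excF_mean = 30,
                          excF_sd = 15, n_harmonics = 2L, amplitude = 0.02))
  }
  p <- repertoire_params()
  p <- p[p$name == name, , drop = FALSE]
  if (nrow(p) == 0L) stop("unknown call type: ", name)
  reg <- call_type(name)
  amp <- if (name %in% c("knock", "clap")) 0.8 else 0.3
  if (p$category == "harmonic") {
    synthesis_spec(name, "harmonic",
                   dur_mean = p$dur_mean, dur_sd = p$dur_sd,
                   f0_mean = p$f0_mean, f0_sd = p$f0_sd,
                   excF_mean = ifelse(is.na(p$excF_mean), 0, p$excF_mean),
                   excF_sd = ifelse(is.na(p$excF_sd), 0, p$excF_sd),
                   n_harmonics = default_n_harmonics(p),
                   fmax_mean = p$fmax_mean, fmax_sd = p$fmax_sd,
                   amplitude = amp)
  } else if (p$category == "noisy") {
    synthesis_spec(name, "noisy",
                   dur_mean = p$dur_mean, dur_sd = p$dur_sd,
                   fmax_mean = p$fmax_mean, fmax_sd = p$fmax_sd,
                   q_mean = c(p$q25_mean, p$q50_mean, p$q75_mean),
                   q_sd = c(p$q25_sd, p$q50_sd, p$q75_sd),
                   spectral_band = c(reg$band_lo, reg$band_hi),
                   amplitude = amp)
  } else {
    has_q <- !is.na(p$q25_mean)
    synthesis_spec(name, "pulsative",
                   dur_mean = p$dur_mean, dur_sd = p$dur_sd,
                   fmax_mean = p$fmax_mean, fmax_sd = p$fmax_sd,
                   q_mean = if (has_q) c(p$q25_mean, p$q50_mean, p$q75_mean),
                   q_sd = if (has_q) c(p$q25_sd, p$q50_sd, p$q75_sd),
                   spectral_band = c(max(reg$band_lo, 100),
                                     min(reg$band_hi, 2500)),
                   pr_mean = p$pr_mean, pr_sd = p$pr_sd,
                   pr_mode = if (name == "rumble") "am" else "discrete",
                   amplitude = amp)
  }
}

# truncated normal, lower bound lo (exact inverse-CDF method)
rtrunc_norm <- function(n, mean, sd, lo = 0) {
  if (sd <= 0) return(rep(max(mean, lo), n))
  plo <- stats::pnorm(lo, mean, sd)
  if (plo >= 1) return(rep(lo, n))
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, mean, sd)
}

raised_cosine_taper <- function(n, rate, taper_s = 0.005) {
  nt <- min(n %/% 2L, max(1L, round(taper_s * rate)))
  w <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(nt) / nt))
  w[seq_len(nt)] <- ramp
  w[(n - nt + 1L):n] <- rev(ramp)
  w
}

truth_row <- function(spec, dur, f0 = NA, excF = NA, fmax = NA,
                      q = c(NA, NA, NA), q_target = c(NA, NA, NA), pr = NA) {
  data.frame(type = spec$call_type, category = spec$category,
             gt_dur = dur, gt_f0 = f0, gt_excF = excF, gt_fmax = fmax,
             gt_q25 = q[1], gt_q50 = q[2], gt_q75 = q[3],
             tgt_q25 = q_target[1], tgt_q50 = q_target[2], tgt_q75 = q_target[3],
             gt_pr = pr, stringsAsFactors = FALSE)
}

#' Synthesize a harmonic call
#'
#' A tapered sum of harmonics of a slowly frequency-modulated fundamental.
#' The f0 contour is a single raised-cosine arch centered on the sampled
#' fundamental and spanning exactly the sampled excursion `excF`; harmonic
#' amplitudes roll off (default -6 dB per step) away from the harmonic
#' closest to the sampled spectral-peak target, so the realized `Fmax`
#' falls on the harmonic grid.
#'
#' @param spec a [synthesis_spec()] with `category = "harmonic"`
#' @param seed integer seed (`NULL` to use the current RNG stream)
#' @param rate output sample rate, Hz
#' @return list with `wave` (an [audio_segment()]) and `truth` (one-row
#'   data.frame of realized parameters)
#' @export
synth_harmonic_call <- function(spec, seed = NULL, rate = 22050) {
  stopifnot(inherits(spec, "synthesis_spec"))
  if (spec$category != "harmonic") stop("spec is not harmonic")
  if (!is.null(seed)) set.seed(seed)
  dur <- max(spec$min_dur, rtrunc_norm(1, spec$dur_mean, spec$dur_sd, spec$min_dur))
  excF <- if (spec$excF_mean > 0 || spec$excF_sd > 0) {
    rtrunc_norm(1, spec$excF_mean, spec$excF_sd, 0)
  } else 0
  f0 <- rtrunc_norm(1, spec$f0_mean, spec$f0_sd, lo = max(25, excF / 2 + 20))
  fmax_t <- if (is.na(spec$fmax_mean)) f0 else rtrunc_norm(1, spec$fmax_mean, spec$fmax_sd, 25)
  k_star <- max(1L, min(spec$n_harmonics, as.integer(round(fmax_t / f0))))

  f_top <- spec$n_harmonics * (f0 + excF / 2)
  if (f_top >= rate / 2) {
    stop(sprintf("harmonic %d at %.0f Hz exceeds Nyquist (%.0f Hz)",
                 spec$n_harmonics, f_top, rate / 2))
  }
  n <- max(16L, round(dur * rate))
  t <- (seq_len(n) - 1L) / rate
  # raised-cosine arch centered on f0, spanning excF exactly
  contour <- f0 - excF / 2 + excF * sin(pi * t / dur)^2
  phase <- 2 * pi * cumsum(contour) / rate
  amps <- 10^(spec$rolloff_db * abs(seq_len(spec$n_harmonics) - k_star) / 20)
  x <- numeric(n)
  for (k in seq_len(spec$n_harmonics)) {
    x <- x + amps[k] * sin(k * phase + stats::runif(1, 0, 2 * pi))
  }
  x <- x / max(abs(x)) * spec$amplitude
  x <- x * raised_cosine_taper(n, rate)

  # realized energy quartiles on the harmonic grid (analytic cumulative sum)
  p_k <- amps^2
  cs <- cumsum(p_k) / sum(p_k)
  qf <- vapply(c(0.25, 0.5, 0.75), function(q) f0 * which(cs >= q - 1e-12)[1], 0)
  list(wave = audio_segment(x, rate = rate),
       truth = truth_row(spec, dur, f0 = f0, excF = excF,
                         fmax = k_star * f0, q = qf))
}

# Power-density shape hitting the quartile targets exactly: a Gaussian
# bump at the spectral-peak target carries a fixed energy fraction, and
# each inter-quartile segment's flat floor is topped up so segment energy
# (floor + bump mass inside it) is exactly 25%. The bump therefore sets
# the argmax without displacing the quartiles.
quartile_shape <- function(q, band, fmax = NA, bump_sigma = 25,
                           bump_frac = 0.15) {
  q <- sort(q)
  lo <- max(band[1], 2 * q[1] - q[2])
  hi <- min(band[2], 2 * q[3] - q[2])
  edges <- c(lo, q, hi)
  if (any(diff(edges) <= 0)) {
    edges <- cumsum(c(lo, pmax(diff(edges), 1)))
  }
  if (!is.na(fmax)) {
    fmax <- min(max(fmax, edges[1] + bump_sigma), edges[5] - bump_sigma)
    cdf <- stats::pnorm(edges, fmax, bump_sigma)
    mass_in <- cdf[5] - cdf[1]
    # adaptive bump: its peak must top every flat segment (narrow
    # inter-quartile segments can be tall), its total energy stays small
    # enough that segment energies (floor + bump mass inside, 25% each)
    # remain solvable
    b <- numeric(4)
    for (it in 1:3) {
      d_base <- pmax(0.25 - b, 0.01) / diff(edges)
      a <- 2 * max(d_base)
      frac <- min(0.22, a * mass_in * bump_sigma * sqrt(2 * pi))
      a <- frac / (mass_in * bump_sigma * sqrt(2 * pi))
      b <- frac * diff(cdf) / mass_in
    }
  } else {
    b <- numeric(4)
    a <- 0
  }
  dens <- pmax(0.25 - b, 0.01) / diff(edges)
  list(edges = edges, fmax = fmax,
       fn = function(f) {
         d <- rep(0, length(f))
         for (i in 1:4) {
           sel <- f >= edges[i] & f < edges[i + 1]
           d[sel] <- dens[i]
         }
         if (a > 0) d <- d + a * exp(-(f - fmax)^2 / (2 * bump_sigma^2)) *
             (f >= edges[1] & f < edges[5])
         d
       })
}

# quartiles of a sampled power density by direct cumulative summation
density_quartiles <- function(freq, dens) {
  cs <- cumsum(dens) / sum(dens)
  vapply(c(0.25, 0.5, 0.75), function(q) freq[which(cs >= q)[1]], 0)
}

#' Synthesize a noisy (broadband) call
#'
#' White noise spectrally shaped so that the average spectrum approaches
#' the sampled quartile targets (piecewise-flat density with 25% of the
#' energy between successive quartiles) with a localized emphasis at the
#' sampled `Fmax`. When no quartile targets exist, shaping is flat over
#' `spectral_band`. Ground truth records the realized quartiles computed
#' by direct cumulative summation of the shaping density.
#'
#' @inheritParams synth_harmonic_call
#' @export
synth_noisy_call <- function(spec, seed = NULL, rate = 22050) {
  stopifnot(inherits(spec, "synthesis_spec"))
  if (spec$category != "noisy") stop("spec is not noisy")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spec$q_mean) && is.null(spec$spectral_band)) {
    stop("noisy spec needs quartile targets or a spectral band")
  }
  dur <- max(spec$min_dur, rtrunc_norm(1, spec$dur_mean, spec$dur_sd, spec$min_dur))
  n <- max(32L, round(dur * rate))
  freq <- seq(0, rate / 2, length.out = n %/% 2L + 1L)

  if (!is.null(spec$q_mean)) {
    q_t <- sort(vapply(1:3, function(i)
      rtrunc_norm(1, spec$q_mean[i], if (is.null(spec$q_sd)) 0 else spec$q_sd[i], 30), 0))
    fmax_t <- if (is.na(spec$fmax_mean)) NA else
      rtrunc_norm(1, spec$fmax_mean, spec$fmax_sd, 30)
    band <- spec$spectral_band %||% c(20, rate / 2)
    shp <- quartile_shape(q_t, band, fmax_t)
    dens <- shp$fn(freq)
    # realized spectral peak: argmax of the shaping density itself
    fmax_r <- if (is.na(shp$fmax)) NA else freq[which.max(dens)]
  } else {
    band <- spec$spectral_band
    if (band[2] <= band[1]) stop("empty shaping band")
    dens <- as.numeric(freq >= band[1] & freq <= band[2])
    fmax_r <- NA
    q_t <- rep(NA_real_, 3)
  }
  if (sum(dens) <= 0) stop("empty shaping band")
  x <- shaped_noise(n, rate, dens)
  x <- x / max(abs(x)) * spec$amplitude
  x <- x * raised_cosine_taper(n, rate)
  q_r <- density_quartiles(freq, dens)
  list(wave = audio_segment(x, rate = rate),
       truth = truth_row(spec, dur, fmax = fmax_r, q = q_r, q_target = q_t))
}

# white noise filtered to a given one-sided power density sampled at
# seq(0, rate/2, length n/2+1); internally works at a fast FFT length
shaped_noise <- function(n, rate, dens) {
  m <- stats::nextn(n, c(2, 3, 5))
  nb_n <- n %/% 2L + 1L
  nb_m <- m %/% 2L + 1L
  if (m == n) {
    g <- sqrt(dens)
  } else {
    g <- sqrt(stats::approx(seq(0, rate / 2, length.out = nb_n), dens,
                            xout = seq(0, rate / 2, length.out = nb_m),
                            rule = 2)$y)
  }
  Z <- stats::fft(stats::rnorm(m))
  full <- c(g, rev(g[2:(m - nb_m + 1L)]))
  (Re(stats::fft(Z * full, inverse = TRUE)) / m)[seq_len(n)]
}

#' Synthesize a pulsative call
#'
#' Discrete mode: a series of short broadband clicks at exactly the
#' sampled pulse rate (clicks at `k/PR`, `k = 0..floor(dur*PR)`), each a
#' tapered shaped-noise burst. AM mode: a shaped-noise carrier with a
#' sinusoidal amplitude modulation at the sampled rate.
#'
#' @inheritParams synth_harmonic_call
#' @param click_dur click length in discrete mode, s
#' @param am_depth modulation index in AM mode, 0-1
#' @export
synth_pulsative_call <- function(spec, seed = NULL, rate = 22050,
                                 click_dur = 0.008, am_depth = 0.8) {
  stopifnot(inherits(spec, "synthesis_spec"))
  if (spec$category != "pulsative") stop("spec is not pulsative")
  if (!is.null(seed)) set.seed(seed)
  pr <- rtrunc_norm(1, spec$pr_mean, spec$pr_sd, 0)
  if (pr <= 0) stop("pulse rate must be > 0")
  dur <- max(spec$min_dur, rtrunc_norm(1, spec$dur_mean, spec$dur_sd, spec$min_dur))
  if (dur * pr < 1) stop("fewer than 2 pulses representable (pr*dur < 1)")
  band <- spec$spectral_band %||% c(100, min(2500, rate / 2 * 0.9))

  if (spec$pr_mode == "discrete") {
    n_pulses <- floor(dur * pr) + 1L
    if (n_pulses < 2L) stop("fewer than 2 pulses representable")
    span <- (n_pulses - 1L) / pr
    nc <- max(8L, round(click_dur * rate))
    n <- round(span * rate) + nc + 16L
    freq <- seq(0, rate / 2, length.out = nc %/% 2L + 1L)
    if (!is.na(spec$fmax_mean)) {
      fmax_t <- rtrunc_norm(1, spec$fmax_mean, spec$fmax_sd, 50)
      fmax_t <- min(max(fmax_t, band[1] + 50), band[2] - 50)
      dens <- as.numeric(freq >= band[1] & freq <= band[2]) +
        3 * exp(-(freq - fmax_t)^2 / (2 * 60^2))
      fmax_r <- fmax_t
    } else {
      dens <- as.numeric(freq >= band[1] & freq <= band[2])
      fmax_r <- NA
    }
    x <- numeric(n)
    for (k in seq_len(n_pulses) - 1L) {
      click <- shaped_noise(nc, rate, dens)
      click <- click / max(abs(click)) * raised_cosine_taper(nc, rate, click_dur / 4)
      i0 <- round(k / pr * rate) + 1L
      x[i0:(i0 + nc - 1L)] <- x[i0:(i0 + nc - 1L)] + click
    }
    x <- x / max(abs(x)) * spec$amplitude
    list(wave = audio_segment(x, rate = rate),
         truth = truth_row(spec, dur = span + click_dur, fmax = fmax_r, pr = pr))
  } else {
    if (dur * pr < 2) stop("fewer than 2 modulation cycles representable")
    n <- max(64L, round(dur * rate))
    freq <- seq(0, rate / 2, length.out = n %/% 2L + 1L)
    if (!is.null(spec$q_mean)) {
      q_t <- sort(vapply(1:3, function(i)
        rtrunc_norm(1, spec$q_mean[i], if (is.null(spec$q_sd)) 0 else spec$q_sd[i], 30), 0))
      fmax_t <- if (is.na(spec$fmax_mean)) NA else
        rtrunc_norm(1, spec$fmax_mean, spec$fmax_sd, 30)
      shp <- quartile_shape(q_t, band, fmax_t)
      dens <- shp$fn(freq)
      fmax_r <- if (is.na(shp$fmax)) NA else freq[which.max(dens)]
      q_r <- density_quartiles(freq, dens)
    } else {
      dens <- as.numeric(freq >= band[1] & freq <= band[2])
      fmax_r <- NA
      q_t <- q_r <- rep(NA_real_, 3)
    }
    carrier <- shaped_noise(n, rate, dens)
    t <- (seq_len(n) - 1L) / rate
    am <- (1 + am_depth * cos(2 * pi * pr * t)) / (1 + am_depth)
    x <- carrier * am
    x <- x / max(abs(x)) * spec$amplitude
    x <- x * raised_cosine_taper(n, rate)
    list(wave = audio_segment(x, rate = rate),
         truth = truth_row(spec, dur, fmax = fmax_r, q = q_r,
                           q_target = q_t, pr = pr))
  }
}

#' Synthesize one call of any category
#'
#' Dispatches on `spec$category`.
#'
#' @inheritParams synth_harmonic_call
#' @export
synth_call <- function(spec, seed = NULL, rate = 22050) {
  switch(spec$category,
         harmonic = synth_harmonic_call(spec, seed, rate),
         noisy = synth_noisy_call(spec, seed, rate),
         pulsative = synth_pulsative_call(spec, seed, rate))
}
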