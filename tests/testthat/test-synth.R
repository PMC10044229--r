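test_that("harmonic synthesis places bands on the harmonic grid", {
  # bark-like: fundamental 137 Hz -> bands at 137, 274, 411 Hz
  sp <- synthesis_spec("bark", "harmonic", dur_mean = 0.418, f0_mean = 137,
                       excF_mean = 0, n_harmonics = 3L, fmax_mean = 137)
  o <- synth_harmonic_call(sp, seed = 1)
  x <- as.numeric(o$wave)
  n <- length(x)
  p <- Mod(stats::fft(x)[seq_len(n %/% 2 + 1)])^2
  f <- (seq_len(n %/% 2 + 1) - 1) * 22050 / n
  for (k in 1:3) {
    sel <- abs(f - 137 * k) < 15
    expect_gt(sum(p[sel]) / sum(p), 0.02)
  }
  expect_equal(o$truth$gt_f0, 137)
  expect_equal(o$truth$gt_dur, 0.418)

  # excF = 0 with one harmonic is a pure tone
  tone <- synth_harmonic_call(synthesis_spec("t", "harmonic", dur_mean = 0.5,
                                             f0_mean = 200, n_harmonics = 1L),
                              seed = 2)
  expect_equal(tone$truth$gt_excF, 0)
  expect_equal(fft_peak_freq(as.numeric(tone$wave), 22050), 200, tolerance = 2.5)

  # scream-like single band: FFT-argmax oracle finds 1207 Hz
  sc <- synth_harmonic_call(synthesis_spec("scream", "harmonic", dur_mean = 0.408,
                                           f0_mean = 1207, n_harmonics = 1L),
                            seed = 3)
  expect_equal(fft_peak_freq(as.numeric(sc$wave), 22050), 1207, tolerance = 3)
})

test_that("harmonic synthesis rejects Nyquist violations naming the harmonic", {
  sp <- synthesis_spec("x", "harmonic", dur_mean = 0.3, f0_mean = 2000,
                       n_harmonics = 6L)
  expect_error(synth_harmonic_call(sp, seed = 1, rate = 11025),
               "harmonic 6 .* Nyquist")
})

test_that("noisy synthesis approaches quartile targets", {
  # flat band 300-700 Hz -> median near 500 by symmetry
  flat <- synthesis_spec("n", "noisy", dur_mean = 0.5, spectral_band = c(300, 700))
  o <- synth_noisy_call(flat, seed = 4)
  expect_equal(o$truth$gt_q50, 500, tolerance = 25)

  # hiccup-like targets recovered in the realized density
  sp <- synthesis_spec("hiccup", "noisy", dur_mean = 0.177,
                       q_mean = c(353, 422, 567), fmax_mean = 395,
                       spectral_band = c(20, 1000))
  oh <- synth_noisy_call(sp, seed = 5)
  expect_equal(oh$truth$gt_q25, 353, tolerance = 0.15 * 353)
  expect_equal(oh$truth$gt_q50, 422, tolerance = 0.15 * 422)
  expect_equal(oh$truth$gt_q75, 567, tolerance = 0.15 * 567)

  # degenerate inputs
  expect_error(synth_noisy_call(synthesis_spec("n", "noisy", dur_mean = 0.2,
                                               spectral_band = c(700, 300)),
                                seed = 1), "empty")
  expect_error(synthesis_spec("n", "noisy", dur_mean = 0))
})

test_that("pulsative synthesis realizes the pulse rate", {
  # clap-like series: 5.103 s at 1.70 pulses/s -> 9 pulses
  sp <- synthesis_spec("clap", "pulsative", dur_mean = 5.103, pr_mean = 1.70,
                       spectral_band = c(100, 1000))
  o <- synth_pulsative_call(sp, seed = 6)
  env <- envelope(o$wave)
  pulses <- rle(as.numeric(env) > 0.4 * max(env))
  expect_true(sum(pulses$values) %in% c(8, 9))
  expect_equal(o$truth$gt_pr, 1.70)

  # AM rumble: envelope-FFT oracle finds the modulation rate
  am <- synthesis_spec("rumble", "pulsative", dur_mean = 2, pr_mean = 16.31,
                       pr_mode = "am", spectral_band = c(100, 600))
  oa <- synth_pulsative_call(am, seed = 7)
  e <- envelope(oa$wave)
  expect_equal(fft_peak_freq(as.numeric(e) - mean(e), 22050), 16.31,
               tolerance = 0.8)

  expect_error(synthesis_spec("p", "pulsative", dur_mean = 1, pr_mean = 0))
  expect_error(synth_pulsative_call(
    synthesis_spec("p", "pulsative", dur_mean = 0.3, pr_mean = 1.7,
                   min_dur = 0.29), seed = 1), "fewer than 2")
})

test_that("soundscape mixing is labelled, band-limited and deterministic", {
  quiet <- soundscape_mix(gains = c(shrimp = -Inf, boat = -Inf, flow = -Inf))
  s0 <- synth_soundscape(quiet, duration = 2, seed = 1, rate = 11025)
  expect_equal(max(abs(as.numeric(s0$wave))), 0)
  expect_equal(nrow(s0$labels), 0)

  # shrimp only: >95% of power inside 1.5-5.5 kHz (Parseval oracle)
  shr <- soundscape_mix(gains = c(shrimp = -20, boat = -Inf, flow = -Inf))
  s1 <- synth_soundscape(shr, duration = 5, seed = 2, rate = 22050)
  expect_gt(band_power_fraction(as.numeric(s1$wave), 22050, 1500, 5500), 0.95)

  # call count conservation and placement validation
  mix <- soundscape_mix(gains = c(shrimp = -30, boat = -32, flow = -40))
  spec <- synthesis_spec("whoo", "harmonic", dur_mean = 0.2, f0_mean = 439,
                         n_harmonics = 1L)
  calls <- lapply(seq(0.5, 5, length.out = 10),
                  function(t) list(time = t, spec = spec))
  s2 <- synth_soundscape(mix, calls, duration = 8, seed = 3, rate = 11025)
  expect_equal(sum(s2$labels$label == "whoo"), 10)
  expect_equal(nrow(s2$truth), 10)
  expect_error(synth_soundscape(mix, list(list(time = 9, spec = spec)),
                                duration = 8, seed = 3), "beyond")

  # same seed -> byte-identical WAV
  f1 <- withr::local_tempfile(fileext = ".wav")
  f2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(synth_soundscape(mix, calls, duration = 8, seed = 9,
                             rate = 11025)$wave, f1)
  write_wav(synth_soundscape(mix, calls, duration = 8, seed = 9,
                             rate = 11025)$wave, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("sampled feature tables mirror the published marginals", {
  tab <- sample_feature_table("harmonic", seed = 11)
  expect_equal(nrow(tab), 739)              # published harmonic sample sizes
  expect_equal(length(unique(tab$type)), 11)
  expect_false(anyNA(tab[, c("dur", "f0", "Fmax", "Q25", "Q50", "Q75")]))

  # large-n sample means within 3 SE of the published means
  big <- sample_feature_table("noisy", n_per_type = c(hiccup = 4000), seed = 12)
  p <- repertoire_params()
  pp <- p[p$name == "hiccup", ]
  for (v in c("dur", "Fmax", "Q25", "Q50", "Q75")) {
    col <- c(dur = "dur_mean", Fmax = "fmax_mean", Q25 = "q25_mean",
             Q50 = "q50_mean", Q75 = "q75_mean")[[v]]
    sdc <- sub("mean", "sd", col)
    expect_lt(abs(mean(big[[v]]) - pp[[col]]), 3 * pp[[sdc]] / sqrt(4000) +
                0.02 * pp[[col]])  # truncation at zero shifts means slightly
  }
  expect_error(sample_feature_table("noisy", n_per_type = c(bark = 5)), "unknown")
})

test_that("synthesized call ground truth is recovered by independent oracles", {
  # property over random seeds: FFT/envelope/cumsum oracles agree with the
  # recorded ground truth
  for (seed in 1:6) {
    o <- synth_harmonic_call(synthesis_spec("s", "harmonic", dur_mean = 0.4,
                                            f0_mean = 300 + 50 * seed,
                                            n_harmonics = 1L),
                             seed = seed, rate = 11025)
    expect_equal(fft_peak_freq(as.numeric(o$wave), 11025), o$truth$gt_f0,
                 tolerance = 0.01 * o$truth$gt_f0)

    op <- synth_pulsative_call(synthesis_spec("p", "pulsative", dur_mean = 2,
                                              pr_mean = 5 + seed, pr_mode = "am",
                                              spectral_band = c(100, 800)),
                               seed = seed, rate = 11025)
    e <- envelope(op$wave)
    expect_equal(fft_peak_freq(as.numeric(e) - mean(e), 11025), op$truth$gt_pr,
                 tolerance = 0.06 * op$truth$gt_pr)
  }
})
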