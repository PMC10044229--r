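test_that("spectrogram puts a stationary tone in the right bin, any settings", {
  seg <- tone_segment(500, dur = 1, rate = 11025)
  for (cfg in list(list(fft = 1024L, ov = 0.75), list(fft = 512L, ov = 0.90))) {
    sg <- spectrogram(seg, fft_size = cfg$fft, overlap = cfg$ov)
    ridge <- sg$freq[apply(sg$power, 1, which.max)]
    expect_true(all(abs(ridge - 500) <= sg$freq_step))
    expect_equal(sg$time_step, round(cfg$fft * (1 - cfg$ov)) / 11025)
  }
  # finer time step for the 512/90% variant
  expect_lt(spectrogram(seg, 512L, 0.90)$time_step,
            spectrogram(seg, 1024L, 0.75)$time_step)
})

test_that("spectrogram power is calibrated and flat for white noise", {
  # full-scale bin-centered sine reads mean-square power 0.5 regardless
  # of fft size (scalloping would bite an off-bin tone)
  f0 <- 24 * 11025 / 256
  seg <- tone_segment(f0, dur = 1, rate = 11025)
  for (nfft in c(256L, 1024L)) {
    sg <- spectrogram(seg, fft_size = nfft)
    i <- which.min(abs(sg$freq - f0))
    expect_equal(unname(colMeans(sg$power)[i]), 0.5, tolerance = 0.01)
  }
  set.seed(3)
  wn <- audio_segment(stats::rnorm(11025 * 4), rate = 11025)
  sg <- spectrogram(wn)
  pbar <- colMeans(sg$power)
  mid <- pbar[sg$freq > 500 & sg$freq < 5000]
  expect_lt(stats::sd(mid) / mean(mid), 0.25)   # chi-square flatness
})

test_that("average spectrum respects band limits and Parseval", {
  seg <- tone_segment(300, dur = 0.8, rate = 11025)
  avg <- average_spectrum(seg, band = c(20, 1000))
  expect_false(avg$silent)
  expect_equal(avg$freq[which.max(avg$power)], 300, tolerance = 11)
  # out-of-band tone is rejected and flagged silent
  hi <- tone_segment(1500, dur = 0.8, rate = 11025)
  avg_hi <- average_spectrum(hi, band = c(20, 1000))
  expect_true(avg_hi$silent)
  expect_error(average_spectrum(seg, band = c(500, 100)), "inverted")

  # in-band power fraction matches a direct FFT oracle on a broadband call
  set.seed(4)
  o <- synth_noisy_call(type_spec("growl"), seed = 10, rate = 11025)
  avg_g <- average_spectrum(o$wave, band = c(20, 3000))
  frac_pkg <- sum(avg_g$power) / sum(average_spectrum(o$wave, band = c(1, 5512.5))$power)
  frac_fft <- band_power_fraction(as.numeric(o$wave), 11025, 20, 3000)
  expect_equal(frac_pkg, frac_fft, tolerance = 0.02)
})

test_that("envelope follows amplitude structure", {
  seg <- tone_segment(400, dur = 0.5, rate = 11025)
  env <- envelope(seg)
  core <- env[1000:4500]
  expect_lt((max(core) - min(core)) / mean(core), 0.1)   # flat for a tone

  # 5-pulse train -> 5 envelope peaks above half max
  rate <- 11025
  x <- numeric(rate)
  for (k in 0:4) {
    i <- k * 2000 + 500
    x[i:(i + 200)] <- sin(2 * pi * 500 * seq(0, 200) / rate)
  }
  env5 <- envelope(audio_segment(x, rate))
  above <- rle(env5 > 0.5 * max(env5))
  expect_equal(sum(above$values), 5)

  # AM carrier -> envelope spectrum peak at the modulation rate
  t <- seq(0, 2, by = 1 / rate)[-1]
  am <- audio_segment((1 + 0.8 * cos(2 * pi * 16 * t)) * sin(2 * pi * 800 * t), rate)
  e <- envelope(am)
  expect_equal(fft_peak_freq(e - mean(e), rate), 16, tolerance = 0.6)
  expect_error(envelope(seg, smoothing = 1), "shorter")
})

test_that("merge_and_resample conserves duration and content", {
  set.seed(5)
  a <- audio_segment(stats::rnorm(22050), 22050)
  b <- audio_segment(stats::rnorm(22050 * 2), 22050)
  out <- merge_and_resample(list(a, b), target_rate = 11025)
  expect_equal(attr(out, "rate"), 11025)
  expect_equal(length(out), 11025 * 3, tolerance = 1)

  # identity pass-through
  same <- merge_and_resample(list(a), target_rate = 22050)
  expect_identical(as.numeric(same), as.numeric(a))

  # a 4 kHz tone survives downsampling to 11025 Hz
  tn <- tone_segment(4000, dur = 1, rate = 22050)
  dn <- merge_and_resample(list(tn), target_rate = 11025)
  expect_equal(fft_peak_freq(as.numeric(dn), 11025), 4000, tolerance = 2)

  expect_warning(merge_and_resample(list(a), target_rate = 44100), "upsampling")
  expect_error(merge_and_resample(list(a, audio_segment(1:5, 8000))), "share")
})

test_that("spectrogram energy is consistent under frame-quantized time shifts", {
  set.seed(6)
  x <- stats::rnorm(8192)
  rate <- 8000
  sg1 <- spectrogram(audio_segment(x, rate), fft_size = 256L, overlap = 0.5)
  hop <- 128L
  sg2 <- spectrogram(audio_segment(c(numeric(hop * 2), x), rate),
                     fft_size = 256L, overlap = 0.5)
  n <- nrow(sg1$power)
  expect_equal(sg2$power[3:(n + 2), ], sg1$power, tolerance = 1e-10)
})
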