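cal_ref <- hydrophone_cal(sensitivity = -168.5)

test_that("calibration follows the sensitivity definition", {
  # 1 V-rms sine at -168.5 dB re V/uPa -> 168.5 dB re 1 uPa
  rate <- 11025
  seg <- tone_segment(250, dur = 1, rate = rate, amp = sqrt(2))  # 1 V rms
  p <- calibrate(seg, cal_ref)
  spl <- 20 * log10(sqrt(mean(as.numeric(p)^2)))
  expect_equal(spl, 168.5, tolerance = 0.01)

  # +20 dB gain implies 20 dB less pressure for the same voltage
  p_gain <- calibrate(seg, hydrophone_cal(-168.5, gain = 20))
  expect_equal(20 * log10(sqrt(mean(as.numeric(p_gain)^2))), 148.5,
               tolerance = 0.01)

  # round trip pressure -> volts -> pressure
  inv <- as.numeric(p) * 10^((cal_ref$sensitivity) / 20)
  expect_equal(inv, as.numeric(seg), tolerance = 1e-9)

  expect_error(calibrate(seg, NULL), "no calibration")
  expect_error(hydrophone_cal(12), "negative")
})

test_that("LTSA is constant for a stationary tone and averages consistently", {
  rate <- 11025
  seg <- tone_segment(500, dur = 30, rate = rate)
  lt <- ltsa(seg, time_bin = 5, freq_bin = 10)
  row <- which.min(abs(lt$freq - 500))
  expect_lt(max(lt$db[, row]) - min(lt$db[, row]), 0.2)

  # mean over LTSA time bins equals the whole-file average spectrum
  set.seed(31)
  wn <- audio_segment(stats::rnorm(rate * 30), rate)
  lt2 <- ltsa(wn, time_bin = 5, freq_bin = 10)
  whole <- ltsa(wn, time_bin = 30, freq_bin = 10)
  recombined <- 10 * log10(colMeans(lt2$power))
  expect_lt(max(abs(recombined - whole$db[1, ])), 0.1)

  expect_error(ltsa(tone_segment(100, dur = 2, rate = rate), time_bin = 5), "span")
})

test_that("PSD percentiles match closed-form white noise and mixtures", {
  rate <- 11025
  set.seed(32)
  sigma <- 2000                               # uPa, pretend-calibrated
  wn <- audio_segment(stats::rnorm(rate * 30, sd = sigma), rate)
  psd <- psd_percentiles(wn)
  # flat one-sided density; per-window periodogram bins are ~chi^2_2, so
  # the median sits ln(2) below the mean density
  analytic <- 10 * log10(sigma^2 / (rate / 2)) + 10 * log10(log(2))
  mid <- psd$freq > 200 & psd$freq < 5000
  expect_lt(abs(stats::median(psd$db["P50", mid]) - analytic), 1)
  # pointwise percentile ordering
  expect_true(all(diff(psd$db[, mid]) >= -1e-9))

  # identical windows -> curves coincide
  one_sec <- stats::rnorm(rate)
  rep_seg <- audio_segment(rep(one_sec, 12), rate)
  psd_rep <- psd_percentiles(rep_seg, window = 1, overlap = 0)
  expect_lt(max(psd_rep$db["P90", ] - psd_rep$db["P10", ]), 1e-6)

  # a tone present in ~20% of windows shows in P90, not in P50
  x <- stats::rnorm(rate * 30, sd = 100)
  tone_idx <- seq_len(rate * 6)
  x[tone_idx] <- x[tone_idx] + 2000 * sin(2 * pi * 1000 * seq_along(tone_idx) / rate)
  psd_mix <- psd_percentiles(audio_segment(x, rate), overlap = 0)
  bin <- which.min(abs(psd_mix$freq - 1000))
  bg <- stats::median(psd_mix$db["P50", psd_mix$freq > 800 & psd_mix$freq < 1200])
  expect_gt(psd_mix$db["P90", bin] - bg, 10)
  expect_lt(psd_mix$db["P50", bin] - bg, 3)

  expect_error(psd_percentiles(tone_segment(100, dur = 2, rate = rate)),
               "at least 10")
})

test_that("band levels integrate correctly and add up", {
  rate <- 11025
  # calibrated sine at 125 Hz, SPL 120 dB -> OL125 reads 120 dB, OL2000 floor
  amp <- sqrt(2) * 10^(120 / 20)
  seg <- audio_segment(amp * sin(2 * pi * 125 * seq_len(rate * 10) / rate), rate)
  bl <- band_levels(seg, time_bin = 5)
  expect_equal(mean(bl$OL125), 120, tolerance = 0.1)
  expect_lt(mean(bl$OL2000), 60)
  expect_true(all(bl$BB >= bl$OL125 - 1e-9))

  # BB equals the power sum of disjoint covering bands within 0.1 dB
  set.seed(33)
  wn <- audio_segment(stats::rnorm(rate * 12, sd = 500), rate)
  edges <- c(20, 100, 500, 1500, 3000, 5500)
  parts <- lapply(seq_len(5), function(i) c(edges[i], edges[i + 1]))
  names(parts) <- paste0("b", 1:5)
  bl2 <- band_levels(wn, bands = c(list(BB = c(20, 5500)), parts), time_bin = 4)
  summed <- 10 * log10(rowSums(10^(as.matrix(bl2[paste0("b", 1:5)]) / 10)))
  expect_lt(max(abs(summed - bl2$BB)), 0.1)

  expect_error(band_levels(wn, bands = list(x = c(100, 9000))), "Nyquist")
})

test_that("levels are linear in input gain", {
  rate <- 11025
  set.seed(34)
  x <- stats::rnorm(rate * 12, sd = 200)
  g <- 3.7
  bl1 <- band_levels(audio_segment(x, rate), time_bin = 4)
  bl2 <- band_levels(audio_segment(g * x, rate), time_bin = 4)
  for (col in c("BB", "OL125", "OL500", "OL2000")) {
    expect_equal(bl2[[col]] - bl1[[col]],
                 rep(20 * log10(g), nrow(bl1)), tolerance = 1e-8)
  }
})

test_that("a shrimp-dominated mix puts the 2 kHz octave above the 125 Hz octave", {
  mix <- soundscape_mix(gains = c(shrimp = -20, boat = -40, flow = -45))
  s <- synth_soundscape(mix, duration = 20, seed = 35, rate = 11025)
  bl <- band_levels(s$wave, time_bin = 5)
  expect_true(all(bl$OL2000 > bl$OL125))
})
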