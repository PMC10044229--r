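test_that("duration is read between envelope threshold crossings", {
  rate <- 11025
  x <- numeric(rate)                         # 1 s window
  burst <- round(0.25 * rate):round(0.75 * rate)
  x[burst] <- sin(2 * pi * 440 * burst / rate)
  expect_equal(measure_duration(audio_segment(x, rate)), 0.5, tolerance = 0.02)
  expect_error(measure_duration(audio_segment(numeric(1000), rate)), "silent")

  # clap-like series duration spans the whole series
  o <- synth_pulsative_call(synthesis_spec("clap", "pulsative", dur_mean = 5.103,
                                           pr_mean = 1.7,
                                           spectral_band = c(100, 1000)),
                            seed = 1, rate = 11025)
  expect_equal(measure_duration(o$wave), o$truth$gt_dur, tolerance = 0.05 * 5.103)
})

test_that("f0 estimation recovers harmonic stacks and rejects noise", {
  o <- synth_harmonic_call(synthesis_spec("bark", "harmonic", dur_mean = 0.418,
                                          f0_mean = 137, excF_mean = 45,
                                          n_harmonics = 4L, fmax_mean = 312),
                           seed = 2, rate = 11025)
  expect_equal(estimate_f0(o$wave, band = c(20, 1000), search = c(40, 400)),
               137, tolerance = 0.03 * 137)

  tone <- tone_segment(1207, dur = 0.4, rate = 11025)
  expect_equal(estimate_f0(tone, band = c(20, 2000), search = c(500, 2000)),
               1207, tolerance = 0.03 * 1207)

  set.seed(3)
  wn <- audio_segment(stats::rnorm(11025), 11025)
  expect_error(estimate_f0(wn), "undefined f0")
})

test_that("frequency excursion measures the contour span", {
  tone <- tone_segment(250, dur = 0.5, rate = 11025)
  expect_lt(excursion_frequency(tone, 250), 12)   # unmodulated: ~0 Hz

  o <- synth_harmonic_call(synthesis_spec("b", "harmonic", dur_mean = 0.45,
                                          f0_mean = 137, excF_mean = 45,
                                          n_harmonics = 3L, fmax_mean = 137),
                           seed = 4, rate = 11025)
  expect_equal(excursion_frequency(o$wave, 137), 45, tolerance = 12)

  # monotone chirp 100 -> 180 Hz: analytic excursion 80 Hz
  rate <- 11025
  t <- seq(0, 0.6, by = 1 / rate)[-1]
  f_inst <- 100 + (180 - 100) * t / 0.6
  chirp <- audio_segment(sin(2 * pi * cumsum(f_inst) / rate), rate)
  expect_equal(excursion_frequency(chirp, 140), 80, tolerance = 12)

  expect_error(excursion_frequency(tone_segment(250, dur = 0.001, rate = 11025), 250),
               "track|short")
})

test_that("peak and quartiles follow the cumulative-energy definition", {
  # flat spectrum over [0, 1000]: quartiles at 250/500/750
  flat <- synth_noisy_call(synthesis_spec("n", "noisy", dur_mean = 1.5,
                                          spectral_band = c(1, 1000)),
                           seed = 5, rate = 11025)
  avg <- average_spectrum(flat$wave, band = c(1, 1100))
  pq <- peak_and_quartiles(avg)
  expect_equal(unname(pq[c("Q25", "Q50", "Q75")]), c(250, 500, 750),
               tolerance = 40)

  # all energy in one bin: quartiles collapse onto Fmax
  tone <- tone_segment(300, dur = 0.5, rate = 11025)
  pq1 <- peak_and_quartiles(average_spectrum(tone, band = c(20, 1000)))
  expect_equal(unname(pq1), rep(300, 4), tolerance = 11)

  # brute-force cumulative-sum oracle agreement, bin-exact
  set.seed(6)
  o <- synth_noisy_call(type_spec("hiccup"), seed = 6, rate = 11025)
  avg2 <- average_spectrum(o$wave, band = c(20, 1000))
  pq2 <- peak_and_quartiles(avg2)
  cs <- cumsum(avg2$power) / sum(avg2$power)
  expect_equal(unname(pq2["Q25"]), avg2$freq[which(cs >= 0.25)[1]])
  expect_equal(unname(pq2["Q50"]), avg2$freq[which(cs >= 0.50)[1]])
  expect_equal(unname(pq2["Q75"]), avg2$freq[which(cs >= 0.75)[1]])

  expect_error(peak_and_quartiles(avg2, band = c(2000, 3000)), "zero in-band")
})

test_that("pulse rate matches both reading modes", {
  o <- synth_pulsative_call(synthesis_spec("clap", "pulsative", dur_mean = 5.103,
                                           pr_mean = 1.70,
                                           spectral_band = c(100, 1000)),
                            seed = 7, rate = 11025)
  expect_equal(pulse_rate(o$wave, "discrete"), 1.70, tolerance = 0.05 * 1.70)

  oa <- synth_pulsative_call(synthesis_spec("rumble", "pulsative", dur_mean = 1.062,
                                            pr_mean = 16.31, pr_mode = "am",
                                            spectral_band = c(100, 800)),
                             seed = 8, rate = 11025)
  expect_equal(pulse_rate(oa$wave, "am"), 16.31, tolerance = 0.05 * 16.31)

  # single impulse: no rate
  x <- numeric(11025)
  x[5000] <- 1
  expect_error(pulse_rate(audio_segment(x, 11025), "discrete"), "fewer than 2")
})

test_that("pulse rate equals a manual envelope peak count on random trains", {
  for (seed in 1:8) {
    set.seed(seed)
    pr <- stats::runif(1, 2, 10)
    o <- synth_pulsative_call(synthesis_spec("p", "pulsative", dur_mean = 2.5,
                                             pr_mean = pr,
                                             spectral_band = c(100, 1000)),
                              seed = seed, rate = 11025)
    env <- envelope(o$wave)
    r <- rle(as.numeric(env) > 0.4 * max(env))
    n_manual <- sum(r$values)                 # manual oscillogram count
    expect_equal(n_manual,
                 round((o$truth$gt_dur - 0.008) * o$truth$gt_pr) + 1L)
    expect_equal(pulse_rate(o$wave, "discrete"), pr, tolerance = 0.05 * pr)
  }
})

test_that("extraction dispatches per category and enforces gates", {
  # bark: 7 variables populated, PR absent
  ob <- synth_harmonic_call(type_spec("bark"), seed = 9, rate = 11025)
  fv <- extract_features(ob$wave, "bark")
  expect_false(anyNA(fv[c("dur", "f0", "excF", "Fmax", "Q25", "Q50", "Q75")]))
  expect_true(is.na(fv["PR"]))
  expect_true(all(attr(fv, "mask")[c("dur", "f0", "excF")]))

  # clap: dur and PR only
  oc <- synth_pulsative_call(type_spec("clap"), seed = 10, rate = 11025)
  fc <- extract_features(oc$wave, "clap")
  expect_false(anyNA(fc[c("dur", "PR")]))
  expect_true(all(is.na(fc[c("f0", "Fmax", "Q25", "Q50", "Q75")])))

  # quality and measurability gates
  expect_error(extract_features(ob$wave, "bark", quality = "degraded"), "quality")
  expect_error(extract_features(ob$wave, "moan"), "not measurable")

  # single-band type: quartiles computed internally but masked for reports
  os <- synth_harmonic_call(type_spec("whoo"), seed = 11, rate = 11025)
  fs <- extract_features(os$wave, "whoo")
  expect_false(anyNA(fs[c("Q25", "Q50", "Q75")]))
  expect_false(any(attr(fs, "mask")[c("Q25", "Q50", "Q75")]))
})

test_that("quartile ordering holds on every successful extraction", {
  types <- c("bark", "growl", "hiccup", "squeak", "gloo", "rumble")
  for (seed in seq_along(types)) {
    o <- synth_call(type_spec(types[seed]), seed = 100 + seed, rate = 11025)
    fv <- extract_features(o$wave, types[seed])
    q <- fv[c("Q25", "Q50", "Q75")]
    if (!anyNA(q)) {
      expect_true(q[1] <= q[2] && q[2] <= q[3])
    }
    if (!is.na(fv["dur"])) expect_gt(fv[["dur"]], 0)
  }
})
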