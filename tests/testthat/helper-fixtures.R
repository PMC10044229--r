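# Reference out-of-bag confusion matrices from the field study the
# synthetic world mirrors (11 harmonic, 3 noisy, 3 pulsative call types).
reference_confusion <- function(category) {
  path <- system.file("extdata", paste0("confusion_", category, ".csv"),
                      package = "sealscape")
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$type
  storage.mode(m) <- "integer"
  m
}

# a clean unit-amplitude tone segment
tone_segment <- function(freq, dur = 1, rate = 11025, amp = 1) {
  t <- seq(0, dur, by = 1 / rate)[-1]
  audio_segment(amp * sin(2 * pi * freq * t), rate = rate)
}

# band power fraction by direct FFT (Parseval oracle, independent of the
# package's spectral code path)
band_power_fraction <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x)[seq_len(n %/% 2 + 1)])^2
  f <- (seq_len(n %/% 2 + 1) - 1) * rate / n
  sum(p[f >= lo & f <= hi]) / sum(p)
}

# dominant frequency by FFT argmax (peak-pick oracle)
fft_peak_freq <- function(x, rate) {
  n <- length(x)
  p <- Mod(stats::fft(x)[seq_len(n %/% 2 + 1)])^2
  (which.max(p) - 1) * rate / n
}
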