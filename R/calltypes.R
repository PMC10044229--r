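#' Call-type registry
#'
#' The 18-type underwater monk-seal repertoire: 12 harmonic, 3 noisy and 3
#' pulsative call types. Each type carries its analysis band, a
#' measurability flag (moans are too faint to be measured) and the
#' availability mask saying which of the variables
#' dur/f0/excF/Fmax/Q25/Q50/Q75/PR are reported for it.
#'
#' Band-limit rules: spectral analysis runs 20 Hz–1 kHz by default (snapping
#' shrimp dominate higher frequencies); growls and knocks carry energy above
#' 1 kHz and are analysed to 3 kHz; high-pitched screams to 2 kHz. For
#' harmonic types showing only one or two frequency bands (scream, whine,
#' whoo) energy quartiles are not reported.
#'
#' @return data.frame, one row per call type
#' @export
call_type_registry <- function() {
  ct <- function(name, category, band_hi, measurable, f0, excF, Q, PR,
                 Fmax = TRUE) {
    data.frame(name = name, category = category,
               band_lo = 20, band_hi = band_hi, measurable = measurable,
               m_dur = measurable, m_f0 = f0, m_excF = excF, m_Fmax = Fmax & measurable,
               m_Q25 = Q, m_Q50 = Q, m_Q75 = Q, m_PR = PR,
               pr_mode = if (!PR) NA_character_ else
                 if (name == "rumble") "am" else "discrete",
               stringsAsFactors = FALSE)
  }
  rbind(
    ct("bark",     "harmonic", 1000, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    ct("croak",    "harmonic", 1000, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    ct("cry",      "harmonic", 1000, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    ct("gloo",     "harmonic", 1000, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    ct("gloogloo", "harmonic", 1000, TRUE,  TRUE,  FALSE, TRUE,  FALSE),
    ct("groan",    "harmonic", 1000, TRUE,  TRUE,  FALSE, TRUE,  FALSE),
    ct("moan",     "harmonic", 1000, FALSE, FALSE, FALSE, FALSE, FALSE, Fmax = FALSE),
    ct("scream",   "harmonic", 2000, TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    ct("whine",    "harmonic", 1000, TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    ct("whoo",     "harmonic", 1000, TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    ct("wop",      "harmonic", 1000, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    ct("wom",      "harmonic", 1000, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    ct("growl",    "noisy",    3000, TRUE,  FALSE, FALSE, TRUE,  FALSE),
    ct("hiccup",   "noisy",    1000, TRUE,  FALSE, FALSE, TRUE,  FALSE),
    ct("squeak",   "noisy",    1000, TRUE,  FALSE, FALSE, TRUE,  FALSE),
    ct("clap",     "pulsative", 1000, TRUE, FALSE, FALSE, FALSE, TRUE, Fmax = FALSE),
    ct("knock",    "pulsative", 3000, TRUE, FALSE, FALSE, FALSE, TRUE),
    ct("rumble",   "pulsative", 1000, TRUE, FALSE, FALSE, TRUE,  TRUE)
  )
}

#' Look up one call type
#'
#' @param name call-type name (see [call_type_registry()])
#' @return single-row data.frame from the registry
#' @export
call_type <- function(name) {
  reg <- call_type_registry()
  i <- match(tolower(name), reg$name)
  if (is.na(i)) stop("unknown call type: ", name)
  reg[i, , drop = FALSE]
}

#' Repertoire feature statistics
#'
#' Published per-type means and standard deviations of the measured
#' acoustic variables (duration s; f0, excF, Fmax, Q25/Q50/Q75 Hz; pulse
#' rate pulses/s) together with the per-type sample sizes. These marginals
#' parameterize the synthetic-call generator and the feature-table sampler;
#' `NA` marks variables not reported for a type.
#'
#' @return data.frame, one row per measured call type (moans excluded)
#' @export
repertoire_params <- function() {
  h <- function(name, n, dm, ds, f0m, f0s, exm, exs, fmm, fms,
                q25m = NA, q25s = NA, q50m = NA, q50s = NA, q75m = NA, q75s = NA) {
    data.frame(name = name, category = "harmonic", n = n,
               dur_mean = dm, dur_sd = ds, f0_mean = f0m, f0_sd = f0s,
               excF_mean = exm, excF_sd = exs, fmax_mean = fmm, fmax_sd = fms,
               q25_mean = q25m, q25_sd = q25s, q50_mean = q50m, q50_sd = q50s,
               q75_mean = q75m, q75_sd = q75s, pr_mean = NA_real_, pr_sd = NA_real_,
               stringsAsFactors = FALSE)
  }
  nz <- function(name, n, dm, ds, fmm, fms, q25m, q25s, q50m, q50s, q75m, q75s) {
    data.frame(name = name, category = "noisy", n = n,
               dur_mean = dm, dur_sd = ds, f0_mean = NA_real_, f0_sd = NA_real_,
               excF_mean = NA_real_, excF_sd = NA_real_, fmax_mean = fmm, fmax_sd = fms,
               q25_mean = q25m, q25_sd = q25s, q50_mean = q50m, q50_sd = q50s,
               q75_mean = q75m, q75_sd = q75s, pr_mean = NA_real_, pr_sd = NA_real_,
               stringsAsFactors = FALSE)
  }
  pl <- function(name, n, dm, ds, fmm, fms, q25m, q25s, q50m, q50s, q75m, q75s,
                 prm, prs) {
    data.frame(name = name, category = "pulsative", n = n,
               dur_mean = dm, dur_sd = ds, f0_mean = NA_real_, f0_sd = NA_real_,
               excF_mean = NA_real_, excF_sd = NA_real_, fmax_mean = fmm, fmax_sd = fms,
               q25_mean = q25m, q25_sd = q25s, q50_mean = q50m, q50_sd = q50s,
               q75_mean = q75m, q75_sd = q75s, pr_mean = prm, pr_sd = prs,
               stringsAsFactors = FALSE)
  }
  rbind(
    h("bark",     294, 0.418, 0.262, 137,  37, 45, 27, 312, 190, 275, 83, 450, 134, 687, 148),
    h("croak",     32, 0.460, 0.147,  96,  40, 43, 29, 282, 146, 238, 86, 366, 162, 622, 406),
    h("cry",       24, 1.386, 1.074, 290, 150, 95, 77, 360, 170, 272, 106, 433, 118, 699, 129),
    h("gloo",      76, 0.350, 0.359, 112,  29, 74, 43, 147,  79, 153, 53, 283, 109, 490, 147),
    h("gloogloo",  39, 0.555, 0.562, 116,  28, NA, NA, 193,  80, 171, 37, 288,  61, 503, 119),
    h("groan",     78, 0.500, 0.247,  79,  36, NA, NA, 174,  87, 178, 58, 287,  82, 507, 289),
    h("scream",    19, 0.408, 0.277, 1207, 444, 150, 111, 1207, 444),
    h("whine",     47, 0.663, 0.313, 134,  45, 51, 30, 143,  41),
    h("whoo",      65, 0.207, 0.068, 439, 154, 73, 48, 461, 190),
    h("wop",       23, 0.229, 0.069, 297,  70, 68, 30, 406, 145, 316, 59, 486, 110, 699, 94),
    h("wom",       42, 0.303, 0.100,  95,  30, 54, 33, 100,  44, 117, 39, 288, 157, 632, 191),
    nz("growl",   442, 1.136, 0.616, 648, 412, 542, 249, 920, 388, 1399, 662),
    nz("hiccup",  210, 0.177, 0.042, 395, 109, 353,  82, 422,  99,  567, 120),
    nz("squeak",   43, 0.155, 0.081, 557, 147, 422,  92, 556,  92,  690, 105),
    pl("clap",     13, 5.103, 1.619, NA, NA, NA, NA, NA, NA, NA, NA, 1.70, 0.16),
    pl("knock",   226, 1.922, 1.828, 699, 441, NA, NA, NA, NA, NA, NA, 6.81, 1.43),
    pl("rumble",   23, 1.062, 0.434, 205,  65, 215, 50, 347, 97, 571, 142, 16.31, 3.5)
  )
}

# number of synthesized harmonics per type: enough to cover the upper
# energy quartile; single/double-band types get 1-2 bands
default_n_harmonics <- function(p) {
  if (p$name %in% c("scream", "whoo")) return(1L)
  if (p$name == "whine") return(2L)
  if (is.na(p$q75_mean)) return(4L)
  max(3L, min(12L, ceiling((p$q75_mean + p$q75_sd) / p$f0_mean)))
}
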