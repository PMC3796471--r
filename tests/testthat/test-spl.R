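# build a bare recording with labelled segments for direct SPL tests
mk_recording <- function(segs, sr = 22050, gap = 0.1) {
  gap_n <- round(gap * sr)
  samples <- numeric(0)
  rows <- list()
  for (nm in names(segs)) {
    s <- segs[[nm]]
    rows[[nm]] <- data.frame(label = nm, onset_s = length(samples) / sr,
                             duration_s = length(s$x) / sr, kind = s$kind,
                             frequency = s$frequency %||% NA_real_,
                             species = NA_character_,
                             stringsAsFactors = FALSE)
    samples <- c(samples, s$x, numeric(gap_n))
  }
  list(wave = waveform(samples, sr), schedule = do.call(rbind, rows))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

sine <- function(amp, f = 1000, dur = 1, sr = 22050)
  amp * sin(2 * pi * f * (seq_len(dur * sr) - 1) / sr)

test_that("calibration maps digital RMS to the reference SPL", {
  # digital RMS 1.0 (amplitude sqrt(2)) -> offset exactly 94
  rec <- mk_recording(list(
    cal = list(x = sine(sqrt(2)), kind = "calibration", frequency = 1000)))
  cal <- calibrate_recording(rec$wave, rec$schedule)
  expect_equal(cal$offset, 94, tolerance = 1e-3)
  expect_equal(cal$cal_segments_used, 1)
  expect_true(is.na(cal$drift))
})

test_that("two calibration tones average in dB and report drift", {
  rec <- mk_recording(list(
    cal_start = list(x = sine(sqrt(2)), kind = "calibration"),
    cal_end = list(x = sine(sqrt(2) * 10^(-0.4 / 20)), kind = "calibration")))
  cal <- calibrate_recording(rec$wave, rec$schedule)
  expect_equal(cal$offset, 94.2, tolerance = 1e-3)
  expect_equal(cal$drift, 0.4, tolerance = 1e-3)
  expect_false(cal$drift_warning)
  rec2 <- mk_recording(list(
    cal_start = list(x = sine(sqrt(2)), kind = "calibration"),
    cal_end = list(x = sine(sqrt(2) * 10^(-2 / 20)), kind = "calibration")))
  expect_warning(calibrate_recording(rec2$wave, rec2$schedule), "drift")
  expect_error(calibrate_recording(rec$wave,
                                   rec$schedule[0, , drop = FALSE]),
               "no calibration")
})

test_that("a full-scale sine measures 90.99 dB RMS under a 94-dB reference", {
  rec <- mk_recording(list(
    cal = list(x = sine(sqrt(2) / 32767 * 32767), kind = "calibration"),
    tone = list(x = sine(1), kind = "tone", frequency = 1000)))
  # force offset = 94 exactly via an explicit calibration object
  cal <- structure(list(offset = 94, cal_segments_used = 1, drift = NA,
                        drift_warning = FALSE), class = "calibration")
  m <- measure_spl(rec$wave, rec$schedule, cal, "tone", noise_label = NA)
  expect_equal(m$spl_rms, 20 * log10(1 / sqrt(2)) + 94, tolerance = 0.01)
  expect_equal(m$spl_rms, 90.99, tolerance = 0.01)
  # sine crest factor: peak - rms = 3.01 dB
  expect_equal(m$spl_peak - m$spl_rms, 3.01, tolerance = 0.01)
  expect_gte(m$spl_peak, m$spl_rms)
})

test_that("silent and clipped segments are flagged invalid", {
  set.seed(1)
  rec <- mk_recording(list(
    cal = list(x = sine(sqrt(2) / 2), kind = "calibration"),
    quiet = list(x = numeric(22050) + 1e-7 * rnorm(22050), kind = "tone",
                 frequency = 1000),
    clipped = list(x = pmin(1, pmax(-1, sine(3))), kind = "tone",
                   frequency = 1000),
    background = list(x = 0.01 * rnorm(22050), kind = "noise_floor")))
  cal <- calibrate_recording(rec$wave, rec$schedule)
  q <- measure_spl(rec$wave, rec$schedule, cal, "quiet")
  expect_lte(q$snr, 0)
  expect_false(q$valid)
  cl <- measure_spl(rec$wave, rec$schedule, cal, "clipped")
  expect_true(cl$clipped)
  expect_false(cl$valid)
})

test_that("flat gain shifts SPL unless calibration is re-run", {
  pbs <- tiny_playback()
  sc <- propagation_scenario("g", "water", 0, noise_spl = -Inf,
                             gain_steps = c("1" = 0), seed = 3)
  tr <- simulate_transect(pbs, sc, distances = c(0.5, 1), cal_duration = 1,
                          background_duration = 16)
  rec <- tr$recordings[["1"]]
  cal <- calibrate_recording(rec$wave, rec$schedule)
  g <- 5
  boosted <- waveform(rec$wave$samples * 10^(g / 20), rec$wave$sample_rate)
  m0 <- measure_spl(rec$wave, rec$schedule, cal, "tone_800",
                    noise_label = NA)
  m1 <- measure_spl(boosted, rec$schedule, cal, "tone_800", noise_label = NA)
  expect_equal(m1$spl_rms - m0$spl_rms, g, tolerance = 1e-6)
  expect_equal(m1$spl_peak - m0$spl_peak, g, tolerance = 1e-6)
  cal2 <- calibrate_recording(boosted, rec$schedule)
  m2 <- measure_spl(boosted, rec$schedule, cal2, "tone_800",
                    noise_label = NA)
  expect_equal(m2$spl_rms, m0$spl_rms, tolerance = 1e-6)
})

test_that("background-noise maxima come from 15-s tiled windows", {
  sr <- 8000
  set.seed(2)
  target_spl <- 60
  cal <- structure(list(offset = 94, cal_segments_used = 1, drift = NA,
                        drift_warning = FALSE), class = "calibration")
  x <- rnorm(60 * sr, sd = 10^((target_spl - 94) / 20))
  st <- background_noise_stats(waveform(x, sr), cal)
  expect_equal(st$n_windows, 4)           # 60 s / 15 s
  expect_equal(st$max_rms_spl, target_spl, tolerance = 0.5)
  expect_false(st$truncated)
  # a transient boosts the peak statistic of its window
  x2 <- x; x2[sr * 20] <- 0.9
  st2 <- background_noise_stats(waveform(x2, sr), cal)
  expect_equal(st2$max_peak_spl, 20 * log10(0.9) + 94, tolerance = 0.01)
  expect_warning(
    stt <- background_noise_stats(waveform(x[1:(5 * sr)], sr), cal),
    "shorter")
  expect_true(stt$truncated)
})

test_that("calibration absorbs simulator gain steps (gain-invariant SPL)", {
  tr_gain <- flat_transect(ea = 0, noise_spl = -Inf,
                           gain_steps = c("4" = 10, "8" = 20), seed = 5)
  tr_flat <- flat_transect(ea = 0, noise_spl = -Inf,
                           gain_steps = c("4" = 0, "8" = 0), seed = 5)
  mg <- measure_transect(tr_gain)
  mf <- measure_transect(tr_flat)
  expect_equal(mg$spl_rms, mf$spl_rms, tolerance = 0.1)
})
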