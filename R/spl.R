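#' Calibrate a recording against its calibration tone(s)
#'
#' The calibrator emits a tone of known SPL (94 dB re 20 uPa at 1 kHz by
#' convention) through the whole measurement chain, so the digital RMS of the
#' recorded calibration segment fixes the mapping from digital level to
#' absolute SPL: \code{offset = reference_spl - 20 log10(RMS_digital)}. With a
#' start and an end tone the two offsets are averaged (in dB) and their
#' difference is reported as drift.
#'
#' @param wave recording \code{waveform} (digital).
#' @param schedule its schedule; calibration segments have
#'   \code{kind == "calibration"}.
#' @param reference_spl calibrator level, dB SPL (default 94).
#' @param drift_tol warn when |drift| exceeds this many dB (default 1).
#' @return list of class \code{"calibration"}: \code{offset} (dB),
#'   \code{cal_segments_used}, \code{drift} (dB, NA with a single segment),
#'   \code{drift_warning} (logical).
#' @export
calibrate_recording <- function(wave, schedule, reference_spl = 94,
                                drift_tol = 1) {
  cal <- schedule[schedule$kind == "calibration", , drop = FALSE]
  if (nrow(cal) == 0L) stop("no calibration segment in schedule")
  offsets <- vapply(cal$label, function(lb) {
    seg <- extract_segment(wave, schedule, lb)
    reference_spl - 20 * log10(sample_rms(seg$samples, seg$sample_rate,
                                          trim = 0.005))
  }, numeric(1))
  drift <- if (length(offsets) >= 2L)
    unname(offsets[length(offsets)] - offsets[1L]) else NA_real_
  warn <- isTRUE(abs(drift) > drift_tol)
  if (warn)
    warning(sprintf("calibration drift %.2f dB exceeds %.1f dB", drift,
                    drift_tol))
  structure(list(offset = mean(offsets),
                 cal_segments_used = length(offsets),
                 drift = drift, drift_warning = warn),
            class = "calibration")
}

# one-sided power spectrum with cumulative band power, so repeated band-RMS
# queries against the same (long) noise segment cost one FFT total
power_spectrum <- function(x, sample_rate) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1L)
  p <- Mod(X[half])^2 / n^2
  mult <- rep(2, length(half))
  mult[1] <- 1
  if (n %% 2 == 0) mult[length(half)] <- 1
  list(f = (half - 1) * sample_rate / n, cum_power = cumsum(p * mult))
}

spectrum_band_rms <- function(spec, lo, hi) {
  i0 <- findInterval(lo, spec$f)          # last bin below lo
  i1 <- findInterval(hi, spec$f)          # last bin <= hi
  if (i1 <= i0) return(0)
  sqrt(spec$cum_power[i1] - spec$cum_power[i0])
}

# one-sided FFT band RMS of a sample vector between lo and hi Hz
band_rms <- function(x, sample_rate, lo, hi) {
  spectrum_band_rms(power_spectrum(x, sample_rate), lo, hi)
}

#' Measure the sound pressure level of one scheduled segment
#'
#' RMS and peak SPL (dB re 20 uPa) of a segment, referenced through a
#' calibration offset. RMS excludes 5-ms edge ramps. The signal-to-noise
#' ratio compares the segment's RMS SPL with the background-noise level in a
#' matched band: +/- 1/3 octave around a tone's frequency, or the full
#' 0.2--5 kHz band for calls and broadband segments. Segments clipped for
#' more than 1\% of samples, or with SNR below the threshold, are flagged
#' invalid.
#'
#' @param wave recording \code{waveform}.
#' @param schedule schedule data.frame.
#' @param calibration result of \code{\link{calibrate_recording}}.
#' @param label segment label to measure.
#' @param snr_threshold validity threshold in dB (default 6).
#' @param noise_label label of the background-noise segment (default
#'   \code{"background"}; set NA to skip SNR screening).
#' @param call_band band for non-tonal segments, Hz (default c(200, 5000)).
#' @param noise_ref optional precomputed noise power spectrum (internal
#'   cache used by \code{\link{measure_transect}}).
#' @return one-row data.frame: \code{signal_id}, \code{kind},
#'   \code{frequency}, \code{species}, \code{spl_rms}, \code{spl_peak},
#'   \code{snr}, \code{clipped}, \code{valid}.
#' @export
measure_spl <- function(wave, schedule, calibration, label,
                        snr_threshold = 6, noise_label = "background",
                        call_band = c(200, 5000), noise_ref = NULL) {
  row <- schedule[schedule$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("segment not found (or not unique): ", label)
  seg <- extract_segment(wave, schedule, label)
  rms <- sample_rms(seg$samples, seg$sample_rate, trim = 0.005)
  spl_rms <- 20 * log10(rms) + calibration$offset
  spl_peak <- 20 * log10(max(abs(seg$samples))) + calibration$offset
  clipped <- mean(abs(seg$samples) >= 0.999) > 0.01

  snr <- NA_real_
  if (is.null(noise_ref) && !is.na(noise_label) &&
      noise_label %in% schedule$label) {
    noi <- extract_segment(wave, schedule, noise_label)
    noise_ref <- power_spectrum(noi$samples, noi$sample_rate)
  }
  if (!is.null(noise_ref)) {
    band <- if (identical(row$kind, "tone") && is.finite(row$frequency))
      c(row$frequency / 2^(1 / 6), row$frequency * 2^(1 / 6))
    else call_band
    nb <- spectrum_band_rms(noise_ref, band[1], band[2])
    snr <- spl_rms - (20 * log10(nb) + calibration$offset)
  }
  valid <- !clipped && (is.na(snr) || snr >= snr_threshold)
  data.frame(signal_id = label, kind = row$kind, frequency = row$frequency,
             species = row$species, spl_rms = spl_rms, spl_peak = spl_peak,
             snr = snr, clipped = clipped, valid = valid,
             stringsAsFactors = FALSE)
}

#' Background-noise statistics over tiled windows
#'
#' The noise recording is tiled into windows (15 s by default); per-window
#' RMS and peak SPL are computed and their maxima returned.
#'
#' @param wave noise-only \code{waveform} (digital).
#' @param calibration a \code{\link{calibrate_recording}} result.
#' @param window window length in seconds (default 15).
#' @return list: \code{max_rms_spl}, \code{max_peak_spl}, \code{n_windows},
#'   \code{truncated} (TRUE when the segment was shorter than one window).
#' @export
background_noise_stats <- function(wave, calibration, window = 15) {
  n <- length(wave$samples)
  wlen <- round(window * wave$sample_rate)
  truncated <- n < wlen
  if (truncated) {
    warning("noise segment shorter than one window; using a single ",
            "truncated window")
    wlen <- n
  }
  n_win <- n %/% wlen
  rms_spl <- peak_spl <- numeric(n_win)
  for (i in seq_len(n_win)) {
    x <- wave$samples[((i - 1L) * wlen + 1L):(i * wlen)]
    rms_spl[i] <- 20 * log10(sqrt(mean(x^2))) + calibration$offset
    peak_spl[i] <- 20 * log10(max(abs(x))) + calibration$offset
  }
  list(max_rms_spl = max(rms_spl), max_peak_spl = max(peak_spl),
       n_windows = n_win, truncated = truncated)
}

#' Measure every playback segment of a simulated transect
#'
#' Calibrates each recording against its embedded calibration tones (per-
#' recording referencing) and measures RMS/peak SPL and SNR for every call,
#' tone and white-noise segment at every distance.
#'
#' @param transect a \code{transect} from \code{\link{simulate_transect}}.
#' @param snr_threshold SNR validity threshold in dB (default 6).
#' @param reference_spl calibrator level (default the transect's own).
#' @return data.frame of measurement records: locality, substrate, distance,
#'   signal_id, kind, frequency, species, spl_rms, spl_peak, snr, clipped,
#'   valid, cal_offset, cal_drift.
#' @export
measure_transect <- function(transect, snr_threshold = 6,
                             reference_spl = NULL) {
  stopifnot(inherits(transect, "transect"))
  if (is.null(reference_spl)) reference_spl <- transect$params$cal_spl
  sc <- transect$scenario
  rows <- lapply(transect$recordings, function(rec) {
    calib <- calibrate_recording(rec$wave, rec$schedule, reference_spl)
    segs <- rec$schedule[rec$schedule$kind %in%
                           c("call", "tone", "white_noise"), , drop = FALSE]
    noise_ref <- if ("background" %in% rec$schedule$label) {
      noi <- extract_segment(rec$wave, rec$schedule, "background")
      power_spectrum(noi$samples, noi$sample_rate)
    } else NULL
    meas <- do.call(rbind, lapply(segs$label, function(lb)
      measure_spl(rec$wave, rec$schedule, calib, lb,
                  snr_threshold = snr_threshold, noise_ref = noise_ref)))
    rownames(meas) <- NULL
    cbind(data.frame(locality = rep(sc$locality, nrow(meas)),
                     substrate = sc$substrate, distance = rec$distance,
                     stringsAsFactors = FALSE),
          meas,
          data.frame(cal_offset = rep(calib$offset, nrow(meas)),
                     cal_drift = calib$drift))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
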