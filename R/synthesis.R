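#' Pure-tone schedule for the playback program
#'
#' The tone series probes transmission between 0.2 and 5 kHz: a 100-Hz series
#' from 200 to 2400 Hz (23 tones) followed by a 500-Hz series from 2500 to
#' 5000 Hz (6 tones), 29 tones in all, each 0.5 s at full scale.
#'
#' @param duration tone duration in seconds (default 0.5).
#' @param peak_amplitude peak amplitude as a fraction of full scale, in (0, 1].
#' @return data.frame with columns \code{frequency} (Hz), \code{duration} (s)
#'   and \code{peak_amplitude}.
#' @export
tone_schedule <- function(duration = 0.5, peak_amplitude = 1) {
  stopifnot(duration > 0, peak_amplitude > 0, peak_amplitude <= 1)
  freqs <- c(seq(200, 2400, by = 100), seq(2500, 5000, by = 500))
  data.frame(frequency = freqs, duration = duration,
             peak_amplitude = peak_amplitude)
}

#' Synthesize a pure tone
#'
#' A sine at the requested frequency with 5-ms raised-cosine onset and offset
#' ramps (to avoid spectral splatter at segment edges).
#'
#' @param frequency tone frequency in Hz; must be below Nyquist.
#' @param duration duration in seconds.
#' @param peak_amplitude peak amplitude, fraction of full scale in (0, 1].
#' @param sample_rate sampling rate in Hz.
#' @param ramp ramp length in seconds (default 0.005).
#' @return a \code{waveform}.
#' @export
synth_tone <- function(frequency, duration = 0.5, peak_amplitude = 1,
                       sample_rate = 44100, ramp = 0.005) {
  stopifnot(frequency > 0, duration > 0,
            peak_amplitude > 0, peak_amplitude <= 1)
  if (frequency >= sample_rate / 2)
    stop("tone frequency ", frequency, " Hz is at or above Nyquist (",
         sample_rate / 2, " Hz)")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- sin(2 * pi * frequency * t)
  x <- apply_ramps(x, sample_rate, ramp)
  waveform(peak_amplitude * x / max(abs(x)), sample_rate)
}

# raised-cosine fade-in/out over `ramp` seconds at each end
apply_ramps <- function(x, sample_rate, ramp) {
  k <- round(ramp * sample_rate)
  if (k > 0 && 2 * k < length(x)) {
    w <- 0.5 * (1 - cos(pi * (seq_len(k) - 0.5) / k))
    x[seq_len(k)] <- x[seq_len(k)] * w
    x[length(x) - k + seq_len(k)] <- x[length(x) - k + seq_len(k)] * rev(w)
  }
  x
}

#' Specification of a synthetic advertisement call
#'
#' Parameters describing one individual's call: the dominant (spectral-peak)
#' frequency, call duration, number of harmonic partials, an optional
#' low-frequency secondary band, and the amplitude-modulation rate of the
#' pulsed envelope. Real frog calls carry far more temporal fine structure;
#' this stand-in reproduces only dominant frequency, duration, harmonic
#' content and AM envelope.
#'
#' @param species_label text label, e.g. \code{"P_perezi"}.
#' @param dominant_frequency Hz, spectral peak of the synthesized call.
#' @param duration_ms call duration in milliseconds.
#' @param secondary_band optional Hz: a weaker component below the dominant.
#' @param harmonic_count number of harmonic partials (default 4).
#' @param am_rate amplitude-modulation rate in Hz (default 50).
#' @param n_calls calls per individual included in the playback (default 6).
#' @return a list of class \code{"call_spec"}.
#' @export
call_spec <- function(species_label, dominant_frequency, duration_ms,
                      secondary_band = NULL, harmonic_count = 4,
                      am_rate = 50, n_calls = 6) {
  stopifnot(dominant_frequency > 0, duration_ms > 0, n_calls >= 1,
            harmonic_count >= 1)
  structure(list(species_label = species_label,
                 dominant_frequency = dominant_frequency,
                 duration_ms = duration_ms,
                 secondary_band = secondary_band,
                 harmonic_count = harmonic_count,
                 am_rate = am_rate,
                 n_calls = n_calls),
            class = "call_spec")
}

#' Default call specifications for the two study species
#'
#' Thirteen individuals: seven of the native species (dominant frequency
#' 2678.3 +/- 279.5 Hz, duration 430 +/- 183 ms, truncated to the observed
#' ranges 2153.3--3186.9 Hz and 181--862 ms) and six of the invasive species
#' (1405.2 +/- 552.6 Hz within 430.7--1981.1 Hz; 641 +/- 101 ms within
#' 453--862 ms), six calls each. Individual parameters are drawn once from
#' these truncated normal distributions, deterministically for a given seed.
#'
#' @param seed integer seed for the individual-level draws.
#' @return list of \code{call_spec}, one per individual, named
#'   \code{Pp1..Pp7}, \code{Lc1..Lc6}.
#' @export
study_call_specs <- function(seed = 20090330) {
  rtrunc <- function(rng, n, mean, sd, lo, hi) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- mean + sd * rng()
        if (v >= lo && v <= hi) break
      }
      out[i] <- v
    }
    out
  }
  specs <- list()
  withr_seed <- function(expr) expr  # draws below share one RNG stream
  set.seed(seed)
  rng <- function() rnorm(1)
  pf <- rtrunc(rng, 7, 2678.3, 279.5, 2153.3, 3186.9)
  pd <- rtrunc(rng, 7, 430, 183, 181, 862)
  for (i in 1:7)
    specs[[paste0("Pp", i)]] <- call_spec("P_perezi", pf[i], pd[i],
                                          secondary_band = 1000,
                                          harmonic_count = 3, am_rate = 22)
  lf <- rtrunc(rng, 6, 1405.2, 552.6, 430.7, 1981.1)
  ld <- rtrunc(rng, 6, 641, 101, 453, 862)
  for (i in 1:6)
    specs[[paste0("Lc", i)]] <- call_spec("L_catesbeianus", lf[i], ld[i],
                                          secondary_band = 300,
                                          harmonic_count = 3, am_rate = 100)
  specs
}

#' Synthesize an advertisement call from a specification
#'
#' A harmonic stack whose strongest partial sits exactly at the dominant
#' frequency (higher partials decay by half per step), with an optional weaker
#' secondary band, a raised-cosine pulsatile AM envelope at \code{am_rate},
#' and 10-ms edge ramps. Partials at or above Nyquist are dropped with a
#' warning. Output is peak-normalized to 1 and bit-reproducible for a fixed
#' (spec, seed, sample_rate).
#'
#' @param spec a \code{call_spec}.
#' @param sample_rate Hz.
#' @param seed integer; seeds the partial phases.
#' @return a \code{waveform}.
#' @export
synth_call <- function(spec, sample_rate = 44100, seed = 1) {
  stopifnot(inherits(spec, "call_spec"))
  n <- round(spec$duration_ms / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  set.seed(seed)
  phases <- runif(spec$harmonic_count + 1, 0, 2 * pi)
  x <- numeric(n)
  dropped <- 0L
  for (k in seq_len(spec$harmonic_count)) {
    f <- spec$dominant_frequency * k
    if (f >= sample_rate / 2) { dropped <- dropped + 1L; next }
    x <- x + 0.5^(k - 1) * sin(2 * pi * f * t + phases[k])
  }
  if (dropped > 0L)
    warning(dropped, " partial(s) above Nyquist dropped for ",
            spec$species_label)
  if (!is.null(spec$secondary_band) && spec$secondary_band < sample_rate / 2)
    x <- x + 0.3 * sin(2 * pi * spec$secondary_band * t +
                         phases[spec$harmonic_count + 1])
  # pulsatile AM: raised-cosine between 0.25 and 1 at am_rate
  env <- 0.625 + 0.375 * cos(2 * pi * spec$am_rate * t)
  x <- x * env
  x <- apply_ramps(x, sample_rate, 0.010)
  waveform(x / max(abs(x)), sample_rate)
}

#' Band-limited white noise
#'
#' Gaussian noise band-limited by an FFT mask (default 0.1--10 kHz, clipped to
#' Nyquist) and peak-normalized.
#'
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param band length-2 numeric, passband in Hz.
#' @param seed integer seed.
#' @return a \code{waveform}.
#' @export
white_noise <- function(duration = 3, sample_rate = 44100,
                        band = c(100, 10000), seed = 1) {
  n <- round(duration * sample_rate)
  set.seed(seed)
  x <- rnorm(n)
  hi <- min(band[2], sample_rate / 2 * 0.999)
  x <- fft_bandpass(x, sample_rate, band[1], hi)
  x <- apply_ramps(x, sample_rate, 0.005)
  waveform(x / max(abs(x)), sample_rate)
}

# zero-phase brick-wall bandpass via FFT mask
fft_bandpass <- function(x, sample_rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)           # two-sided bin frequencies
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (\code{signal::filtfilt}), used to strip low-frequency rumble (wind,
#' handling noise) below the cutoff before assembly.
#'
#' @param wave a \code{waveform}.
#' @param cutoff high-pass cutoff in Hz (default 300).
#' @param order filter order (default 4).
#' @return filtered \code{waveform}.
#' @export
high_pass <- function(wave, cutoff = 300, order = 4) {
  stopifnot(inherits(wave, "waveform"), cutoff > 0,
            cutoff < wave$sample_rate / 2)
  bf <- signal::butter(order, cutoff / (wave$sample_rate / 2), type = "high")
  waveform(signal::filtfilt(bf, wave$samples), wave$sample_rate)
}

#' Assemble the full playback program
#'
#' Concatenates, in order: per-individual advertisement-call blocks (each
#' individual's calls repeated \code{n_calls} times), the pure-tone series,
#' one white-noise segment, and a 1-kHz calibration tone segment, separated by
#' silent gaps. Every segment is 100\% peak-normalized before assembly so all
#' signals share the same relative amplitude. Call segments are optionally
#' high-pass filtered at 300 Hz (default on, as is standard for field playback
#' material; tones are synthesized clean and left unfiltered by default).
#'
#' @param tones data.frame from \code{\link{tone_schedule}} (or a subset).
#' @param calls list of \code{call_spec} (e.g. \code{\link{study_call_specs}}).
#' @param sample_rate Hz (default 44100).
#' @param gap inter-segment silence in seconds (default 0.5).
#' @param noise_duration white-noise segment duration, seconds (default 3).
#' @param cal_frequency calibration / level-setting tone frequency, Hz.
#' @param cal_duration calibration tone duration, seconds (default 3).
#' @param filter_calls logical, high-pass calls at \code{hp_cutoff} (default TRUE).
#' @param filter_tones logical, high-pass tones too (default FALSE).
#' @param hp_cutoff high-pass cutoff in Hz (default 300).
#' @param seed integer seed for call synthesis and noise.
#' @return list with elements \code{wave} (a \code{waveform}) and
#'   \code{schedule}: data.frame(label, onset_s, duration_s, kind, frequency,
#'   species), one row per non-silent segment. \code{kind} is one of
#'   \code{"call"}, \code{"tone"}, \code{"white_noise"}, \code{"level_ref"}
#'   (the broadcast-level reference tone, distinct from the measurement-chain
#'   calibrator embedded later by the transect simulator).
#' @export
assemble_playback <- function(tones = tone_schedule(),
                              calls = study_call_specs(),
                              sample_rate = 44100, gap = 0.5,
                              noise_duration = 3,
                              cal_frequency = 1000, cal_duration = 3,
                              filter_calls = TRUE, filter_tones = FALSE,
                              hp_cutoff = 300, seed = 1) {
  if ((is.null(tones) || nrow(tones) == 0L) && length(calls) == 0L)
    stop("nothing to assemble: no tones and no calls")
  segs <- list()
  meta <- list()
  add <- function(wave, label, kind, frequency = NA_real_,
                  species = NA_character_) {
    w <- wave$samples / max(abs(wave$samples))
    segs[[length(segs) + 1L]] <<- w
    meta[[length(meta) + 1L]] <<- data.frame(
      label = label, duration_s = length(w) / sample_rate, kind = kind,
      frequency = frequency, species = species, stringsAsFactors = FALSE)
  }
  for (nm in names(calls)) {
    spec <- calls[[nm]]
    for (j in seq_len(spec$n_calls)) {
      w <- synth_call(spec, sample_rate, seed = seed + 1000L * j +
                        utf8ToInt(substr(nm, nchar(nm), nchar(nm))))
      if (filter_calls) w <- high_pass(w, hp_cutoff)
      add(w, paste0(nm, "_c", j), "call", spec$dominant_frequency,
          spec$species_label)
    }
  }
  if (!is.null(tones)) {
    for (i in seq_len(nrow(tones))) {
      w <- synth_tone(tones$frequency[i], tones$duration[i],
                      tones$peak_amplitude[i], sample_rate)
      if (filter_tones) w <- high_pass(w, hp_cutoff)
      add(w, paste0("tone_", tones$frequency[i]), "tone", tones$frequency[i])
    }
  }
  if (noise_duration > 0)
    add(white_noise(noise_duration, sample_rate, seed = seed + 7L),
        "white_noise", "white_noise")
  if (cal_duration > 0)
    add(synth_tone(cal_frequency, cal_duration, 1, sample_rate),
        "level_ref", "level_ref", cal_frequency)

  gap_n <- round(gap * sample_rate)
  sched <- do.call(rbind, meta)
  onsets <- numeric(nrow(sched))
  pos <- 0L
  out <- vector("list", 2L * nrow(sched))
  for (i in seq_len(nrow(sched))) {
    onsets[i] <- pos / sample_rate
    out[[2L * i - 1L]] <- segs[[i]]
    out[[2L * i]] <- numeric(gap_n)
    pos <- pos + length(segs[[i]]) + gap_n
  }
  sched$onset_s <- onsets
  sched <- sched[, c("label", "onset_s", "duration_s", "kind",
                     "frequency", "species")]
  list(wave = waveform(unlist(out, use.names = FALSE), sample_rate),
       schedule = sched)
}

#' Extract one scheduled segment from a recording
#'
#' @param wave a \code{waveform}.
#' @param schedule schedule data.frame.
#' @param label segment label to extract.
#' @return a \code{waveform} holding that segment's samples.
#' @export
extract_segment <- function(wave, schedule, label) {
  row <- schedule[schedule$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("segment not found (or not unique): ", label)
  i0 <- round(row$onset_s * wave$sample_rate) + 1L
  i1 <- min(length(wave$samples),
            i0 + round(row$duration_s * wave$sample_rate) - 1L)
  waveform(wave$samples[i0:i1], wave$sample_rate)
}
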