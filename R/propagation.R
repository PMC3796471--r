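#' Define a propagation scenario
#'
#' A scenario is the ground truth for one (locality, substrate) transect: a
#' frequency-dependent excess-attenuation profile expressed in dB per doubling
#' of distance beyond spherical spreading, a background-noise floor, recorder
#' gain steps per distance, and an optional fixed loudspeaker coloration.
#'
#' @param locality text label.
#' @param substrate \code{"water"} or \code{"soil"}.
#' @param ea_profile excess attenuation in dB per distance doubling: a single
#'   number (flat), a data.frame with columns \code{frequency} and \code{ea_db}
#'   (linearly interpolated, constant beyond the grid), or a function of
#'   frequency in Hz.
#' @param noise_spl background noise floor, dB SPL re 20 uPa (\code{-Inf} for
#'   a noiseless medium).
#' @param gain_steps named numeric: recorder gain offset (dB) per distance,
#'   names are distances in metres. Distances absent from the vector get 0 dB.
#' @param source_response optional loudspeaker coloration in dB versus
#'   frequency (number, data.frame \code{frequency}/\code{gain_db}, or
#'   function); must stay within +/- 8 dB.
#' @param two_ray optional list(delay_s, coef): adds a single surface
#'   reflection (comb filter) with the given extra delay and amplitude
#'   coefficient; off (NULL) by default.
#' @param seed integer seed for the scenario's noise realizations.
#' @return object of class \code{"propagation_scenario"}.
#' @export
propagation_scenario <- function(locality, substrate = c("water", "soil"),
                                 ea_profile = 0, noise_spl = -Inf,
                                 gain_steps = c("0.5" = 0, "1" = 0, "2" = 0,
                                                "4" = 10, "8" = 10),
                                 source_response = NULL, two_ray = NULL,
                                 seed = 1) {
  substrate <- match.arg(substrate)
  ea_fn <- profile_fn(ea_profile, "ea_db")
  src_fn <- if (is.null(source_response)) function(f) rep(0, length(f))
            else profile_fn(source_response, "gain_db")
  probe <- seq(200, 5000, by = 100)
  if (any(!is.finite(ea_fn(probe)))) stop("ea_profile must be finite")
  if (any(abs(src_fn(probe)) > 8 + 1e-9))
    stop("source_response must stay within +/- 8 dB over 0.2-5 kHz")
  structure(list(locality = locality, substrate = substrate,
                 ea_profile = ea_fn, source_response = src_fn,
                 noise_spl = noise_spl, gain_steps = gain_steps,
                 two_ray = two_ray, seed = as.integer(seed)),
            class = "propagation_scenario")
}

# normalize a profile (number / data.frame / function) to a function of Hz
profile_fn <- function(p, value_col) {
  if (is.function(p)) return(p)
  if (is.numeric(p) && length(p) == 1L) return(function(f) rep(p, length(f)))
  if (is.data.frame(p)) {
    stopifnot(all(c("frequency", value_col) %in% names(p)))
    fr <- p$frequency; va <- p[[value_col]]
    return(function(f) stats::approx(fr, va, xout = f, rule = 2)$y)
  }
  stop("profile must be a number, a data.frame or a function")
}

# recorder gain (dB) for a distance under a scenario
gain_at <- function(scenario, distance) {
  g <- scenario$gain_steps[as.character(distance)]
  if (is.na(g)) 0 else unname(g)
}

# reference pressure, Pa
P_REF <- 2e-5

#' Propagate a pressure waveform to a receiver distance
#'
#' Applies, in the frequency domain (zero phase), the gain
#' \deqn{-[20 \log_{10}(d/d_0) + EA(f)\,\log_2(d/d_0)] + S(f)}
#' where \eqn{d_0} is the reference distance, \eqn{EA(f)} the scenario's
#' excess-attenuation profile (dB per distance doubling) and \eqn{S(f)} the
#' distance-independent loudspeaker coloration; then adds receiver-side
#' Gaussian background noise realizing the scenario's noise floor, and finally
#' applies the recorder gain step for that distance. Input samples are in
#' pascals; noise realizations are deterministic per (scenario seed, distance).
#'
#' @param source \code{waveform} in pressure units (Pa) as emitted at the
#'   reference distance.
#' @param distance receiver distance in metres, \code{>= reference}.
#' @param scenario a \code{\link{propagation_scenario}}.
#' @param reference reference distance in metres (default 0.5).
#' @param add_noise logical; set FALSE for a noiseless run.
#' @param apply_gain logical; set FALSE to skip the recorder gain step.
#' @return \code{waveform} in pressure units at the recorder input.
#' @export
propagate <- function(source, distance, scenario, reference = 0.5,
                      add_noise = TRUE, apply_gain = TRUE) {
  stopifnot(inherits(source, "waveform"),
            inherits(scenario, "propagation_scenario"))
  if (distance < reference)
    stop("distance (", distance, " m) below the reference (", reference, " m)")
  sr <- source$sample_rate
  n <- length(source$samples)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(source$samples, numeric(nfft - n)))
  f <- (seq_len(nfft) - 1) * sr / nfft
  f <- pmin(f, sr - f)
  log2r <- log2(distance / reference)
  gain_db <- -(20 * log10(distance / reference) +
                 scenario$ea_profile(f) * log2r) +
             scenario$source_response(f)
  G <- 10^(gain_db / 20)
  if (!is.null(scenario$two_ray) && distance > reference) {
    tr <- scenario$two_ray
    G <- G * Mod(1 + tr$coef * exp(-2i * pi * f * tr$delay_s))
  }
  y <- Re(stats::fft(X * G, inverse = TRUE))[seq_len(n)] / nfft
  if (add_noise && is.finite(scenario$noise_spl)) {
    set.seed(scenario$seed + round(1000 * distance))
    y <- y + stats::rnorm(n, sd = P_REF * 10^(scenario$noise_spl / 20))
  }
  if (apply_gain) y <- y * 10^(gain_at(scenario, distance) / 20)
  waveform(y, sr)
}

#' Simulate one recording transect
#'
#' Produces one recording per distance. Each recording contains a calibration
#' tone at the start and end (the calibrator is held at the microphone, so the
#' tone passes through the recorder gain but not through the medium), the
#' propagated playback with receiver-side background noise, and a trailing
#' background-noise-only segment. The playback's level-reference segment sets
#' the absolute scale: its peak pressure at the reference distance equals
#' \code{broadcast_peak_spl}.
#'
#' @param playback list(wave, schedule) from \code{\link{assemble_playback}}
#'   (digital full-scale audio).
#' @param scenario a \code{\link{propagation_scenario}}.
#' @param distances metres; must include the reference distance.
#' @param reference reference distance, m (default 0.5).
#' @param broadcast_peak_spl peak SPL (dB re 20 uPa) of the 1-kHz
#'   level-reference tone at the reference distance (default 75).
#' @param cal_spl calibrator level, dB SPL (default 94).
#' @param cal_frequency calibrator frequency, Hz (default 1000).
#' @param cal_duration calibration tone duration, s (default 3).
#' @param background_duration trailing noise-only segment, s (default 60).
#' @param mic_fullscale_pa pressure mapped to digital full scale (default
#'   20 Pa, i.e. 120 dB SPL full scale).
#' @param gap silence between blocks, s (default 0.25).
#' @return object of class \code{"transect"}: a list with \code{recordings}
#'   (per distance: wave, schedule, distance, gain_db), \code{scenario} (the
#'   ground truth, retained), and \code{params}.
#' @export
simulate_transect <- function(playback, scenario,
                              distances = c(0.5, 1, 2, 4, 8),
                              reference = 0.5,
                              broadcast_peak_spl = 75, cal_spl = 94,
                              cal_frequency = 1000, cal_duration = 3,
                              background_duration = 60,
                              mic_fullscale_pa = 20, gap = 0.25) {
  stopifnot(inherits(scenario, "propagation_scenario"),
            reference %in% distances || all(distances >= reference))
  sr <- playback$wave$sample_rate
  ref_rows <- playback$schedule[playback$schedule$kind == "level_ref", ,
                                drop = FALSE]
  ref_peak <- if (nrow(ref_rows) > 0L)
    max(abs(extract_segment(playback$wave, playback$schedule,
                            ref_rows$label[1])$samples))
  else max(abs(playback$wave$samples))
  p_scale <- P_REF * 10^(broadcast_peak_spl / 20) / ref_peak
  src_pa <- waveform(playback$wave$samples * p_scale, sr)

  cal_rms_pa <- P_REF * 10^(cal_spl / 20)
  cal_tone <- synth_tone(cal_frequency, cal_duration, 1, sr)
  cal_pa <- cal_tone$samples / sample_rms(cal_tone$samples, sr, 0.005) *
    cal_rms_pa
  gap_n <- round(gap * sr)

  recordings <- lapply(distances, function(d) {
    glin <- 10^(gain_at(scenario, d) / 20)
    prop <- propagate(src_pa, d, scenario, reference)
    noise_sd <- if (is.finite(scenario$noise_spl))
      P_REF * 10^(scenario$noise_spl / 20) else 0
    set.seed(scenario$seed + round(1000 * d) + 17L)
    bg <- stats::rnorm(round(background_duration * sr), sd = noise_sd) * glin
    set.seed(scenario$seed + round(1000 * d) + 29L)
    mk_cal <- function() (cal_pa +
      stats::rnorm(length(cal_pa), sd = noise_sd)) * glin
    cal1 <- mk_cal(); cal2 <- mk_cal()
    pa <- c(cal1, numeric(gap_n), prop$samples, numeric(gap_n), bg,
            numeric(gap_n), cal2)
    blocks <- data.frame(
      label = c("cal_start", "background", "cal_end"),
      onset_s = c(0,
                  (length(cal1) + 2L * gap_n + length(prop$samples)) / sr,
                  (length(pa) - length(cal2)) / sr),
      duration_s = c(cal_duration, background_duration, cal_duration),
      kind = c("calibration", "noise_floor", "calibration"),
      frequency = c(cal_frequency, NA, cal_frequency),
      species = NA_character_, stringsAsFactors = FALSE)
    play_sched <- playback$schedule
    play_sched$onset_s <- play_sched$onset_s + (length(cal1) + gap_n) / sr
    sched <- rbind(blocks[1, ], play_sched, blocks[2:3, ])
    rownames(sched) <- NULL
    list(wave = waveform(pa / mic_fullscale_pa, sr), schedule = sched,
         distance = d, gain_db = gain_at(scenario, d))
  })
  names(recordings) <- as.character(distances)
  structure(list(recordings = recordings, scenario = scenario,
                 params = list(reference = reference,
                               broadcast_peak_spl = broadcast_peak_spl,
                               cal_spl = cal_spl,
                               mic_fullscale_pa = mic_fullscale_pa,
                               distances = distances)),
            class = "transect")
}

#' Build the seven-locality study fixture
#'
#' Constructs seeded scenarios for seven localities by two substrates and
#' simulates every transect. Water profiles follow the qualitative pattern
#' seen over water surfaces: negative excess attenuation (channeling) below
#' about 2 kHz with a sharp sigmoidal rise near 2--3 kHz. Soil profiles have a
#' larger, more variable baseline with slow spectral undulation. Fully
#' deterministic for a fixed seed.
#'
#' @param playback list(wave, schedule); defaults to the full
#'   \code{\link{assemble_playback}} program.
#' @param localities character vector of locality labels (default seven).
#' @param distances metres (default 0.5, 1, 2, 4, 8).
#' @param noise_spl background noise floor dB SPL (default 15, a quiet
#'   pre-sunset field site, leaving signal-to-noise margin at all distances
#'   so the repeated-measures design stays complete).
#' @param seed master seed.
#' @param ... further arguments passed to \code{\link{simulate_transect}}.
#' @return list of class \code{"study_fixture"}: one \code{transect} per
#'   (locality, substrate), named \code{"<locality>.<substrate>"}.
#' @export
make_study_fixture <- function(playback = assemble_playback(),
                               localities = c("Arimbo", "Donana", "ElCabaco",
                                              "LasJaras", "Navalcarnero",
                                              "Villasbuenas", "Zarzalejo"),
                               distances = c(0.5, 1, 2, 4, 8),
                               noise_spl = 15, seed = 1, ...) {
  scenarios <- study_scenarios(localities, noise_spl, seed)
  out <- lapply(scenarios, function(sc)
    simulate_transect(playback, sc, distances = distances, ...))
  structure(out, class = "study_fixture")
}

#' Seeded scenarios for the study localities
#'
#' @inheritParams make_study_fixture
#' @return named list of \code{\link{propagation_scenario}}.
#' @export
study_scenarios <- function(localities = c("Arimbo", "Donana", "ElCabaco",
                                           "LasJaras", "Navalcarnero",
                                           "Villasbuenas", "Zarzalejo"),
                            noise_spl = 15, seed = 1) {
  grid <- seq(100, 6000, by = 100)
  out <- list()
  for (i in seq_along(localities)) {
    for (sub in c("water", "soil")) {
      sc_seed <- seed + 100L * i + (sub == "soil")
      set.seed(sc_seed)
      if (sub == "water") {
        lo <- stats::runif(1, -3, -1)
        hi <- stats::runif(1, 2, 5)
        f0 <- stats::runif(1, 2000, 3000)
        ea <- lo + (hi - lo) * stats::plogis((grid - f0) / 250)
      } else {
        base <- stats::runif(1, 1, 4)
        per <- stats::runif(1, 1500, 3000)
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 0.5, 1.5)
        ea <- base + amp * sin(2 * pi * grid / per + ph)
      }
      set.seed(sc_seed + 13L)
      src <- stats::runif(1, -2, 2) +
        2 * sin(2 * pi * grid / stats::runif(1, 2000, 4000) +
                  stats::runif(1, 0, 2 * pi))
      out[[paste0(localities[i], ".", sub)]] <- propagation_scenario(
        locality = localities[i], substrate = sub,
        ea_profile = data.frame(frequency = grid, ea_db = ea),
        noise_spl = noise_spl,
        source_response = data.frame(frequency = grid, gain_db = src),
        seed = sc_seed)
    }
  }
  out
}

#' Write a transect to WAV files plus manifest and ground-truth tables
#'
#' @param transect a \code{transect}.
#' @param dir output directory (created if needed).
#' @return data.frame manifest, invisibly.
#' @export
write_transect <- function(transect, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- transect$scenario
  rows <- lapply(transect$recordings, function(rec) {
    file <- sprintf("%s_%s_%gm.wav", sc$locality, sc$substrate, rec$distance)
    wav_write(rec$wave, file.path(dir, file))
    utils::write.csv(rec$schedule,
                     file.path(dir, sub("\\.wav$", "_schedule.csv", file)),
                     row.names = FALSE)
    data.frame(locality = sc$locality, substrate = sc$substrate,
               distance_m = rec$distance, file = file,
               gain_db = rec$gain_db, seed = sc$seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  grid <- seq(200, 5000, by = 100)
  utils::write.csv(data.frame(locality = sc$locality,
                              substrate = sc$substrate, frequency = grid,
                              ea_db_per_doubling = sc$ea_profile(grid)),
                   file.path(dir, "ground_truth_ea.csv"), row.names = FALSE)
  invisible(manifest)
}
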