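# Shared reduced-scale fixtures. Audio is synthesized at 22.05 kHz with short
# segments so the whole suite stays fast; the code path is identical to the
# full-scale defaults. Expensive objects are built once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small playback: 5 tones spanning the category range + 2 individuals
tiny_playback <- function(sr = 22050) {
  cached(paste0("pb", sr), {
    tones <- tone_schedule()[c(1, 7, 15, 24, 29), ]   # 200,800,1600,2500,5000
    calls <- study_call_specs()[c("Pp1", "Lc1")]
    calls <- lapply(calls, function(s) { s$n_calls <- 2; s })
    assemble_playback(tones, calls, sample_rate = sr, gap = 0.1,
                      noise_duration = 1, cal_duration = 1, seed = 42)
  })
}

# transect over a flat EA profile, quiet enough for precise level recovery
flat_transect <- function(ea = 0, noise_spl = -Inf, seed = 7,
                          gain_steps = c("4" = 10, "8" = 10), sr = 22050) {
  sc <- propagation_scenario("flat", "water", ea_profile = ea,
                             noise_spl = noise_spl, gain_steps = gain_steps,
                             seed = seed)
  simulate_transect(tiny_playback(sr), sc, cal_duration = 1,
                    background_duration = 16)
}

# mean recovered EA per distance for a transect
ea_by_distance <- function(transect, snr_threshold = 6) {
  m <- measure_transect(transect, snr_threshold = snr_threshold)
  ea <- ea_from_measurements(m, quiet = TRUE)
  stats::aggregate(excess_attenuation ~ distance, ea, mean)
}

# balanced long-format RM dataset: g between groups x n_per subjects,
# within distance (4) x substrate (2); iid N(0,1) errors unless effects given
null_rm_data <- function(n_per = 8, g = 3, distance_effect = 0) {
  n <- n_per * g
  subj <- sprintf("s%02d", seq_len(n))
  d <- expand.grid(subject = subj, distance = c(1, 2, 4, 8),
                   substrate = c("water", "soil"),
                   stringsAsFactors = FALSE)
  d$group <- rep(letters[seq_len(g)], each = n_per)[match(d$subject, subj)]
  d$y <- stats::rnorm(nrow(d)) +
    distance_effect * as.numeric(factor(d$distance))
  d
}

# the full tone-study layout (29 subjects x 4 x 2 x 7) with iid errors
tone_layout_data <- function() {
  freqs <- tone_schedule()$frequency
  subj <- paste0("tone_", freqs)
  d <- expand.grid(signal_id = subj, distance = c(1, 2, 4, 8),
                   substrate = c("water", "soil"),
                   locality = paste0("L", 1:7), stringsAsFactors = FALSE)
  d$frequency_category <- bin_frequency(freqs)[match(d$signal_id, subj)]
  d$y <- stats::rnorm(nrow(d))
  d
}
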