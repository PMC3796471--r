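#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one serializable
#' object. Defaults reproduce the full study design: the complete playback
#' program (13 individuals x 6 calls, 29 tones, white noise, calibration) at
#' 44.1 kHz, seven localities by two substrates by five distances, a 6-dB SNR
#' validity screen and the shifted-log response transform. Reduced values
#' (fewer tones, shorter segments, lower sample rate) run the identical code
#' path at smaller problem sizes.
#'
#' @param seed master seed.
#' @param sample_rate Hz.
#' @param distances metres, including the 0.5-m reference.
#' @param localities character vector of locality labels.
#' @param tones tone table (\code{\link{tone_schedule}} or a subset).
#' @param calls list of \code{call_spec}.
#' @param noise_spl background noise floor, dB SPL.
#' @param snr_threshold SNR validity threshold, dB.
#' @param transform response transform for the ANOVA stage.
#' @param correction sphericity-correction policy for \code{\link{rm_anova}}.
#' @param gap inter-segment silence in the playback, s.
#' @param noise_duration white-noise segment, s.
#' @param cal_duration calibration tone, s.
#' @param background_duration trailing noise-only segment, s.
#' @param outdir output directory (NULL: nothing written).
#' @param stages character vector of stages to run, a subset of
#'   \code{c("synth", "simulate", "measure", "attenuate", "summarize",
#'   "anova")}.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1, sample_rate = 44100,
                            distances = c(0.5, 1, 2, 4, 8),
                            localities = c("Arimbo", "Donana", "ElCabaco",
                                           "LasJaras", "Navalcarnero",
                                           "Villasbuenas", "Zarzalejo"),
                            tones = tone_schedule(),
                            calls = study_call_specs(),
                            noise_spl = 15, snr_threshold = 6,
                            transform = "shifted_log",
                            correction = "auto",
                            gap = 0.5, noise_duration = 3,
                            cal_duration = 3, background_duration = 60,
                            outdir = NULL,
                            stages = c("synth", "simulate", "measure",
                                       "attenuate", "summarize", "anova")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: stimulus synthesis, transect simulation for every
#' (locality, substrate), calibrated SPL measurement, excess-attenuation
#' computation, linear-scale summary tables, and the two repeated-measures
#' ANOVAs (tones with frequency category between subjects; calls with species
#' between subjects and per-individual linear-scale cell averages). Each
#' stage consumes the previous stage's output; tabular results are written as
#' CSV when \code{config$outdir} is set, along with the resolved
#' configuration and per-stage timings.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with elements \code{playback}, \code{fixture},
#'   \code{measurements}, \code{ea}, \code{tone_summary},
#'   \code{call_cells}, \code{call_summary}, \code{anova_tones},
#'   \code{anova_calls}, \code{timings} (present elements depend on
#'   \code{config$stages}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  timings <- c()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  want <- function(s) s %in% config$stages

  if (want("synth"))
    res$playback <- tic("synth", assemble_playback(
      tones = config$tones, calls = config$calls,
      sample_rate = config$sample_rate, gap = config$gap,
      noise_duration = config$noise_duration,
      cal_duration = config$cal_duration, seed = config$seed))
  if (want("simulate")) {
    if (is.null(res$playback)) stop("stage 'simulate' needs 'synth' output")
    res$fixture <- tic("simulate", make_study_fixture(
      playback = res$playback, localities = config$localities,
      distances = config$distances, noise_spl = config$noise_spl,
      seed = config$seed, cal_duration = config$cal_duration,
      background_duration = config$background_duration))
  }
  if (want("measure")) {
    if (is.null(res$fixture)) stop("stage 'measure' needs 'simulate' output")
    res$measurements <- tic("measure", {
      out <- do.call(rbind, lapply(res$fixture, measure_transect,
                                   snr_threshold = config$snr_threshold))
      rownames(out) <- NULL
      out
    })
  }
  if (want("attenuate")) {
    if (is.null(res$measurements))
      stop("stage 'attenuate' needs 'measure' output")
    res$ea <- tic("attenuate",
                  ea_from_measurements(res$measurements, quiet = TRUE))
  }
  if (want("summarize")) {
    if (is.null(res$ea)) stop("stage 'summarize' needs 'attenuate' output")
    res <- c(res, tic("summarize", {
      tones <- res$ea[res$ea$kind == "tone" &
                        !is.na(res$ea$frequency_category), , drop = FALSE]
      list(
        tone_summary = summarize_ea(tones,
                                    c("substrate", "frequency_category")),
        call_cells = species_call_ea(res$ea),
        call_summary = summarize_ea(
          species_call_ea(res$ea,
                          group_by = c("individual", "species", "locality",
                                       "substrate", "distance")),
          c("species", "substrate", "distance")))
    }))
  }
  if (want("anova")) {
    if (is.null(res$ea)) stop("stage 'anova' needs 'attenuate' output")
    res <- c(res, tic("anova", {
      tones <- res$ea[res$ea$kind == "tone" &
                        !is.na(res$ea$frequency_category), , drop = FALSE]
      tones$response <- transform_response(tones$excess_attenuation,
                                           config$transform)
      within <- intersect(c("distance", "substrate", "locality"),
                          names(which(vapply(
                            tones[c("distance", "substrate", "locality")],
                            function(x) length(unique(x)) > 1, TRUE))))
      at <- rm_anova(tones, "response", "signal_id", within,
                     between = "frequency_category",
                     correction = config$correction)
      cells <- species_call_ea(res$ea,
                               group_by = c("individual", "species",
                                            "locality", "substrate",
                                            "distance"))
      cells$response <- transform_response(cells$excess_attenuation,
                                           config$transform)
      ac <- rm_anova(cells, "response", "individual", within,
                     between = "species", correction = config$correction)
      list(anova_tones = at, anova_calls = ac)
    }))
  }
  res$timings <- unlist(timings)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(
      x, file.path(config$outdir, f), row.names = FALSE)
    if (!is.null(res$playback)) wr(res$playback$schedule, "schedule.csv")
    if (!is.null(res$measurements)) wr(res$measurements, "measurements.csv")
    if (!is.null(res$ea)) wr(res$ea, "excess_attenuation.csv")
    if (!is.null(res$tone_summary)) wr(res$tone_summary, "tone_summary.csv")
    if (!is.null(res$call_cells)) wr(res$call_cells, "call_cells.csv")
    if (!is.null(res$call_summary)) wr(res$call_summary, "call_summary.csv")
    if (!is.null(res$anova_tones)) {
      wr(res$anova_tones$table, "anova_tones.csv")
      wr(res$anova_calls$table, "anova_calls.csv")
    }
    cfg <- config
    cfg$tones <- nrow(cfg$tones)
    cfg$calls <- length(cfg$calls)
    jsonlite::write_json(cfg[setdiff(names(cfg), "outdir")],
                         file.path(config$outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

#' Verify the desk-reproducible printed summary cells
#'
#' Recomputes, from the transcribed summary-table fixtures, every cell that
#' is derivable from other printed cells via the linear-scale averaging rule:
#' the five pooled-substrate ("Total") category means of the tone table from
#' their Water/Soil counterparts; the four per-species substrate means of the
#' call table from their four distance cells; and the two species grand means
#' from the eight distance cells each. Agreement is checked at 2-decimal
#' rounding (half away from zero). Running with the power (\code{/10})
#' convention instead of the amplitude (\code{/20}) convention makes the
#' checks fail, which is how the implemented convention was identified.
#'
#' @param fixtures_dir directory holding the fixture CSVs (default: the
#'   copies installed with the package).
#' @param convention passed to \code{\link{db_mean}}.
#' @return data.frame: check, expected, computed, pass; with attribute
#'   \code{n_pass}.
#' @export
verify_printed_tables <- function(fixtures_dir = system.file(
                                    "extdata", package = "callprop"),
                                  convention = "amplitude") {
  rd <- function(f) utils::read.csv(file.path(fixtures_dir, f),
                                    comment.char = "#",
                                    stringsAsFactors = FALSE)
  tones <- rd("tone_excess_attenuation_summary.csv")
  calls <- rd("call_excess_attenuation_summary.csv")
  grand <- rd("call_grand_means.csv")
  if (nrow(tones) == 0L || nrow(calls) == 0L) stop("fixture tables missing")
  checks <- list()
  add <- function(name, expected, values) {
    computed <- round_half_away(db_mean(values, convention), 2)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, expected = expected, computed = computed,
      pass = isTRUE(all.equal(expected, computed, tolerance = 1e-9)),
      stringsAsFactors = FALSE)
  }
  for (cat in unique(tones$category)) {
    ws <- tones$mean_db[tones$substrate %in% c("Water", "Soil") &
                          tones$category == cat]
    tot <- tones$mean_db[tones$substrate == "Total" & tones$category == cat]
    add(paste0("tone_total_", cat), tot, ws)
  }
  for (sp in unique(calls$species)) {
    for (sub in unique(calls$substrate)) {
      sel <- calls$species == sp & calls$substrate == sub
      dd <- calls$mean_db[sel & calls$distance != "mean"]
      mm <- calls$mean_db[sel & calls$distance == "mean"]
      add(paste0("call_mean_", sp, "_", sub), mm, dd)
    }
  }
  for (sp in grand$species) {
    dd <- calls$mean_db[calls$species == sp & calls$distance != "mean"]
    add(paste0("grand_mean_", sp), grand$mean_db[grand$species == sp], dd)
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  attr(out, "n_pass") <- sum(out$pass)
  out
}
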