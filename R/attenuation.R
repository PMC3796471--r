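#' Spherical-spreading transmission loss
#'
#' Geometric loss of a point source between a reference distance and a
#' farther distance: \code{20 log10(distance / reference)} dB, i.e. 6.02 dB
#' per doubling of distance.
#'
#' @param distance metres.
#' @param reference reference distance, metres (default 0.5).
#' @return loss in dB.
#' @export
spherical_loss <- function(distance, reference = 0.5) {
  if (any(distance <= 0) || reference <= 0)
    stop("distances must be positive")
  if (any(distance < reference))
    stop("distance below the reference distance")
  20 * log10(distance / reference)
}

#' Excess attenuation relative to spherical spreading
#'
#' The actual transmission loss (SPL at the reference minus SPL at the far
#' position) minus the loss predicted by spherical spreading. Positive values
#' mean the sound attenuated faster than the geometric prediction, negative
#' values slower (channeling/enhancement).
#'
#' @param spl_ref SPL at the reference distance, dB re 20 uPa.
#' @param spl_far SPL at the far distance, dB re 20 uPa.
#' @param distance far distance, metres.
#' @param reference reference distance, metres (default 0.5).
#' @return excess attenuation in dB.
#' @export
excess_attenuation <- function(spl_ref, spl_far, distance, reference = 0.5) {
  stopifnot(is.finite(spl_ref), is.finite(spl_far))
  (spl_ref - spl_far) - spherical_loss(distance, reference)
}

#' Average decibel values on a linear (pressure) scale
#'
#' Converts dB values to linear pressure ratios (amplitude convention,
#' \code{10^(v/20)}), averages, and converts back:
#' \code{20 log10(mean(10^(v/20)))}. This is the averaging rule used for all
#' summary cells; by Jensen's inequality it is never below the arithmetic
#' mean of the dB values. A power convention (\code{10^(v/10)}) is available
#' for comparison but is not used by any summary.
#'
#' @param values numeric vector of dB values.
#' @param convention \code{"amplitude"} (default) or \code{"power"}.
#' @return the linear-domain mean, in dB.
#' @export
db_mean <- function(values, convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  if (length(values) == 0L) stop("db_mean of an empty vector")
  if (any(!is.finite(values))) stop("db_mean requires finite values")
  k <- if (convention == "amplitude") 20 else 10
  k * log10(mean(10^(values / k)))
}

#' Round half away from zero
#'
#' Table-style rounding (2.345 -> 2.35, -2.345 -> -2.35), unlike R's default
#' round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Frequency category of a pure tone
#'
#' Maps a frequency to one of five analysis categories chosen around the
#' spectral structure of the two species' calls: F1 0.2--0.5 kHz (fundamental
#' of the invasive species), F2 0.6--1.0, F3 1.1--2.0 (its dominant band),
#' F4 2.1--3.0 (dominant band of the native species), F5 3.5--5.0 kHz.
#' Frequencies in the gaps (0.5--0.6 and 3.0--3.5 kHz, exclusive) or outside
#' 0.2--5 kHz are uncategorized (NA).
#'
#' @param frequency Hz (vectorized).
#' @return factor with levels F1..F5; NA where uncategorized.
#' @export
bin_frequency <- function(frequency) {
  stopifnot(all(frequency > 0))
  khz <- frequency / 1000
  lo <- c(F1 = 0.2, F2 = 0.6, F3 = 1.1, F4 = 2.1, F5 = 3.5)
  hi <- c(F1 = 0.5, F2 = 1.0, F3 = 2.0, F4 = 3.0, F5 = 5.0)
  out <- rep(NA_character_, length(khz))
  for (i in seq_along(lo))
    out[khz >= lo[i] - 1e-9 & khz <= hi[i] + 1e-9] <- names(lo)[i]
  factor(out, levels = names(lo))
}

#' Excess-attenuation records from SPL measurements
#'
#' Pairs each far-distance measurement with the reference-distance
#' measurement of the same signal on the same (locality, substrate) transect
#' and computes excess attenuation. Records flagged invalid (clipped or below
#' the SNR threshold) on either side of a pair are excluded, with a message.
#'
#' @param measurements data.frame from \code{\link{measure_transect}} (rows
#'   from several transects may be bound together).
#' @param reference reference distance, m (default 0.5).
#' @param quiet suppress the exclusion message.
#' @return data.frame of EA records: locality, substrate, distance,
#'   signal_id, kind, frequency, frequency_category, species,
#'   excess_attenuation.
#' @export
ea_from_measurements <- function(measurements, reference = 0.5,
                                 quiet = FALSE) {
  m <- measurements
  n_invalid <- sum(!m$valid)
  if (n_invalid > 0L && !quiet)
    message(n_invalid, " invalid measurement(s) excluded")
  m <- m[m$valid, , drop = FALSE]
  ref <- m[m$distance == reference, , drop = FALSE]
  far <- m[m$distance > reference, , drop = FALSE]
  key <- function(d) paste(d$locality, d$substrate, d$signal_id, sep = "\r")
  ref_spl <- stats::setNames(ref$spl_rms, key(ref))
  far$spl_ref <- ref_spl[key(far)]
  far <- far[!is.na(far$spl_ref), , drop = FALSE]
  ea <- mapply(excess_attenuation, far$spl_ref, far$spl_rms, far$distance,
               MoreArgs = list(reference = reference))
  out <- data.frame(locality = far$locality, substrate = far$substrate,
                    distance = far$distance, signal_id = far$signal_id,
                    individual = ifelse(far$kind == "call",
                                        sub("_c\\d+$", "", far$signal_id),
                                        NA_character_),
                    kind = far$kind, frequency = far$frequency,
                    frequency_category = bin_frequency(
                      ifelse(is.finite(far$frequency), far$frequency, 1000)),
                    species = far$species,
                    excess_attenuation = as.numeric(ea),
                    stringsAsFactors = FALSE)
  out$frequency_category[!is.finite(out$frequency) | out$kind != "tone"] <- NA
  rownames(out) <- NULL
  out
}

#' Per-cell call averages on the linear scale
#'
#' Within each grouping cell the excess-attenuation values of the individual
#' calls are averaged with \code{\link{db_mean}} (dB -> linear pressure ->
#' mean -> dB). The default grouping pools a species' calls per (locality,
#' substrate, distance); grouping by \code{individual} instead yields the
#' per-subject cells the repeated-measures ANOVA consumes. Cells with fewer
#' than \code{min_calls} records are flagged.
#'
#' @param ea_records data.frame from \code{\link{ea_from_measurements}},
#'   call rows.
#' @param group_by grouping columns (default species, locality, substrate,
#'   distance).
#' @param min_calls minimum records per cell before flagging (default 4).
#' @return data.frame: grouping columns, excess_attenuation (dB, linear-scale
#'   mean), n, flagged.
#' @export
species_call_ea <- function(ea_records,
                            group_by = c("species", "locality", "substrate",
                                         "distance"),
                            min_calls = 4) {
  d <- ea_records[ea_records$kind == "call", , drop = FALSE]
  if (nrow(d) == 0L) stop("no call records")
  stopifnot(all(group_by %in% names(d)))
  g <- interaction(d[group_by], drop = TRUE)
  rows <- lapply(split(d, g), function(cell) {
    cbind(cell[1, group_by, drop = FALSE],
          data.frame(excess_attenuation = db_mean(cell$excess_attenuation),
                     n = nrow(cell), flagged = nrow(cell) < min_calls))
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[group_by]), ]
  rownames(out) <- NULL
  out
}

#' Summary table of excess attenuation
#'
#' Groups EA records and reports, per group: the linear-scale mean
#' (\code{\link{db_mean}}), the dB-scale standard deviation, plain extrema of
#' the dB values, and the record count. Empty groups are dropped.
#'
#' @param ea_records data.frame with an \code{excess_attenuation} column.
#' @param group_by character vector of grouping column names.
#' @return data.frame with the grouping columns plus mean, sd, min, max, n.
#' @export
summarize_ea <- function(ea_records, group_by) {
  stopifnot(all(group_by %in% names(ea_records)))
  d <- ea_records[!is.na(ea_records$excess_attenuation), , drop = FALSE]
  g <- interaction(d[group_by], drop = TRUE)
  rows <- lapply(split(d, g), function(cell) {
    v <- cell$excess_attenuation
    cbind(cell[1, group_by, drop = FALSE],
          data.frame(mean = db_mean(v),
                     sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                     min = min(v), max = max(v), n = length(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
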