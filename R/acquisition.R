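## The 18-frame paired LSI/SFDI acquisition cycle: slot schedule, effective
## frame rates, the frame manifest, and set-level dropped-frame rejection.
## One cycle = 3 wavelengths x 2 spatial frequencies x 3 phases, with
## wavelengths cycling fastest (mitigates temperature drift of the LEDs);
## the pattern (fx, phase) advances once every three frames.

#' Build the 18-slot acquisition cycle schedule
#'
#' Slots are indexed 0-17. Wavelengths cycle fastest (slots 0, 1, 2 carry
#' 660, 780, 850 nm at the same pattern), and the illumination pattern
#' advances every three frames, phases 0/120/240 degrees within each
#' spatial-frequency block. The inter-frame period is \code{1/rawRate}.
#'
#' @param rawRate raw acquisition frame rate, Hz (default 50).
#' @param wavelengths the three wavelengths, nm.
#' @param fxs the two spatial frequencies, mm^-1.
#' @param phases the three phases, degrees.
#' @return a \linkS4class{CycleSchedule}.
#' @examples
#' makeSchedule(50)
#' @export
makeSchedule <- function(rawRate = 50, wavelengths = c(660, 780, 850),
                         fxs = c(0, 0.3), phases = c(0, 120, 240)) {
  stopifnot(rawRate > 0, length(wavelengths) == 3L, length(fxs) == 2L,
            length(phases) == 3L)
  pat <- expand.grid(phase = phases, fx = fxs)[, c("fx", "phase")]
  entries <- data.frame(
    index = 0:17,
    wavelength = rep(wavelengths, times = 6L),
    fx = rep(pat$fx, each = 3L),
    phase = rep(pat$phase, each = 3L),
    offset_s = (0:17) / rawRate
  )
  new("CycleSchedule", rawRate = rawRate, entries = entries)
}

#' Effective LSI and SFDI frame rates
#'
#' Every raw frame is an LSI frame, while one complete SFDI set needs the
#' full 18-frame cycle: \code{lsi = rawRate}, \code{sfdi = rawRate/18}
#' (50 Hz raw gives 50 Hz LSI and 2.8 Hz SFDI).
#'
#' @param rawRate raw acquisition frame rate, Hz.
#' @return named list with elements \code{lsi} and \code{sfdi}, Hz.
#' @export
effectiveRates <- function(rawRate) {
  stopifnot(rawRate > 0)
  list(lsi = rawRate, sfdi = rawRate / 18)
}

#' Frame file name convention
#'
#' \code{<stream>_<cycle:06d>_<index:02d>.tiff}.
#'
#' @param stream stream name (e.g. "lsi", "sfdi").
#' @param cycle cycle number (0-based).
#' @param index slot index 0-17.
#' @return character vector of file names.
#' @export
frameFileName <- function(stream, cycle, index) {
  sprintf("%s_%06d_%02d.tiff", stream, as.integer(cycle), as.integer(index))
}

#' Read / write a frame manifest
#'
#' The manifest is a CSV with columns \code{path}, \code{modality}
#' (\code{"lsi"} or \code{"sfdi"}), \code{cycle}, \code{index} (0-17) and
#' \code{timestamp_s}.
#'
#' @param manifest manifest data.frame (for writing).
#' @param path CSV file path.
#' @return \code{readManifest} returns the manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "modality", "cycle", "index", "timestamp_s")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  m
}

#' Validate paired frame streams and reject incomplete 18-frame sets
#'
#' Groups frame records into candidate 18-frame sets keyed on the cycle
#' number and slot index (timestamps are used only for ordering and
#' reporting, so the grouping is robust to trigger jitter). A cycle is
#' accepted only if both the LSI and the SFDI stream contain all indices
#' 0-17; a dropped frame in either modality rejects the entire set in both.
#' Rejection is a reported outcome, not an error.
#'
#' @param manifest manifest data.frame (see \code{\link{readManifest}}).
#' @return list with \code{accepted} (manifest rows of accepted cycles),
#'   \code{rejected} (manifest rows of rejected cycles),
#'   \code{acceptedCycles}, \code{rejectedCycles}, and \code{report} — a
#'   data.frame of rejected cycle ids with the modality and missing indices.
#' @export
validateSets <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  manifest <- manifest[order(manifest$timestamp_s), , drop = FALSE]
  cycles <- sort(unique(manifest$cycle))
  report <- list()
  complete <- logical(length(cycles))
  for (ci in seq_along(cycles)) {
    cy <- cycles[ci]
    ok <- TRUE
    for (mod in c("lsi", "sfdi")) {
      idx <- manifest$index[manifest$cycle == cy & manifest$modality == mod]
      missing <- setdiff(0:17, idx)
      if (length(missing)) {
        ok <- FALSE
        report[[length(report) + 1L]] <- data.frame(
          cycle = cy, modality = mod,
          missing = paste(missing, collapse = ";"))
      }
    }
    complete[ci] <- ok
  }
  acceptedCycles <- cycles[complete]
  keep <- manifest$cycle %in% acceptedCycles
  list(accepted = manifest[keep, , drop = FALSE],
       rejected = manifest[!keep, , drop = FALSE],
       acceptedCycles = acceptedCycles,
       rejectedCycles = cycles[!complete],
       report = if (length(report)) do.call(rbind, report) else
         data.frame(cycle = numeric(0), modality = character(0),
                    missing = character(0)))
}
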