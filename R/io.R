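## Frame and map I/O. Raw frames are grayscale TIFF (8-bit LSI, 16-bit
## SFDI, integer counts); derived maps are written as 32-bit float TIFF
## scaled into [0, 1] with the scale factor and units recorded in a JSON
## sidecar. Time courses are CSV.

#' Write / read a raw camera frame as grayscale TIFF
#'
#' Integer counts are stored at the stated bit depth and recovered exactly.
#'
#' @param frame matrix of integer counts in \code{[0, 2^bitDepth - 1]}.
#' @param path file path.
#' @param bitDepth 8 (LSI) or 16 (SFDI).
#' @return \code{readFrameTiff} returns a matrix of integer counts.
#' @export
writeFrameTiff <- function(frame, path, bitDepth = 16L) {
  stopifnot(bitDepth %in% c(8L, 16L))
  mx <- 2^bitDepth - 1
  fr <- round(pmin(pmax(frame, 0), mx))
  tiff::writeTIFF(fr / mx, path, bits.per.sample = as.integer(bitDepth))
  invisible(path)
}

#' @rdname writeFrameTiff
#' @export
readFrameTiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "double"
  m
}

#' Write a derived map as 32-bit float TIFF with a JSON sidecar
#'
#' Values are scaled into [0, 1] for storage; the sidecar
#' (\code{<path>.json}) records the scale factor, units, NA count and any
#' extra metadata, and \code{readMapTiff} undoes the scaling and restores
#' NAs.
#'
#' @param map numeric matrix (NAs allowed).
#' @param path TIFF file path.
#' @param units unit string recorded in the sidecar (e.g. "mm^-1").
#' @param meta named list of additional metadata (wavelength, fx, ...).
#' @return \code{readMapTiff} returns the matrix with attribute
#'   \code{"meta"}.
#' @export
writeMapTiff <- function(map, path, units = "", meta = list()) {
  nInvalid <- sum(is.na(map))
  finite <- map[is.finite(map)]
  lo <- if (length(finite)) min(finite, 0) else 0
  hi <- if (length(finite)) max(finite, lo + 1) else 1
  stored <- (map - lo) / (hi - lo)
  stored[is.na(stored)] <- 0
  tiff::writeTIFF(stored, path, bits.per.sample = 32L)
  side <- c(list(units = units, offset = lo, scale = hi - lo,
                 invalid_pixels = nInvalid,
                 na_mask = which(is.na(map))), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMapTiff
#' @export
readMapTiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- m * side$scale + side$offset
  if (length(side$na_mask)) m[side$na_mask] <- NA_real_
  attr(m, "meta") <- side
  m
}

#' Write a time course as CSV
#'
#' Columns: \code{frame_index}, \code{timestamp_s}, \code{value}.
#'
#' @param values numeric vector, one per time point.
#' @param timestamps timestamps, s.
#' @param path CSV file path.
#' @export
writeTimecourseCsv <- function(values, timestamps, path) {
  stopifnot(length(values) == length(timestamps))
  utils::write.csv(data.frame(frame_index = seq_along(values) - 1L,
                              timestamp_s = timestamps, value = values),
                   path, row.names = FALSE)
  invisible(path)
}
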