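## Spatial speckle contrast pipeline: raw frame -> K -> SFI -> beta-corrected
## SFI, plus ROI time-course extraction. Only spatial contrast is computed
## (single-exposure imaging); temporal and multi-exposure variants are out of
## scope.

## Integral-image box sum; interior pixels only, NA on the border whose
## window would exit the frame.
.boxSum <- function(m, w) {
  h <- (w - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  cs <- rbind(0, cbind(0, cs))           # (nr+1) x (nc+1), cs[i+1,j+1]=sum m[1:i,1:j]
  out <- matrix(NA_real_, nr, nc)
  if (nr >= w && nc >= w) {
    i <- (h + 1L):(nr - h)
    j <- (h + 1L):(nc - h)
    out[i, j] <- cs[i + h + 1L, j + h + 1L, drop = FALSE] -
      cs[i - h, j + h + 1L, drop = FALSE] -
      cs[i + h + 1L, j - h, drop = FALSE] +
      cs[i - h, j - h, drop = FALSE]
  }
  out
}

#' Spatial speckle contrast map
#'
#' Sliding-window speckle contrast \eqn{K = \sigma(I)/\langle I\rangle}: each
#' interior pixel is assigned the ratio of the sample standard deviation
#' (denominator N-1) to the mean of the intensities in the window centred on
#' it. Pixels whose window exits the frame (a \code{(window-1)/2}-pixel
#' border) and windows with non-positive mean are flagged invalid rather than
#' padded, since padding biases K near edges.
#'
#' @param frame 2-D intensity image (counts), non-negative.
#' @param window odd sliding-window side length, pixels (default 5).
#' @param exposure camera exposure time T, seconds (default 0.010).
#' @return a \linkS4class{ContrastMap}.
#' @examples
#' f <- matrix(rexp(64 * 64, 1 / 60), 64, 64)
#' speckleContrast(f)
#' @export
speckleContrast <- function(frame, window = 5L, exposure = 0.010) {
  stopifnot(is.matrix(frame), window >= 1, window %% 2 == 1, exposure > 0)
  if (min(frame) < 0) stop("intensities must be non-negative")
  w <- as.integer(window)
  n <- w * w
  s1 <- .boxSum(frame, w)
  s2 <- .boxSum(frame * frame, w)
  mean_ <- s1 / n
  varw <- if (n > 1) pmax(s2 - s1 * s1 / n, 0) / (n - 1) else s1 * 0
  k <- sqrt(varw) / mean_
  invalid <- is.na(s1) | !(mean_ > 0)
  k[invalid] <- NA_real_
  new("ContrastMap", k = k, exposure = exposure, window = as.numeric(w),
      invalid = invalid)
}

#' Temporally pooled spatial speckle contrast of a frame stack
#'
#' Low-bias cycle-level contrast estimator: for each pixel, the window
#' variance and window mean are first averaged over the frames of the
#' stack, and the contrast is
#' \eqn{K = \sqrt{\overline{s^2}} / \overline{m}}. Averaging before the
#' ratio removes most of the finite-window sampling bias of the
#' single-frame estimator, and the residual window-correlation factor is
#' common to static and dynamic stacks, so it cancels exactly against a
#' beta factor estimated from a static stack with the same estimator.
#'
#' @param frames list of frames (matrices) or an array
#'   \code{[rows, cols, frames]}.
#' @inheritParams speckleContrast
#' @return a \linkS4class{ContrastMap}.
#' @export
cycleContrast <- function(frames, window = 5L, exposure = 0.010) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  stopifnot(is.list(frames), length(frames) >= 1L, window %% 2 == 1,
            exposure > 0)
  w <- as.integer(window)
  n <- w * w
  s2sum <- 0; msum <- 0
  for (f in frames) {
    if (min(f) < 0) stop("intensities must be non-negative")
    s1 <- .boxSum(f, w)
    s2 <- .boxSum(f * f, w)
    m1 <- s1 / n
    s2sum <- s2sum + pmax(s2 - s1 * s1 / n, 0) / (n - 1)
    msum <- msum + m1
  }
  nf <- length(frames)
  mbar <- msum / nf
  k <- sqrt(s2sum / nf) / mbar
  invalid <- is.na(mbar) | !(mbar > 0)
  k[invalid] <- NA_real_
  new("ContrastMap", k = k, exposure = exposure, window = as.numeric(w),
      invalid = invalid)
}

#' Speckle flow index from a contrast map
#'
#' Simplified single-exposure flow metric \eqn{SFI = 1/(2 T K^2)} (units
#' s^-1), approximating the inverse field decorrelation time. Pixels with
#' K = 0 (formally infinite flow index) and pixels already invalid in the
#' contrast map are flagged invalid.
#'
#' @param c a \linkS4class{ContrastMap}.
#' @return a \linkS4class{FlowMap} with \code{kind = "sfi"}.
#' @examples
#' k <- matrix(0.5, 8, 8)
#' cm <- new("ContrastMap", k = k, exposure = 0.01, window = 5,
#'           invalid = matrix(FALSE, 8, 8))
#' mapValues(sfi(cm))[1, 1]  # 200 s^-1
#' @export
sfi <- function(c) {
  stopifnot(is(c, "ContrastMap"))
  invalid <- c@invalid | (!is.na(c@k) & c@k == 0)
  v <- 1 / (2 * c@exposure * c@k^2)
  v[invalid] <- NA_real_
  new("FlowMap", values = v, kind = "sfi", invalid = invalid)
}

#' Circular region-of-interest mask
#'
#' @param dims image dimensions (rows, cols).
#' @param center ROI centre (row, col), pixels; defaults to the image centre.
#' @param radius ROI radius, pixels.
#' @return logical matrix, TRUE inside the ROI.
#' @export
circularRoi <- function(dims, radius, center = (dims + 1) / 2) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Estimate the speckle normalization factor beta from a static phantom
#'
#' For a static phantom measured with exposure much shorter than the
#' decorrelation time, beta is approximated as the squared speckle contrast.
#' The median contrast over the ROI (invalid pixels excluded) is used so the
#' estimate is robust to up to 50\% contaminated pixels.
#'
#' @param staticPhantomContrast a \linkS4class{ContrastMap} measured on a
#'   static phantom.
#' @param roi logical mask of the ROI (defaults to all valid pixels).
#' @param source identifier recorded with the estimate.
#' @return a \linkS4class{BetaFactor}.
#' @export
estimateBeta <- function(staticPhantomContrast, roi = NULL,
                         source = "static-phantom") {
  stopifnot(is(staticPhantomContrast, "ContrastMap"))
  k <- staticPhantomContrast@k
  use <- !staticPhantomContrast@invalid
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(k)))
    use <- use & roi
  }
  if (!any(use)) stop("ROI contains no valid contrast pixels")
  kmed <- stats::median(k[use])
  new("BetaFactor", beta = kmed^2, source = source)
}

#' Apply the beta correction to a flow map
#'
#' \eqn{SFI_{\beta\text{-corrected}} = \beta \cdot SFI}. A common scalar
#' factor, so time courses normalized to their initial value are invariant
#' to it.
#'
#' @param f a \linkS4class{FlowMap}.
#' @param b a \linkS4class{BetaFactor} (or a plain number in (0, 1]).
#' @return a \linkS4class{FlowMap} of the same kind.
#' @export
betaCorrect <- function(f, b) {
  stopifnot(is(f, "FlowMap"))
  beta <- if (is(b, "BetaFactor")) b@beta else as.numeric(b)
  stopifnot(length(beta) == 1L, beta > 0, beta <= 1)
  new("FlowMap", values = f@values * beta, kind = f@kind, invalid = f@invalid)
}

## Centred moving average with partial windows at the series edges (a
## constant series is left unchanged). For even lengths the window extends
## one sample further forward than backward.
.movingAverage <- function(x, len) {
  n <- length(x)
  if (len > n) stop("filter length exceeds series length")
  if (len == 1L) return(x)
  back <- floor((len - 1) / 2)
  fwd <- ceiling((len - 1) / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) + fwd, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' ROI median time course with moving-average filtering
#'
#' Extracts, for each map in a sequence, the median value within a region of
#' interest (invalid pixels excluded), then applies a centred moving-average
#' filter of the stated length.
#'
#' @param maps list of \linkS4class{FlowMap} / \linkS4class{ContrastMap}
#'   objects or plain matrices, one per time point.
#' @param roi logical ROI mask matching the map dimensions.
#' @param filterLen moving-average length in frames (>= 1); 1 returns the
#'   raw median series.
#' @return numeric vector, one value per time point.
#' @export
roiTimecourse <- function(maps, roi, filterLen = 1L) {
  stopifnot(is.list(maps), length(maps) >= 1L, filterLen >= 1)
  med <- vapply(maps, function(m) {
    inv <- NULL
    if (is.matrix(m)) {
      v <- m
    } else {
      v <- mapValues(m)
      if (existsMethod("invalidMask", class(m))) inv <- invalidMask(m)
    }
    stopifnot(identical(dim(roi), dim(v)))
    use <- roi
    if (!is.null(inv)) use <- use & !inv
    use <- use & !is.na(v)
    if (!any(use)) return(NA_real_)
    stats::median(v[use])
  }, numeric(1))
  .movingAverage(med, as.integer(filterLen))
}
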