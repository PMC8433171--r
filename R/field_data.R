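## Reduction of field-video detections: perspective camera-to-ground-plane
## transform, two-axis ellipsoid body volumes, and a synthetic camera-scene
## generator so the whole pipeline is testable without video.
##
## Pixel convention: (x_c, y_c) in [0, x_cm] x [0, y_cm], with the image
## centre mapping to the field origin. Larger y_c means closer to the
## camera (smaller ground y_r).

#' Construct camera parameters
#'
#' @param tilt angle between ground plane and camera-plane normal (radians;
#'   append `"deg"` handling yourself or use `degrees()`).
#' @param hfov horizontal view angle (radians).
#' @param h camera height over the ground (field units, e.g. metres).
#' @param x_cm,y_cm horizontal and vertical resolution (pixels).
#' @return a validated [CameraParams-class] object.
#' @examples
#' cam <- cameraParams(tilt = 0.9, hfov = 1.0, h = 1.5,
#'                     x_cm = 1920, y_cm = 1080)
#' cameraToField(960, 540, cam)  # image centre -> origin
#' @export
cameraParams <- function(tilt, hfov, h, x_cm, y_cm) {
  new("CameraParams", tilt = tilt, hfov = hfov, h = h,
      x_cm = as.numeric(x_cm), y_cm = as.numeric(y_cm))
}

#' Convert degrees to radians
#'
#' Convenience for configs quoting camera angles in degrees.
#'
#' @param deg angle in degrees.
#' @return angle in radians.
#' @export
degrees <- function(deg) deg * pi / 180

setMethod("show", "CameraParams", function(object) {
  cat(sprintf(
    "CameraParams: tilt %.4g rad, hfov %.4g rad, h %.4g, %d x %d px\n",
    object@tilt, object@hfov, object@h,
    as.integer(object@x_cm), as.integer(object@y_cm)))
  invisible(object)
})

#' Camera-to-field perspective transform
#'
#' Maps pixel coordinates to ground-plane field coordinates:
#' \deqn{y_r = h[\cot(\alpha + \tan^{-1}((2 y_c - y_{cm})/x_{cm}
#'   \tan(\beta/2))) - \cot\alpha]}
#' \deqn{x_r = (2 x_c - x_{cm})/x_{cm} \; h \sqrt{1 + (y_r/h +
#'   \cot\alpha)^2} \tan(\beta/2)}
#' with \eqn{\alpha} the tilt, \eqn{\beta} the horizontal view angle and
#' `h` the camera height.
#'
#' @param x_c,y_c pixel coordinates (vectorised).
#' @param cam a [CameraParams-class] object.
#' @return data.frame with columns `x_r`, `y_r`.
#' @export
cameraToField <- function(x_c, y_c, cam) {
  stopifnot(length(x_c) == length(y_c))
  a <- cam@tilt
  tb2 <- tan(cam@hfov / 2)
  psi <- atan((2 * y_c - cam@y_cm) / cam@x_cm * tb2)
  ang <- a + psi
  bad <- which(ang <= 0 | ang >= pi)
  if (length(bad))
    stop("ray at or above the horizon for input row(s): ",
         paste(bad, collapse = ", "))
  y_r <- cam@h * (1 / tan(ang) - 1 / tan(a))
  x_r <- (2 * x_c - cam@x_cm) / cam@x_cm * cam@h *
    sqrt(1 + (y_r / cam@h + 1 / tan(a))^2) * tb2
  data.frame(x_r = x_r, y_r = y_r)
}

#' Field-to-camera inverse transform
#'
#' Exact inverse of [cameraToField()] on the imageable domain; the
#' round-trip agrees to better than 1e-9 pixels. Points behind the camera
#' (not representable by any view ray) raise an error.
#'
#' @param x_r,y_r field coordinates (vectorised).
#' @param cam a [CameraParams-class] object.
#' @return data.frame with columns `x_c`, `y_c`.
#' @export
fieldToCamera <- function(x_r, y_r, cam) {
  stopifnot(length(x_r) == length(y_r))
  a <- cam@tilt
  tb2 <- tan(cam@hfov / 2)
  ctg <- y_r / cam@h + 1 / tan(a)
  ang <- pi / 2 - atan(ctg)  # acot with range (0, pi)
  psi <- ang - a
  bad <- which(psi <= -pi / 2 + 1e-12 | psi >= pi / 2 - 1e-12)
  if (length(bad))
    stop("point not imageable (behind the camera) for row(s): ",
         paste(bad, collapse = ", "))
  y_c <- (cam@y_cm + cam@x_cm * tan(psi) / tb2) / 2
  x_c <- (cam@x_cm + cam@x_cm * x_r / (cam@h * sqrt(1 + ctg^2) * tb2)) / 2
  data.frame(x_c = x_c, y_c = y_c)
}

#' Local ground scale of a pixel
#'
#' Field units per pixel around a pixel position, computed as the square
#' root of the absolute Jacobian determinant of [cameraToField()] by central
#' differences. Used to convert measured pixel body lengths to field
#' lengths; an isotropic approximation (perspective foreshortening differs
#' along and across the view axis).
#'
#' @param x_c,y_c pixel coordinates (vectorised).
#' @param cam a [CameraParams-class] object.
#' @param hPx finite-difference step in pixels.
#' @return numeric vector of scales.
#' @export
localPixelScale <- function(x_c, y_c, cam, hPx = 0.5) {
  fx <- cameraToField(x_c + hPx, y_c, cam)
  fx0 <- cameraToField(x_c - hPx, y_c, cam)
  fy <- cameraToField(x_c, y_c + hPx, cam)
  fy0 <- cameraToField(x_c, y_c - hPx, cam)
  j11 <- (fx$x_r - fx0$x_r) / (2 * hPx)
  j21 <- (fx$y_r - fx0$y_r) / (2 * hPx)
  j12 <- (fy$x_r - fy0$x_r) / (2 * hPx)
  j22 <- (fy$y_r - fy0$y_r) / (2 * hPx)
  sqrt(abs(j11 * j22 - j12 * j21))
}

#' Two-axis ellipsoid body volume
#'
#' `V = (pi/6) * length * width^2 * thicknessFactor`: an ellipsoid with
#' semi-axes `length/2, width/2, width/2`, i.e. body thickness taken equal
#' to body width. The unknown thickness-to-width ratio enters as a
#' configurable constant factor.
#'
#' @param length,width body axes in field units, `length >= width > 0`
#'   (vectorised).
#' @param thicknessFactor multiplicative correction for the
#'   thickness-to-width ratio (default 1).
#' @return volume(s).
#' @export
ellipsoidVolume <- function(length, width, thicknessFactor = 1) {
  if (any(!(width > 0)) || any(!(length > 0)))
    stop("body axes must be positive")
  if (any(length < width))
    stop("body length must be >= body width")
  pi / 6 * length * width^2 * thicknessFactor
}

#' Synthesize a camera detection table from ground truth
#'
#' Projects known field positions and body axes through [fieldToCamera()],
#' adds Gaussian pixel noise, and emits the detection table the reduction
#' pipeline consumes — a synthetic stand-in for a processed field video.
#'
#' @param truth data.frame with columns `x_r, y_r, len, wid` (field units)
#'   and optionally `frame`.
#' @param cam a [CameraParams-class] object.
#' @param sigmaPx standard deviation of the Gaussian pixel noise added to
#'   the detected centre coordinates (body axes are measured from many
#'   painted pixels and are left noise-free).
#' @param seed optional RNG seed.
#' @return data.frame `frame, x_c, y_c, len_px, wid_px`.
#' @export
synthesizeScene <- function(truth, cam, sigmaPx = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("x_r", "y_r", "len", "wid") %in% names(truth)))
  px <- fieldToCamera(truth$x_r, truth$y_r, cam)
  s <- localPixelScale(px$x_c, px$y_c, cam)
  n <- nrow(truth)
  data.frame(
    frame = if ("frame" %in% names(truth)) truth$frame else rep(1L, n),
    x_c = px$x_c + rnorm(n, 0, sigmaPx),
    y_c = px$y_c + rnorm(n, 0, sigmaPx),
    len_px = truth$len / s,
    wid_px = truth$wid / s)
}

#' Reduce a detection table to field coordinates and volumes
#'
#' Applies [cameraToField()] to detection centres, converts pixel body axes
#' to field lengths with the local ground scale and computes two-axis
#' ellipsoid volumes.
#'
#' @param detections data.frame `frame, x_c, y_c, len_px, wid_px` (as
#'   written by [synthesizeScene()] or a video-processing step).
#' @param cam a [CameraParams-class] object.
#' @param thicknessFactor passed to [ellipsoidVolume()].
#' @return data.frame `frame, x_r, y_r, len, wid, volume`.
#' @export
reduceDetections <- function(detections, cam, thicknessFactor = 1) {
  stopifnot(all(c("x_c", "y_c", "len_px", "wid_px") %in% names(detections)))
  fd <- cameraToField(detections$x_c, detections$y_c, cam)
  s <- localPixelScale(detections$x_c, detections$y_c, cam)
  len <- detections$len_px * s
  wid <- detections$wid_px * s
  data.frame(
    frame = if ("frame" %in% names(detections)) detections$frame else 1L,
    x_r = fd$x_r, y_r = fd$y_r, len = len, wid = wid,
    volume = ellipsoidVolume(pmax(len, wid), pmin(len, wid),
                             thicknessFactor))
}

#' Consistency check of a camera calibration against the surface-wave speed
#'
#' Field calibrations of the tilt and height can be checked against the
#' known speed of capillary-gravity surface waves (0.24 m/s): given pixel
#' positions of a wave front at known times (taken along the image centre
#' column), the front positions are transformed to field coordinates and a
#' straight line is fitted; the fitted speed should match the reference.
#' This is a checker for a user-supplied calibration, not an auto-fitter.
#'
#' @param cam a [CameraParams-class] object.
#' @param times observation times (seconds).
#' @param y_c pixel row of the wave front at each time.
#' @param waveSpeed reference speed in field units per second.
#' @return list with the fitted `speed`, the `relError` against the
#'   reference, and the fitted front positions `y_r`.
#' @export
checkWaveCalibration <- function(cam, times, y_c, waveSpeed = 0.24) {
  stopifnot(length(times) == length(y_c), length(times) >= 2L)
  fr <- cameraToField(rep(cam@x_cm / 2, length(y_c)), y_c, cam)
  fit <- lm(fr$y_r ~ times)
  speed <- abs(unname(coef(fit)[2]))
  list(speed = speed, relError = (speed - waveSpeed) / waveSpeed,
       y_r = fr$y_r)
}
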