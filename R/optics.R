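#' Frame averaging
#'
#' Pixel-wise arithmetic mean of repeated exposures of the same field,
#' the usual way to beat down sensor read noise before densitometry
#' (averaging k frames divides the noise standard deviation by sqrt(k)).
#'
#' @param frames a list of numeric matrices / `image_plane`s with identical
#'   dimensions, or a 3-D array with frames along the third dimension.
#' @return An `image_plane` of kind `"intensity"`.
#' @export
average_frames <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) < 1L) {
    stop("need at least one frame", call. = FALSE)
  }
  px <- attr(frames[[1]], "pixel_size_um") %||% 0.45
  mats <- lapply(frames, as_plane_matrix)
  d <- dim(mats[[1]])
  ok <- vapply(mats, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("frames have mismatched dimensions", call. = FALSE)
  acc <- Reduce(`+`, mats) / length(mats)
  image_plane(acc, "intensity", pixel_size_um = px)
}

#' Green-channel extraction
#'
#' The green channel covers the absorption peak of the Feulgen-DNA dye
#' complex, so densitometry is performed on it alone.
#'
#' @param rgb height x width x 3 numeric array (R, G, B), or a matrix
#'   (already single-channel; passed through with a warning).
#' @param pixel_size_um micrometres per pixel recorded on the output plane.
#' @return An `image_plane` of kind `"intensity"`.
#' @export
extract_green <- function(rgb, pixel_size_um = 0.45) {
  if (is.matrix(rgb) || is_image_plane(rgb)) {
    warning("input is already single-channel; passing it through")
    return(image_plane(as_plane_matrix(rgb), "intensity", pixel_size_um))
  }
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] >= 3L)) {
    stop("expected an RGB array (height x width x 3)", call. = FALSE)
  }
  image_plane(rgb[, , 2], "intensity", pixel_size_um = pixel_size_um)
}

#' Background correction by the transmittance-ratio method
#'
#' Divides the sample image by a blank-field (clear area) image taken under
#' the same illumination, yielding per-pixel transmittance in (0, 1]. A
#' per-pixel blank removes illumination gradients exactly; a scalar blank
#' (e.g. the mean grey level of a clear region) is supported when no blank
#' frame exists.
#'
#' @param sample intensity plane of the stained field.
#' @param blank intensity plane of the blank field, or a positive scalar.
#' @param od_max optical-density ceiling; transmittances below
#'   `10^(-od_max)` are clipped to that floor.
#' @return An `image_plane` of transmittance values in `(0, 1]` (kind
#'   `"intensity"`).
#' @export
background_correct <- function(sample, blank, od_max = 3) {
  s <- as_plane_matrix(sample)
  px <- attr(sample, "pixel_size_um") %||% 0.45
  if (length(blank) == 1L) {
    if (!is.finite(blank) || blank <= 0) {
      stop("scalar blank must be positive", call. = FALSE)
    }
    b <- matrix(blank, nrow(s), ncol(s))
  } else {
    b <- as_plane_matrix(blank)
    if (!identical(dim(b), dim(s))) {
      stop("sample and blank dimensions differ", call. = FALSE)
    }
    if (any(b <= 0)) {
      stop("blank field contains non-positive pixels", call. = FALSE)
    }
  }
  eps <- 10^(-od_max)
  tr <- pmin(pmax(s / b, eps), 1)
  image_plane(tr, "intensity", pixel_size_um = px)
}

#' Transmittance to optical density
#'
#' Per-pixel OD = -log10(T). Transmittance at 1 gives OD 0; values at or
#' below `10^(-od_max)` saturate at `od_max` (an 8-bit sensor cannot
#' resolve more than about 3 OD units).
#'
#' @param transmittance plane of values in `(0, 1]` (see
#'   [background_correct()]).
#' @param od_max OD ceiling, default 3.
#' @return An `image_plane` of kind `"optical_density"`.
#' @export
to_optical_density <- function(transmittance, od_max = 3) {
  tr <- as_plane_matrix(transmittance)
  px <- attr(transmittance, "pixel_size_um") %||% 0.45
  if (any(tr > 1 + 1e-9)) {
    stop("transmittance values above 1; run background_correct first",
         call. = FALSE)
  }
  eps <- 10^(-od_max)
  od <- -log10(pmax(tr, eps))
  image_plane(pmin(od, od_max), "optical_density", pixel_size_um = px)
}

#' Full optical chain: frames to an OD plane
#'
#' Convenience wrapper: average frames, take the green channel, correct
#' against the blank field and convert to optical density.
#'
#' @param frames list of RGB arrays (or one array) of the stained field.
#' @param blank_frames list of RGB arrays (or one array) of the blank
#'   field, or a positive scalar incident-light level.
#' @param pixel_size_um micrometres per pixel.
#' @param od_max OD ceiling.
#' @return An `image_plane` of kind `"optical_density"`.
#' @export
frames_to_od <- function(frames, blank_frames, pixel_size_um = 0.45,
                         od_max = 3) {
  green_of <- function(x) {
    if (is.list(x)) {
      average_frames(lapply(x, function(f) {
        as_plane_matrix(extract_green(f, pixel_size_um))
      }))
    } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] >= 3L) {
      extract_green(x, pixel_size_um)
    } else {
      image_plane(as_plane_matrix(x), "intensity", pixel_size_um)
    }
  }
  g <- green_of(frames)
  b <- if (length(blank_frames) == 1L && is.numeric(blank_frames)) {
    blank_frames
  } else {
    green_of(blank_frames)
  }
  to_optical_density(background_correct(g, b, od_max), od_max)
}
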