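#' A 2-D scalar image plane
#'
#' Lightweight container used throughout the package: a numeric matrix
#' (`[row, col]`, row 1 at the top) carrying its value kind (raw/transmitted
#' intensity or optical density) and the physical pixel size.
#'
#' Coordinates reported by downstream functions are 0-based with x running
#' right (columns) and y running down (rows); pixel centres sit at integer
#' coordinates.
#'
#' @param pixels numeric matrix of pixel values.
#' @param value_kind `"intensity"` or `"optical_density"`.
#' @param pixel_size_um micrometres per pixel. The default 0.45 corresponds
#'   to a 40x objective on the type of camera used for Feulgen cytometry
#'   work this package targets.
#' @return An `image_plane` object (a classed numeric matrix).
#' @export
image_plane <- function(pixels,
                        value_kind = c("intensity", "optical_density"),
                        pixel_size_um = 0.45) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (value_kind == "intensity" && any(pixels < 0, na.rm = TRUE)) {
    stop("intensity planes must be non-negative", call. = FALSE)
  }
  structure(pixels,
            value_kind = value_kind,
            pixel_size_um = pixel_size_um,
            class = c("image_plane", "matrix", "array"))
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d, kind = %s, pixel size = %g um\n",
              nrow(x), ncol(x), attr(x, "value_kind"),
              attr(x, "pixel_size_um")))
  cat(sprintf("  value range [%g, %g]\n",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' @rdname image_plane
#' @param x object to test.
#' @export
is_image_plane <- function(x) inherits(x, "image_plane")

value_kind <- function(x) attr(x, "value_kind") %||% "intensity"

`%||%` <- function(a, b) if (is.null(a)) b else a

as_plane_matrix <- function(x) {
  if (is_image_plane(x)) {
    m <- unclass(x)
    attr(m, "value_kind") <- NULL
    attr(m, "pixel_size_um") <- NULL
    m
  } else if (is.matrix(x)) {
    x
  } else {
    stop("expected a matrix or image_plane", call. = FALSE)
  }
}

#' Read and write images as PNG
#'
#' Greyscale planes are stored as 8- or 16-bit PNG; RGB scenes as 8-bit
#' colour PNG; label masks as 16-bit greyscale PNG holding the integer
#' label values. `max_value` sets the grey level that maps to 1.0 in the
#' PNG encoding (255 for 8-bit data).
#'
#' @param path file path.
#' @param image matrix (greyscale) or height x width x 3 array (RGB) of
#'   values in `[0, max_value]`.
#' @param max_value full-scale value of the data (default 255).
#' @param bit_depth 8 or 16.
#' @return `read_image_png` returns a matrix or 3-D array scaled back to
#'   `[0, max_value]`; `read_label_png` an integer matrix of labels.
#' @export
write_image_png <- function(image, path, max_value = 255, bit_depth = 8L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  img <- if (is_image_plane(image)) as_plane_matrix(image) else image
  img <- pmin(pmax(img / max_value, 0), 1)
  png::writePNG(img, target = path,
                dpi = NULL, asp = NULL, text = NULL,
                metadata = NULL)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path, max_value = 255) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img * max_value
}

#' @rdname write_image_png
#' @param labels integer matrix of region labels (0 = background).
#' @details Label masks hold up to 65535 labels: the high byte goes to the
#'   red channel and the low byte to the green channel of an 8-bit RGB PNG
#'   (the `png` package writes 8 bits per channel).
#' @export
write_label_png <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  hi <- labels %/% 256L
  lo <- labels %% 256L
  arr <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  arr[, , 1] <- hi / 255
  arr[, , 2] <- lo / 255
  png::writePNG(arr, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3L) {
    return(matrix(as.integer(round(img * 255)), nrow = nrow(img)))
  }
  hi <- round(img[, , 1] * 255)
  lo <- round(img[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo), nrow = dim(img)[1])
}
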