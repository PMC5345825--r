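#' Otsu's threshold
#'
#' Histogram-based threshold maximising the between-class variance. The
#' value returned is a bin edge of an `n_bins` histogram spanning the data
#' range; among tied maximisers the lowest edge is returned. On Feulgen
#' intensity images the nuclei are the dark class, i.e. foreground is
#' `pixels < threshold`.
#'
#' @param plane numeric matrix or `image_plane`.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold value (scalar).
#' @export
otsu_threshold <- function(plane, n_bins = 256L) {
  x <- as.vector(as_plane_matrix(plane))
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("constant image: no threshold exists", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- as.numeric(tabulate(idx, nbins = n_bins))
  centres <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(counts)
  w1 <- sum(counts) - w0
  s0 <- cumsum(counts * centres)
  mu_tot <- s0[n_bins] / w0[n_bins]
  # candidate cut after bin j separates bins 1..j from j+1..n_bins
  j <- seq_len(n_bins - 1L)
  mu0 <- s0[j] / w0[j]
  mu1 <- (s0[n_bins] - s0[j]) / w1[j]
  bcv <- w0[j] * w1[j] * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- -Inf
  best <- which(bcv >= max(bcv) - 1e-12 * abs(max(bcv)))[1]
  breaks[best + 1L]
}

#' Binarise an image plane
#'
#' @param plane numeric matrix or `image_plane`.
#' @param threshold threshold value (e.g. from [otsu_threshold()]).
#' @param dark_foreground if `TRUE` (intensity images) foreground is
#'   `< threshold`; set `FALSE` for OD planes where nuclei are bright.
#' @return Integer matrix, 1 = foreground, 0 = background.
#' @export
binarize <- function(plane, threshold, dark_foreground = TRUE) {
  m <- as_plane_matrix(plane)
  fg <- if (dark_foreground) m < threshold else m > threshold
  matrix(as.integer(fg), nrow(m), ncol(m))
}

#' Connected-component labelling
#'
#' @param mask integer/logical matrix; nonzero = foreground.
#' @param connectivity 8 (default, standard for foreground) or 4.
#' @return Integer matrix of labels 1..k (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  cpp_label(to_int_mask(mask), as.integer(connectivity))
}

to_int_mask <- function(mask) {
  m <- as_plane_matrix(if (is.logical(mask)) mask * 1L else mask)
  storage.mode(m) <- "integer"
  m
}

#' Remove objects touching the image border
#'
#' Incomplete nuclei overlapping the frame edge bias both morphometry and
#' densitometry, so any connected component with a pixel on the first or
#' last row/column is deleted.
#'
#' @param mask binary or labelled integer matrix.
#' @return Matrix of the same kind with edge-touching components removed.
#' @export
remove_edge_objects <- function(mask) {
  m <- to_int_mask(mask)
  lab <- if (max(m) > 1L) m else cpp_label(m, 8L)
  nr <- nrow(lab); nc <- ncol(lab)
  edge <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  edge <- edge[edge > 0L]
  out <- m
  out[lab %in% edge] <- 0L
  out
}

#' Fill interior holes
#'
#' Background regions (4-connected) not reaching the image border are
#' converted to foreground. Applied before the watershed so that chromatin
#' texture dropouts inside a nucleus do not fragment it.
#'
#' @param mask binary integer matrix.
#' @return Binary integer matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- to_int_mask(mask)
  bg <- matrix(as.integer(m == 0L), nrow(m), ncol(m))
  lab <- cpp_label(bg, 4L)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  hole <- lab > 0L & !(lab %in% border)
  out <- m
  out[hole] <- 1L
  out
}

shift_mat <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

smooth3 <- function(m) {
  acc <- matrix(0, nrow(m), ncol(m))
  wt <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    s <- shift_mat(m, dr, dc, fill = NA)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    wt <- wt + ok
  }
  acc / wt
}

#' Watershed separation of touching nuclei
#'
#' Distance-transform watershed: the exact Euclidean distance transform of
#' the binary mask is lightly smoothed and thresholded, within each
#' connected component, at `seed_frac` times the component's distance
#' maximum; the connected pieces of that core region become the seeds of a
#' Meyer flooding. Two touching convex nuclei produce two cores (the neck
#' between them is shallow), while a single elongated nucleus keeps one
#' core along its flat distance ridge, so it is not oversplit. Seed cores
#' of the same component whose centroids are closer than `min_distance`
#' are merged. Watershed lines are returned as background, so the union of
#' the output labels is a subset of the input mask and no pixel belongs to
#' two labels.
#'
#' @param mask binary integer matrix.
#' @param min_distance merge radius for seed cores in pixels (default 5).
#' @param seed_frac fraction of the per-component distance maximum that
#'   defines the seed cores (default 0.75; it must exceed the neck-to-
#'   radius depth ratio of the overlaps that should be split).
#' @param smooth logical; smooth the distance transform with a 3x3 mean
#'   before seed picking (default `TRUE`).
#' @return Integer label matrix.
#' @export
watershed_split <- function(mask, min_distance = 5, seed_frac = 0.75,
                            smooth = TRUE) {
  m <- to_int_mask(mask)
  m[m != 0L] <- 1L
  if (all(m == 0L)) return(m)
  d <- sqrt(cpp_edt_sq(m))
  ds <- if (smooth) smooth3(d) else d
  ds[m == 0L] <- 0
  comp <- cpp_label(m, 8L)
  ncomp <- max(comp)
  compmax <- vapply(seq_len(ncomp), function(k) max(ds[comp == k]),
                    numeric(1))
  core <- matrix(as.integer(m == 1L & ds >= seed_frac * compmax[pmax(comp,
                                                                     1L)]),
                 nrow(m), ncol(m))
  seeds <- cpp_label(core, 8L)
  ns <- max(seeds)
  if (ns > 1L && min_distance > 0) {
    # merge seed cores of the same component closer than min_distance
    idx <- which(seeds > 0L, arr.ind = TRUE)
    sid <- seeds[seeds > 0L]
    cx <- tapply(idx[, 2], sid, mean)
    cy <- tapply(idx[, 1], sid, mean)
    sc <- vapply(seq_len(ns), function(k) comp[seeds == k][1], integer(1))
    parent <- seq_len(ns)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        if (sc[i] == sc[j] &&
            (cx[i] - cx[j])^2 + (cy[i] - cy[j])^2 < min_distance^2) {
          parent[find(j)] <- find(i)
        }
      }
    }
    remap <- vapply(seq_len(ns), find, integer(1))
    remap <- match(remap, sort(unique(remap)))
    pos <- seeds > 0L
    seeds[pos] <- remap[seeds[pos]]
  }
  cpp_watershed(d, seeds, m)
}

#' Size filtering of labelled regions
#'
#' Keeps labels whose pixel count lies in `[min_px, max_px]` (inclusive).
#' The published bounds for single mussel-haemocyte nuclei are 25 and 300
#' pixels; both are exposed because larger neoplastic nuclei (mean area
#' above 400 px^2) require a wider upper bound.
#'
#' @param labels integer label matrix.
#' @param min_px,max_px inclusive pixel-count bounds (defaults 25, 300).
#' @param relabel renumber surviving labels 1..k (default `TRUE`).
#' @return Integer label matrix.
#' @export
size_filter <- function(labels, min_px = 25L, max_px = 300L, relabel = TRUE) {
  if (min_px > max_px) stop("min_px must be <= max_px", call. = FALSE)
  lab <- to_int_mask(labels)
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  ids <- which(sizes >= min_px & sizes <= max_px)
  map <- integer(max(lab))
  map[ids] <- if (relabel) seq_along(ids) else ids
  out <- lab
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  out
}

#' Label-preserving dilation
#'
#' Grows every label by one 8-connected shell per iteration; a pixel
#' reachable from two or more distinct labels in the same iteration stays
#' background, so touching regions never merge and the label count is
#' unchanged.
#'
#' @param labels integer label matrix.
#' @param iterations number of dilation shells (default 1).
#' @return Integer label matrix.
#' @export
dilate_no_merge <- function(labels, iterations = 1L) {
  cpp_dilate_no_merge(to_int_mask(labels), as.integer(iterations))
}

#' Remove labels overlapping an exclusion mask
#'
#' Automated stand-in for manual editing away of non-target nuclei: any
#' label whose overlap fraction with the exclusion mask exceeds
#' `max_overlap` is deleted.
#'
#' @param labels integer label matrix.
#' @param exclusion binary matrix of the same dimensions (nonzero =
#'   excluded territory).
#' @param max_overlap overlap fraction above which a label is removed
#'   (default 0.5).
#' @return Integer label matrix (original label ids kept).
#' @export
apply_exclusion <- function(labels, exclusion, max_overlap = 0.5) {
  lab <- to_int_mask(labels)
  ex <- to_int_mask(exclusion)
  if (!identical(dim(lab), dim(ex))) {
    stop("exclusion mask dimensions differ from labels", call. = FALSE)
  }
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  inter <- tabulate(lab[lab > 0L & ex != 0L], nbins = max(lab))
  drop <- which(sizes > 0L & inter / pmax(sizes, 1L) > max_overlap)
  out <- lab
  out[lab %in% drop] <- 0L
  out
}

#' Segment nuclei in a green-channel intensity image
#'
#' The full chain: Otsu threshold (dark class) -> hole filling ->
#' edge-object removal -> watershed separation -> size filter ->
#' label-preserving dilation -> optional exclusion mask.
#'
#' @param plane intensity plane (nuclei dark) or OD plane (set
#'   `dark_foreground = FALSE`).
#' @param n_bins histogram bins for Otsu.
#' @param dark_foreground polarity flag, see [binarize()].
#' @param watershed apply watershed separation (default `TRUE`).
#' @param min_distance watershed seed separation.
#' @param min_px,max_px size-filter bounds.
#' @param dilate_iters dilation shells applied after size filtering
#'   (default 0; the masks from Otsu already fit the rendered nuclei).
#' @param exclusion optional exclusion mask.
#' @param max_overlap exclusion overlap threshold.
#' @return Integer label matrix with labels 1..k.
#' @export
segment_nuclei <- function(plane, n_bins = 256L, dark_foreground = TRUE,
                           watershed = TRUE, min_distance = 5,
                           min_px = 25L, max_px = 300L, dilate_iters = 0L,
                           exclusion = NULL, max_overlap = 0.5) {
  thr <- otsu_threshold(plane, n_bins)
  mask <- binarize(plane, thr, dark_foreground)
  mask <- fill_holes(mask)
  mask <- remove_edge_objects(mask)
  lab <- if (watershed) {
    watershed_split(mask, min_distance = min_distance)
  } else {
    cpp_label(mask, 8L)
  }
  lab <- size_filter(lab, min_px = min_px, max_px = max_px)
  if (dilate_iters > 0L) lab <- dilate_no_merge(lab, dilate_iters)
  if (!is.null(exclusion)) lab <- apply_exclusion(lab, exclusion, max_overlap)
  lab
}
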