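#' Trace the outer boundary of a region
#'
#' Moore-neighbour tracing through pixel centres. The polygon is closed
#' (last vertex connects back to the first) and follows the 8-connected
#' outer contour; a single-pixel region yields a one-point polygon.
#'
#' @param mask binary matrix of the region (nonzero = inside).
#' @return n x 2 matrix of 0-based (x, y) boundary pixel centres, in trace
#'   order.
#' @export
trace_boundary <- function(mask) {
  rc <- cpp_trace_boundary(to_int_mask(mask))
  cbind(x = rc[, 2] - 1L, y = rc[, 1] - 1L)
}

poly_perimeter <- function(P) {
  n <- nrow(P)
  if (n < 2L) return(0)
  Q <- rbind(P, P[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(Q)^2)))
}

# minimum distance from point q to the closed polygon's edges
point_polygon_dist <- function(q, P) {
  A <- P
  B <- P[c(2:nrow(P), 1), , drop = FALSE]
  ab <- B - A
  len2 <- rowSums(ab^2)
  aq1 <- q[1] - A[, 1]; aq2 <- q[2] - A[, 2]
  t <- (aq1 * ab[, 1] + aq2 * ab[, 2]) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  px <- A[, 1] + t * ab[, 1]
  py <- A[, 2] + t * ab[, 2]
  min(sqrt((q[1] - px)^2 + (q[2] - py)^2))
}

poly_area <- function(P) {
  n <- nrow(P)
  if (n < 3L) return(0)
  x <- P[, 1]; y <- P[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

circle_from2 <- function(a, b) {
  list(centre = (a + b) / 2, r = sqrt(sum((a - b)^2)) / 2)
}

circle_from3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    # collinear: smallest pair circle covering all three
    cand <- list(circle_from2(a, b), circle_from2(a, c), circle_from2(b, c))
    pts <- rbind(a, b, c)
    ok <- vapply(cand, function(ci) {
      all(sqrt(rowSums((pts - rep(ci$centre, each = 3))^2)) <= ci$r + 1e-9)
    }, logical(1))
    cand <- cand[ok]
    rs <- vapply(cand, `[[`, numeric(1), "r")
    return(cand[[which.min(rs)]])
  }
  ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
           (sum(c^2)) * (a[2] - b[2])) / d
  uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
           (sum(c^2)) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(centre = ctr, r = sqrt(sum((a - ctr)^2)))
}

trivial_circle <- function(R) {
  n <- if (is.null(R)) 0L else nrow(R)
  if (n == 0L) return(list(centre = c(0, 0), r = -1))
  if (n == 1L) return(list(centre = R[1, ], r = 0))
  if (n == 2L) return(circle_from2(R[1, ], R[2, ]))
  circle_from3(R[1, ], R[2, ], R[3, ])
}

in_circle <- function(p, ci) {
  ci$r >= 0 && sqrt(sum((p - ci$centre)^2)) <= ci$r + 1e-9
}

welzl <- function(P, R) {
  if (nrow(P) == 0L || (!is.null(R) && nrow(R) == 3L)) {
    return(trivial_circle(R))
  }
  p <- P[1, ]
  D <- welzl(P[-1, , drop = FALSE], R)
  if (in_circle(p, D)) return(D)
  welzl(P[-1, , drop = FALSE], rbind(R, p))
}

#' Minimal enclosing circle
#'
#' Welzl's recursive algorithm on a point set (typically convex-hull
#' vertices); exact up to floating tolerance.
#'
#' @param pts n x 2 matrix of points.
#' @return List with `centre` (length-2) and `r` (radius).
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  welzl(pts, NULL)
}

#' Base geometric measures of a region
#'
#' Computes the size measures of the descriptor set from a region's pixel
#' set and traced boundary: the perimeter is the length of the polygon
#' through boundary-pixel centres, the area is the shoelace area of that
#' polygon, MinR is the inscribed-circle radius centred at the pixel
#' centre-of-mass (nearest approach to the boundary polygon), MaxR the
#' enclosing-circle radius about that centre, Feret is the largest
#' boundary-point
#' distance (computed on the convex hull), Breadth the boundary extent
#' perpendicular to the Feret axis, CHull/ConvexArea the hull perimeter and
#' area, and MBCRadius the minimal-enclosing-circle radius.
#'
#' Regions with fewer than 3 boundary points are degenerate: their Area is
#' the pixel count, Perimeter 0, and all other measures `NA`.
#'
#' @param mask binary matrix of one region.
#' @return Named list of base measures plus `pixel_count`, `centroid` and
#'   the boundary polygon.
#' @export
base_measures <- function(mask) {
  m <- to_int_mask(mask)
  idx <- which(m != 0L, arr.ind = TRUE)
  npx <- nrow(idx)
  if (npx == 0L) stop("empty region", call. = FALSE)
  centroid <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1) # (x, y), 0-based
  P <- trace_boundary(m)
  if (nrow(P) < 3L) {
    return(list(pixel_count = npx, centroid = centroid, polygon = P,
                Perimeter = 0, Area = npx, MinR = NA_real_, MaxR = NA_real_,
                Feret = NA_real_, Breadth = NA_real_, CHull = NA_real_,
                ConvexArea = NA_real_, MBCRadius = NA_real_,
                degenerate = TRUE))
  }
  perim <- poly_perimeter(P)
  area <- poly_area(P)
  B <- unique(P)
  dists <- sqrt((B[, 1] - centroid[1])^2 + (B[, 2] - centroid[2])^2)
  # inscribed-circle radius: nearest approach to the boundary polygon
  # (edges, not just vertices); the enclosing radius is attained at a
  # vertex so the vertex maximum suffices
  minr <- point_polygon_dist(centroid, P)
  hull_idx <- grDevices::chull(B[, 1], B[, 2])
  H <- B[hull_idx, , drop = FALSE]
  # Feret: largest pairwise distance; sufficient to search hull vertices
  dx <- outer(H[, 1], H[, 1], `-`)
  dy <- outer(H[, 2], H[, 2], `-`)
  dd <- dx^2 + dy^2
  k <- which.max(dd)
  i <- (k - 1L) %% nrow(H) + 1L
  j <- (k - 1L) %/% nrow(H) + 1L
  feret <- sqrt(dd[k])
  u <- (H[j, ] - H[i, ]) / feret
  perp <- c(-u[2], u[1])
  proj <- B[, 1] * perp[1] + B[, 2] * perp[2]
  breadth <- diff(range(proj))
  mbc <- min_enclosing_circle(H)
  list(pixel_count = npx, centroid = centroid, polygon = P,
       Perimeter = perim, Area = area,
       MinR = minr, MaxR = max(dists),
       Feret = feret, Breadth = breadth,
       CHull = poly_perimeter(H), ConvexArea = poly_area(H),
       MBCRadius = mbc$r, degenerate = FALSE)
}

#' Derived shape descriptors
#'
#' The 11 dimensionless (plus Concavity, in px^2) ratios built from the
#' base measures:
#' AspRatio = Feret/Breadth; Circularity = 4*pi*Area/Perimeter^2 (form
#' factor); Roundness = 4*Area/(pi*Feret^2); Compactness =
#' sqrt((4/pi)*Area)/Feret; Solidity = Area/ConvexArea; Concavity =
#' ConvexArea - Area; Convexity = CHull/Perimeter; Shape =
#' Perimeter^2/Area; ModRatio = 2*MinR/Feret; Sphericity = MinR/MaxR;
#' Rectangularity = Area/(Feret*Breadth).
#'
#' @param bm list of base measures from [base_measures()].
#' @return Named list of the 11 derived descriptors (`NA` on degenerate
#'   input or zero denominators).
#' @export
derived_descriptors <- function(bm) {
  na <- list(AspRatio = NA_real_, Circularity = NA_real_,
             Roundness = NA_real_, Compactness = NA_real_,
             Solidity = NA_real_, Concavity = NA_real_,
             Convexity = NA_real_, Shape = NA_real_, ModRatio = NA_real_,
             Sphericity = NA_real_, Rectangularity = NA_real_)
  if (isTRUE(bm$degenerate)) return(na)
  sdiv <- function(a, b) if (!is.finite(b) || b == 0) NA_real_ else a / b
  list(
    AspRatio = sdiv(bm$Feret, bm$Breadth),
    Circularity = sdiv(4 * pi * bm$Area, bm$Perimeter^2),
    Roundness = sdiv(4 * bm$Area, pi * bm$Feret^2),
    Compactness = sdiv(sqrt((4 / pi) * bm$Area), bm$Feret),
    Solidity = sdiv(bm$Area, bm$ConvexArea),
    Concavity = bm$ConvexArea - bm$Area,
    Convexity = sdiv(bm$CHull, bm$Perimeter),
    Shape = sdiv(bm$Perimeter^2, bm$Area),
    ModRatio = sdiv(2 * bm$MinR, bm$Feret),
    Sphericity = sdiv(bm$MinR, bm$MaxR),
    Rectangularity = sdiv(bm$Area, bm$Feret * bm$Breadth)
  )
}

descriptor_columns <- function() {
  c("IOD", "GrAverage", "Perimeter", "Area", "MinR", "MaxR", "Feret",
    "Breadth", "CHull", "MBCRadius", "AspRatio", "Circularity", "Roundness",
    "Compactness", "Solidity", "Concavity", "Convexity", "Shape",
    "ModRatio", "Sphericity", "Rectangularity")
}

#' Measure every labelled nucleus
#'
#' One row per label (ascending label order) holding the 21 descriptors.
#' When an OD plane is supplied, IOD is the summed OD over the label's
#' pixels and GrAverage the mean OD; otherwise both are `NA`.
#'
#' @param labels integer label matrix.
#' @param od_plane optional `image_plane` of kind `"optical_density"` with
#'   the same dimensions.
#' @param image_id,stage,cell_type provenance strings recycled across rows.
#' @return `data.frame` with columns `label`, the 21 descriptors, then
#'   `pixel_count`, `centroid_x`, `centroid_y`, `image_id`, `stage`,
#'   `cell_type`.
#' @export
measure_all <- function(labels, od_plane = NULL, image_id = NA_character_,
                        stage = NA_character_, cell_type = "unknown") {
  lab <- to_int_mask(labels)
  od <- NULL
  if (!is.null(od_plane)) {
    od <- as_plane_matrix(od_plane)
    if (!identical(dim(od), dim(lab))) {
      stop("label mask and OD plane dimensions differ", call. = FALSE)
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  rows <- lapply(ids, function(id) {
    pix <- which(lab == id, arr.ind = TRUE)
    r0 <- range(pix[, 1]); c0 <- range(pix[, 2])
    sub <- matrix(0L, diff(r0) + 1L, diff(c0) + 1L)
    sub[cbind(pix[, 1] - r0[1] + 1L, pix[, 2] - c0[1] + 1L)] <- 1L
    bm <- base_measures(sub)
    dd <- derived_descriptors(bm)
    iod <- gr <- NA_real_
    if (!is.null(od)) {
      vals <- od[pix]
      iod <- sum(vals)
      gr <- mean(vals)
    }
    data.frame(label = id, IOD = iod, GrAverage = gr,
               Perimeter = bm$Perimeter, Area = bm$Area, MinR = bm$MinR,
               MaxR = bm$MaxR, Feret = bm$Feret, Breadth = bm$Breadth,
               CHull = bm$CHull, MBCRadius = bm$MBCRadius,
               AspRatio = dd$AspRatio, Circularity = dd$Circularity,
               Roundness = dd$Roundness, Compactness = dd$Compactness,
               Solidity = dd$Solidity, Concavity = dd$Concavity,
               Convexity = dd$Convexity, Shape = dd$Shape,
               ModRatio = dd$ModRatio, Sphericity = dd$Sphericity,
               Rectangularity = dd$Rectangularity,
               pixel_count = bm$pixel_count,
               centroid_x = bm$centroid[1] + c0[1] - 1,
               centroid_y = bm$centroid[2] + r0[1] - 1,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    cols <- c("label", descriptor_columns(), "pixel_count",
              "centroid_x", "centroid_y")
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  out$image_id <- rep(image_id, nrow(out))
  out$stage <- rep(stage, nrow(out))
  out$cell_type <- rep(cell_type, nrow(out))
  out
}
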