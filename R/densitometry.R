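#' Integrated optical density of labelled regions
#'
#' IOD of a nucleus is the sum of per-pixel optical densities over its
#' pixel set (OD = -log10(IF/IB), computed by the optics layer); GrAverage
#' is IOD divided by the pixel count, i.e. the mean OD. Under stoichiometric
#' Feulgen staining, IOD is proportional to the DNA content of the nucleus.
#'
#' @param labels integer label matrix.
#' @param od_plane `image_plane` of kind `"optical_density"`, same
#'   dimensions.
#' @return `data.frame` with columns `label`, `IOD`, `GrAverage`,
#'   `pixel_count` (ascending label).
#' @export
integrated_od <- function(labels, od_plane) {
  lab <- to_int_mask(labels)
  od <- as_plane_matrix(od_plane)
  if (!identical(dim(od), dim(lab))) {
    stop("label mask and OD plane dimensions differ", call. = FALSE)
  }
  if (max(lab) == 0L) stop("no labelled regions", call. = FALSE)
  ids <- sort(unique(lab[lab > 0L]))
  pos <- lab > 0L
  sums <- tapply(od[pos], lab[pos], sum)
  cnts <- tapply(od[pos], lab[pos], length)
  data.frame(label = ids,
             IOD = as.numeric(sums[as.character(ids)]),
             GrAverage = as.numeric(sums[as.character(ids)] /
                                      cnts[as.character(ids)]),
             pixel_count = as.integer(cnts[as.character(ids)]))
}

#' Calibrate the DNA reference standard
#'
#' Feulgen densitometry is relative: ploidy is expressed against the mean
#' IOD of a reference population of normal cells whose absolute DNA content
#' (`Cp`, in picograms per 1C) is known. For normal mussel haemocytes the
#' primary standard is 1C = 0.96 pg.
#'
#' @param reference_table `data.frame` with an `IOD` column of reference
#'   (normal) nuclei.
#' @param Cp picograms per 1C of the primary standard (default 0.96).
#' @param min_n minimum recommended reference size (warning below it).
#' @return A `reference_standard` object with fields `IODp`, `Cp`,
#'   `n_reference`.
#' @export
calibrate_reference <- function(reference_table, Cp = 0.96, min_n = 30L) {
  if (is.numeric(reference_table)) {
    reference_table <- data.frame(IOD = reference_table)
  }
  iod <- reference_table$IOD
  iod <- iod[is.finite(iod)]
  if (length(iod) == 0L) stop("empty reference table", call. = FALSE)
  if (length(iod) < min_n) {
    warning(sprintf("only %d reference nuclei (recommended minimum %d)",
                    length(iod), min_n))
  }
  IODp <- mean(iod)
  if (IODp <= 0) stop("reference mean IOD must be positive", call. = FALSE)
  structure(list(IODp = IODp, Cp = Cp, n_reference = length(iod)),
            class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  cat(sprintf(
    "<reference_standard> IODp = %.4g (n = %d), Cp = %.3g pg/1C\n",
    x$IODp, x$n_reference, x$Cp))
  invisible(x)
}

#' DNA content and ploidy from IOD
#'
#' Cs = (IODs x Cp) / IODp gives the DNA content of the sample nucleus in
#' picograms; the ploidy ratio IODs / IODp places the reference population
#' at 1 by construction.
#'
#' @param iod numeric vector of sample IOD values.
#' @param standard a `reference_standard` from [calibrate_reference()].
#' @return `data.frame` with columns `IOD`, `Cs_pg`, `ploidy`.
#' @export
ploidy <- function(iod, standard) {
  if (!inherits(standard, "reference_standard")) {
    stop("`standard` must come from calibrate_reference()", call. = FALSE)
  }
  ratio <- iod / standard$IODp
  data.frame(IOD = iod, Cs_pg = ratio * standard$Cp, ploidy = ratio)
}

#' Running-average smoothing
#'
#' Centred moving average of odd window size; near the edges the window
#' shrinks symmetrically so the first and last bins average fewer values.
#'
#' @param counts numeric vector (histogram counts).
#' @param window odd window size, default 7.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(counts, window = 7L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  n <- length(counts)
  if (window == 1L || n == 0L) return(as.numeric(counts))
  h <- window %/% 2L
  cs <- cumsum(c(0, counts))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i) # symmetric shrinking at the edges
    out[i] <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  }
  out
}

#' Build a ploidy histogram profile
#'
#' Histogram of per-nucleus ploidy ratios on a fixed grid (default bin
#' width 0.2 C-ratio units over [0, 40]) plus its running-average smoothed
#' curve and the peaks detected on the smoothed curve.
#'
#' @param ploidy_values numeric vector of ploidy ratios.
#' @param bin_width histogram bin width (default 0.2).
#' @param range_max upper histogram limit (default 40).
#' @param window smoothing window (odd, default 7).
#' @param min_prominence peak prominence threshold as a fraction of the
#'   maximum smoothed height (default 0.05).
#' @return A `ploidy_profile` object: list with `bin_edges`, `bin_centres`,
#'   `counts`, `smoothed`, `peaks` (data.frame), `n`.
#' @export
ploidy_profile <- function(ploidy_values, bin_width = 0.2, range_max = 40,
                           window = 7L, min_prominence = 0.05) {
  v <- ploidy_values[is.finite(ploidy_values)]
  v <- pmin(pmax(v, 0), range_max)
  edges <- seq(0, range_max, by = bin_width)
  if (edges[length(edges)] < range_max) edges <- c(edges, range_max)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  sm <- smooth_profile(counts, window)
  pk <- detect_peaks_vec(sm, centres, min_prominence, raw_counts = counts)
  structure(list(bin_edges = edges, bin_centres = centres, counts = counts,
                 smoothed = sm, peaks = pk, n = length(v)),
            class = "ploidy_profile")
}

#' @export
print.ploidy_profile <- function(x, ...) {
  cat(sprintf("<ploidy_profile> %d nuclei, %d bins (width %.3g)\n",
              x$n, length(x$counts), diff(x$bin_edges[1:2])))
  if (nrow(x$peaks)) {
    cat("peaks:\n")
    print(x$peaks, row.names = FALSE)
  } else {
    cat("no peaks detected\n")
  }
  invisible(x)
}

# peak detection on a smoothed vector: local maxima with prominence
# measured against the highest saddle towards higher terrain on each side
# (the convention of scipy.signal.peak_prominences); location refined as
# the count-weighted centroid of the contiguous bins within half a
# prominence of the peak top.
detect_peaks_vec <- function(s, centres, min_prominence = 0.05,
                             raw_counts = NULL) {
  if (is.null(raw_counts)) raw_counts <- s
  empty <- data.frame(location = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  n <- length(s)
  if (n == 0L || max(s) <= 0) return(empty)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      # walk over any plateau
      j <- i
      while (j < n && s[j + 1L] == s[j]) j <- j + 1L
      if (j <= n - 1L && s[j + 1L] < s[j]) {
        cand <- c(cand, (i + j) %/% 2L) # plateau centre
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L) return(empty)
  thr <- min_prominence * max(s)
  rows <- lapply(cand, function(p) {
    h <- s[p]
    # left base
    lmin <- h
    k <- p - 1L
    while (k >= 1L && s[k] <= h) { lmin <- min(lmin, s[k]); k <- k - 1L }
    rmin <- h
    k <- p + 1L
    while (k <= n && s[k] <= h) { rmin <- min(rmin, s[k]); k <- k + 1L }
    prom <- h - max(lmin, rmin)
    # peak support: contiguous bins within half a prominence of the top
    # (found on the smoothed curve); the location is the raw-count
    # centroid over that support -- the smoothing finds the peak, the
    # counts place it (a smoothed centroid is biased near the histogram
    # edge where the running-average window shrinks)
    lev <- h - prom / 2
    a <- p; while (a > 1L && s[a - 1L] >= lev && s[a - 1L] <= s[a]) a <- a - 1L
    b <- p; while (b < n && s[b + 1L] >= lev && s[b + 1L] <= s[b]) b <- b + 1L
    w <- raw_counts[a:b]
    loc <- if (sum(w) > 0) sum(centres[a:b] * w) / sum(w) else centres[p]
    data.frame(location = loc, height = h, prominence = prom)
  })
  pk <- do.call(rbind, rows)
  pk <- pk[pk$prominence >= thr, , drop = FALSE]
  pk <- pk[order(pk$location), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Detect peaks in a ploidy profile
#'
#' @param profile a `ploidy_profile` (or a numeric vector of smoothed
#'   counts together with `centres`).
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   smoothed height (default 0.05).
#' @param centres bin centres when `profile` is a bare vector.
#' @return `data.frame` with columns `location`, `height`, `prominence`.
#' @export
detect_peaks <- function(profile, min_prominence = 0.05, centres = NULL) {
  if (inherits(profile, "ploidy_profile")) {
    return(detect_peaks_vec(profile$smoothed, profile$bin_centres,
                            min_prominence, raw_counts = profile$counts))
  }
  if (is.null(centres)) centres <- seq_along(profile)
  detect_peaks_vec(as.numeric(profile), centres, min_prominence)
}
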