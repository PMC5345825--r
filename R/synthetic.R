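#' Synthetic Feulgen scene from a disease-stage preset
#'
#' Builds a fully parameterised scene specification whose per-nucleus DNA
#' contents are drawn from the stage's ploidy mixture:
#' \describe{
#'   \item{normal}{single component at 1n (normal morphotype).}
#'   \item{light}{components at 1n, 6.2n and 10.7n; the aneuploid
#'     components carry A-type (ovoid, pleomorphic) morphology.}
#'   \item{moderate}{components at 1n and 7n; the 7n component mixes A and
#'     B morphotypes with normal cells at 1n.}
#'   \item{heavy}{components at 1n, 7.8n and a broad 31n component rendered
#'     as multinucleate clusters of B-type nuclei.}
#' }
#' Mixture weights default to 0.5/0.35/0.15 (light), 0.4/0.6 (moderate) and
#' 0.3/0.55/0.15 (heavy); the source material reports the peak positions
#' but not the proportions, so the weights are configuration knobs.
#'
#' @param stage one of `"normal"`, `"light"`, `"moderate"`, `"heavy"`.
#' @param n_nuclei number of nuclei (>= 1).
#' @param seed integer seed; fixing it makes the whole scene (and any
#'   later render) bit-identical.
#' @param component_cv coefficient of variation of each ploidy component
#'   (default 0.08).
#' @param weights optional mixture weights overriding the stage default.
#' @param background_level blank-field brightness in grey levels.
#' @param illumination_gradient length-2 fractional slope (x, y).
#' @param noise_sd Gaussian sensor noise SD in grey levels.
#' @param od_per_C calibration constant: summed OD (OD*px) per 1C of DNA.
#'   The default 19 makes a 1C nucleus of typical normal area (~113 px)
#'   about 0.17 OD per pixel, matching the observed normal mean grey
#'   average.
#' @param touching_pair_fraction fraction of nuclei placed as touching
#'   pairs (default 0).
#' @param multinucleate_fraction fraction of nuclei rendered as
#'   multinucleate clusters in addition to any stage-driven ones.
#' @return A `scene_spec` object.
#' @export
stage_preset <- function(stage, n_nuclei, seed,
                         component_cv = 0.08, weights = NULL,
                         background_level = 220,
                         illumination_gradient = c(0, 0),
                         noise_sd = 2, od_per_C = 19,
                         touching_pair_fraction = 0,
                         multinucleate_fraction = 0) {
  mixes <- stage_mixtures()
  if (!is.character(stage) || length(stage) != 1L ||
      !(stage %in% names(mixes))) {
    stop(sprintf("unknown stage '%s'; expected one of %s",
                 paste(stage, collapse = ","),
                 paste(names(mixes), collapse = ", ")), call. = FALSE)
  }
  if (n_nuclei < 1) stop("n_nuclei must be >= 1", call. = FALSE)
  mix <- mixes[[stage]]
  w <- if (is.null(weights)) mix$weights else weights
  if (length(w) != length(mix$centres) || any(w < 0) || sum(w) <= 0) {
    stop("invalid mixture weights", call. = FALSE)
  }
  w <- w / sum(w)
  geom <- morphotype_geometry()
  set.seed(as.integer(seed))
  comp <- sample.int(length(w), n_nuclei, replace = TRUE, prob = w)
  morph <- mix$morphotypes[comp]
  # 'AB' components mix A and B morphotypes half and half
  ab <- morph == "AB"
  if (any(ab)) morph[ab] <- sample(c("A", "B"), sum(ab), replace = TRUE)
  dna <- stats::rnorm(n_nuclei, mix$centres[comp],
                      component_cv * mix$centres[comp])
  dna <- pmax(dna, 0.05)
  multi <- morph == "B_multi"
  if (multinucleate_fraction > 0) {
    extra <- stats::runif(n_nuclei) < multinucleate_fraction
    multi <- multi | extra
  }
  g <- geom[ifelse(morph == "B_multi", "B_multi", morph)]
  radius <- vapply(g, `[[`, numeric(1), "radius")
  radius <- radius * exp(stats::rnorm(n_nuclei, 0,
                                      vapply(g, `[[`, numeric(1),
                                             "radius_cv")))
  radius <- pmax(radius, 2.5)
  asp_lo <- vapply(g, function(x) x$aspect[1], numeric(1))
  asp_hi <- vapply(g, function(x) x$aspect[2], numeric(1))
  aspect <- stats::runif(n_nuclei, asp_lo, asp_hi)
  aspect[morph %in% c("B", "B_multi")] <-
    pmin(aspect[morph %in% c("B", "B_multi")], 1.15) # B cells stay round
  orientation <- stats::runif(n_nuclei, 0, pi)
  irr <- vapply(g, `[[`, numeric(1), "irregularity")
  tex <- vapply(g, `[[`, numeric(1), "texture")
  cluster_k <- ifelse(multi, sample(3:6, n_nuclei, replace = TRUE), 1L)

  # jittered-grid placement: every nucleus fully inside the frame, pairs
  # of touching nuclei share a grid cell
  ext <- radius * sqrt(pmax(aspect, 1)) * (1 + 2 * irr) +
    ifelse(multi, radius * 0.8, 0)
  maxext <- max(ext)
  n_pairs <- floor(touching_pair_fraction * n_nuclei / 2)
  cell <- ceiling((if (n_pairs > 0) 3.4 else 2.2) * maxext + 4)
  n_cells <- n_nuclei - n_pairs
  ncol_g <- ceiling(sqrt(n_cells))
  nrow_g <- ceiling(n_cells / ncol_g)
  width <- as.integer(ncol_g * cell + 2 * cell)
  height <- as.integer(nrow_g * cell + 2 * cell)
  cells <- sample(seq_len(ncol_g * nrow_g), n_cells)
  cx_cell <- ((cells - 1L) %% ncol_g) * cell + cell + cell / 2
  cy_cell <- ((cells - 1L) %/% ncol_g) * cell + cell + cell / 2
  jit <- (cell / 2 - maxext - 2)
  x <- y <- numeric(n_nuclei)
  # first n_cells nuclei get their own cell; the last 2*n_pairs nuclei are
  # arranged as touching pairs inside the final n_pairs cells
  singles <- seq_len(n_nuclei - 2L * n_pairs)
  x[singles] <- cx_cell[singles] + stats::runif(length(singles), -jit, jit)
  y[singles] <- cy_cell[singles] + stats::runif(length(singles), -jit, jit)
  if (n_pairs > 0) {
    for (p in seq_len(n_pairs)) {
      i <- n_nuclei - 2L * n_pairs + 2L * p - 1L
      j <- i + 1L
      cc <- n_cells - n_pairs + p
      ang <- stats::runif(1, 0, 2 * pi)
      d <- 0.95 * (radius[i] + radius[j])
      x[i] <- cx_cell[cc] - cos(ang) * d / 2
      y[i] <- cy_cell[cc] - sin(ang) * d / 2
      x[j] <- cx_cell[cc] + cos(ang) * d / 2
      y[j] <- cy_cell[cc] + sin(ang) * d / 2
    }
  }
  nuclei <- data.frame(
    id = seq_len(n_nuclei), x = x, y = y,
    morphotype = ifelse(morph == "B_multi", "B", morph),
    base_radius = radius, aspect_ratio = aspect, orientation = orientation,
    boundary_irregularity = irr, dna_content = dna,
    chromatin_texture = tex, multinucleate = multi, cluster_k = cluster_k,
    stringsAsFactors = FALSE)
  structure(list(width = width, height = height, nuclei = nuclei,
                 stage_preset = stage, background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, od_per_C = od_per_C,
                 touching_pair_fraction = touching_pair_fraction,
                 multinucleate_fraction = multinucleate_fraction,
                 component_cv = component_cv, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> stage '%s': %d nuclei in %d x %d px (seed %d)\n",
    x$stage_preset, nrow(x$nuclei), x$width, x$height, x$seed))
  print(table(x$nuclei$morphotype))
  invisible(x)
}

illumination_field <- function(spec) {
  w <- spec$width; h <- spec$height
  gx <- spec$illumination_gradient[1]
  gy <- if (length(spec$illumination_gradient) > 1) {
    spec$illumination_gradient[2]
  } else 0
  xs <- (seq_len(w) - 1) / max(w - 1, 1) - 0.5
  ys <- (seq_len(h) - 1) / max(h - 1, 1) - 0.5
  spec$background_level * outer(1 + gy * ys, 1 + gx * xs)
}

#' Render a synthetic Feulgen scene
#'
#' Each nucleus is an ellipse with a smooth radial boundary perturbation;
#' its per-pixel OD field (with multiplicative chromatin texture) is
#' normalised so that the summed OD equals `od_per_C * dna_content`
#' exactly, before noise — the stain model is conservative by construction
#' (stoichiometric staining). Multinucleate nuclei are drawn as 3-6
#' overlapping round lobes forming one connected blob under a single
#' ground-truth label. Transmitted intensity is
#' `IF = IB * 10^(-OD)` with `IB` the illumination field (background level
#' plus linear gradients); the green channel carries the full stain
#' absorption, red and blue are attenuated less (the dye is magenta).
#' Gaussian sensor noise is added per pixel and channel, clipped to
#' [0, 255].
#'
#' @param spec a `scene_spec` from [stage_preset()] or built manually.
#' @param quantize round intensities to integer grey levels (default
#'   `FALSE`: continuous values, so densitometry is exact up to floating
#'   error).
#' @return List with `image` (h x w x 3 RGB array), `blank` (same shape,
#'   illumination field only), `truth` (list: `label_mask`, `table` with
#'   columns label, morphotype, dna_content, true_iod), and `spec`.
#' @export
render_scene <- function(spec, quantize = FALSE) {
  nuc <- spec$nuclei
  if (any(nuc$base_radius < 2)) {
    stop("nucleus radius < 2 px cannot be rendered", call. = FALSE)
  }
  set.seed(spec$seed + 1L)
  h <- spec$height; w <- spec$width
  od <- matrix(0, h, w)
  lab <- matrix(0L, h, w)
  true_iod <- numeric(nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    res <- rasterize_nucleus(nuc[i, ], h, w)
    pix <- res$pixels # matrix [row, col]
    if (nrow(pix) == 0L) next
    wts <- exp(nuc$chromatin_texture[i] * stats::rnorm(nrow(pix)))
    amount <- spec$od_per_C * nuc$dna_content[i]
    odvals <- wts / sum(wts) * amount
    idx <- (pix[, 2] - 1L) * h + pix[, 1]
    od[idx] <- od[idx] + odvals
    free <- lab[idx] == 0L
    lab[idx[free]] <- i
    true_iod[i] <- amount
  }
  ib <- illumination_field(spec)
  tg <- 10^(-od)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- ib * 10^(-0.25 * od)
  img[, , 2] <- ib * tg
  img[, , 3] <- ib * 10^(-0.40 * od)
  if (min(img[, , 2]) < 1) {
    warning("od_per_C so large that transmitted intensity falls below ",
            "1 grey level; densitometry will saturate")
  }
  blank <- array(rep(ib, 3), dim = c(h, w, 3))
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    blank <- blank + stats::rnorm(length(blank), 0, spec$noise_sd)
  }
  img <- pmin(pmax(img, 0), 255)
  blank <- pmin(pmax(blank, 0), 255)
  if (quantize) {
    img <- round(img)
    blank <- round(blank)
  }
  truth <- list(
    label_mask = lab,
    table = data.frame(label = nuc$id, morphotype = nuc$morphotype,
                       dna_content = nuc$dna_content, true_iod = true_iod,
                       stringsAsFactors = FALSE))
  list(image = img, blank = blank, truth = truth, spec = spec)
}

# pixel set of one nucleus: ellipse with low-order harmonic boundary
# perturbation, or a cluster of overlapping round lobes when multinucleate
rasterize_nucleus <- function(n1, h, w) {
  cx <- n1$x; cy <- n1$y
  R <- n1$base_radius
  if (isTRUE(n1$multinucleate)) {
    k <- n1$cluster_k
    ang0 <- stats::runif(1, 0, 2 * pi)
    angs <- ang0 + 2 * pi * seq_len(k) / k + stats::rnorm(k, 0, 0.15)
    dcen <- R * 0.55
    subr <- R * 0.62 * exp(stats::rnorm(k, 0, 0.05))
    ext <- dcen + max(subr) + 2
    box <- clip_box(cx, cy, ext, h, w)
    if (is.null(box)) return(list(pixels = matrix(0L, 0, 2)))
    inside <- matrix(FALSE, length(box$rows), length(box$cols))
    for (j in seq_len(k)) {
      sx <- cx + cos(angs[j]) * dcen
      sy <- cy + sin(angs[j]) * dcen
      dx <- outer(rep(1, length(box$rows)), box$xs - sx)
      dy <- outer(box$ys - sy, rep(1, length(box$cols)))
      inside <- inside | (dx^2 + dy^2 <= subr[j]^2)
    }
  } else {
    ar <- max(n1$aspect_ratio, 1)
    a <- R * sqrt(ar); b <- R / sqrt(ar)
    irr <- n1$boundary_irregularity
    coefs <- stats::rnorm(6, 0, 1) / 2 # harmonics 2..4, cos & sin
    ext <- a * (1 + 2.5 * irr) + 2
    box <- clip_box(cx, cy, ext, h, w)
    if (is.null(box)) return(list(pixels = matrix(0L, 0, 2)))
    th <- n1$orientation
    dx <- outer(rep(1, length(box$rows)), box$xs - cx)
    dy <- outer(box$ys - cy, rep(1, length(box$cols)))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    rho <- sqrt((u / a)^2 + (v / b)^2)
    phi <- atan2(v, u)
    pert <- 1 + irr * (coefs[1] * cos(2 * phi) + coefs[2] * sin(2 * phi) +
                         coefs[3] * cos(3 * phi) + coefs[4] * sin(3 * phi) +
                         coefs[5] * cos(4 * phi) + coefs[6] * sin(4 * phi))
    inside <- rho <= pmax(pert, 0.2)
  }
  sel <- which(inside, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(list(pixels = matrix(0L, 0, 2)))
  list(pixels = cbind(box$rows[sel[, 1]], box$cols[sel[, 2]]))
}

clip_box <- function(cx, cy, ext, h, w) {
  # 0-based centre coordinates; rows/cols are 1-based matrix indices
  c_lo <- max(1L, floor(cx - ext) + 1L)
  c_hi <- min(w, ceiling(cx + ext) + 1L)
  r_lo <- max(1L, floor(cy - ext) + 1L)
  r_hi <- min(h, ceiling(cy + ext) + 1L)
  if (c_lo > c_hi || r_lo > r_hi) return(NULL)
  list(rows = r_lo:r_hi, cols = c_lo:c_hi,
       xs = (c_lo:c_hi) - 1, ys = (r_lo:r_hi) - 1)
}

#' Sample a feature table from the published group statistics
#'
#' Draws independent per-nucleus descriptor vectors with the published
#' group means and SDs (normal, pooled neoplastic, A-type, B-type).
#' Positive unbounded features use a moment-matched Gamma (support
#' respected without biasing the mean), unit-interval ratios a Gaussian
#' clipped to (0, 1], and AspRatio 1 + Gamma. Ordering constraints
#' (MinR <= MaxR, Breadth <= Feret, Feret <= 2*MBCRadius <= 2*MaxR) are
#' repaired after sampling.
#'
#' @param group `"normal"`, `"neoplastic"`, `"A"` or `"B"`.
#' @param n number of nuclei (>= 1).
#' @param seed integer seed.
#' @return `data.frame` of the 21 descriptors plus a `group` column.
#' @export
sample_feature_table <- function(group, n, seed) {
  tab <- feature_param_table()
  groups <- c("normal", "neoplastic", "A", "B")
  if (!is.character(group) || length(group) != 1L || !(group %in% groups)) {
    stop(sprintf("unknown group '%s'; expected one of %s",
                 paste(group, collapse = ","),
                 paste(groups, collapse = ", ")), call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  m <- tab[[paste0(group, "_m")]]
  s <- tab[[paste0(group, "_s")]]
  out <- list()
  for (k in seq_len(nrow(tab))) {
    out[[tab$feature[k]]] <- draw_feature(n, m[k], s[k], tab$family[k])
  }
  df <- as.data.frame(out)
  # repair ordering invariants
  lo <- pmin(df$MinR, df$MaxR); hi <- pmax(df$MinR, df$MaxR)
  df$MinR <- lo; df$MaxR <- hi
  lo <- pmin(df$Breadth, df$Feret); hi <- pmax(df$Breadth, df$Feret)
  df$Breadth <- lo; df$Feret <- hi
  df$MBCRadius <- pmax(df$MBCRadius, df$Feret / 2)
  df$MaxR <- pmax(df$MaxR, df$MBCRadius)
  df <- df[, descriptor_columns()]
  df$group <- group
  df
}

draw_feature <- function(n, m, s, family) {
  if (s <= 0) return(rep(m, n))
  switch(family,
    gamma = {
      shape <- (m / s)^2
      stats::rgamma(n, shape = shape, rate = m / s^2)
    },
    shifted_gamma = {
      m1 <- m - 1
      if (m1 <= 1e-6) return(1 + abs(stats::rnorm(n, 0, s)))
      1 + stats::rgamma(n, shape = (m1 / s)^2, rate = m1 / s^2)
    },
    unit01 = pmin(pmax(stats::rnorm(n, m, s), 0.01), 1),
    stop("unknown sampling family")
  )
}

#' Serialise / restore a scene specification
#'
#' JSON round-trip of a `scene_spec`, including the per-nucleus table.
#'
#' @param spec a `scene_spec`.
#' @param path file path (`.json`).
#' @return `read_scene_spec` returns the restored `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, digits = I(17),
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$nuclei <- as.data.frame(x$nuclei, stringsAsFactors = FALSE)
  x$nuclei$id <- as.integer(x$nuclei$id)
  x$nuclei$cluster_k <- as.integer(x$nuclei$cluster_k)
  x$nuclei$multinucleate <- as.logical(x$nuclei$multinucleate)
  x$width <- as.integer(x$width)
  x$height <- as.integer(x$height)
  x$seed <- as.integer(x$seed)
  structure(x, class = "scene_spec")
}
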