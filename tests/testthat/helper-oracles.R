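# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's computational paths (convex hull, Welzl, cpp kernels).

# largest pairwise distance over all boundary points, O(n^2)
oracle_feret <- function(B) {
  dd <- outer(B[, 1], B[, 1], `-`)^2 + outer(B[, 2], B[, 2], `-`)^2
  sqrt(max(dd))
}

# extent perpendicular to every maximal-distance chord, O(n^2);
# returns the breadth for each tied maximal pair
oracle_breadth_all <- function(B) {
  dd <- outer(B[, 1], B[, 1], `-`)^2 + outer(B[, 2], B[, 2], `-`)^2
  mx <- max(dd)
  pairs <- which(dd >= mx - 1e-9, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  apply(pairs, 1, function(ij) {
    u <- (B[ij[2], ] - B[ij[1], ]) / sqrt(mx)
    proj <- B[, 1] * (-u[2]) + B[, 2] * u[1]
    diff(range(proj))
  })
}

# minimal enclosing circle radius by exhaustive pairs + triples, O(n^3)
oracle_mbc_radius <- function(B) {
  B <- unique(B)
  n <- nrow(B)
  covers <- function(cx, cy, r) {
    all((B[, 1] - cx)^2 + (B[, 2] - cy)^2 <= r^2 + 1e-9)
  }
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cx <- (B[i, 1] + B[j, 1]) / 2
      cy <- (B[i, 2] + B[j, 2]) / 2
      r <- sqrt((B[i, 1] - cx)^2 + (B[i, 2] - cy)^2)
      if (r < best && covers(cx, cy, r)) best <- r
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          a <- B[i, ]; b <- B[j, ]; cc <- B[k, ]
          d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                      cc[1] * (a[2] - b[2]))
          if (abs(d) < 1e-12) next
          ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
                   sum(cc^2) * (a[2] - b[2])) / d
          uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
                   sum(cc^2) * (b[1] - a[1])) / d
          r <- sqrt((a[1] - ux)^2 + (a[2] - uy)^2)
          if (r < best && covers(ux, uy, r)) best <- r
        }
      }
    }
  }
  unname(best)
}

# closed-polygon length and shoelace area, plain loops
oracle_perimeter <- function(P) {
  n <- nrow(P)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    tot <- tot + sqrt(sum((P[j, ] - P[i, ])^2))
  }
  unname(tot)
}

oracle_area <- function(P) {
  n <- nrow(P)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + P[i, 1] * P[j, 2] - P[j, 1] * P[i, 2]
  }
  unname(abs(s) / 2)
}

# recursive flood fill (4/8-neighbourhood) independent of the C++ kernel
oracle_component_count <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] != 0 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  count
}

# exhaustive between-class-variance scan (loop form)
oracle_otsu <- function(x, n_bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- as.numeric(tabulate(idx, nbins = n_bins))
  centres <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  best <- -Inf; thr <- NA_real_
  for (j in seq_len(n_bins - 1L)) {
    w0 <- sum(counts[1:j]); w1 <- sum(counts[(j + 1):n_bins])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:j] * centres[1:j]) / w0
    m1 <- sum(counts[(j + 1):n_bins] * centres[(j + 1):n_bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- breaks[j + 1L] } # ties: lowest edge
  }
  thr
}

# small random blob: rotated ellipse with harmonic boundary perturbation,
# guaranteed 8-connected (star-shaped about its centre)
random_blob <- function(seed, rmin = 4, rmax = 9) {
  set.seed(seed)
  R <- runif(1, rmin, rmax)
  ar <- runif(1, 1, 1.8)
  th <- runif(1, 0, pi)
  irr <- runif(1, 0, 0.15)
  co <- rnorm(4) / 2
  n <- ceiling(2 * (R * sqrt(ar) * 1.6 + 3))
  ctr <- n / 2
  xx <- outer(rep(1, n), seq_len(n) - ctr)
  yy <- t(xx)
  u <- xx * cos(th) + yy * sin(th)
  v <- -xx * sin(th) + yy * cos(th)
  a <- R * sqrt(ar); b <- R / sqrt(ar)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v, u)
  pert <- 1 + irr * (co[1] * cos(2 * phi) + co[2] * sin(2 * phi) +
                       co[3] * cos(3 * phi) + co[4] * sin(3 * phi))
  matrix(as.integer(rho <= pmax(pert, 0.3)), n, n)
}

# best-overlap Jaccard of each ground-truth label against a segmentation
jaccard_per_truth <- function(gt, lab) {
  vapply(sort(unique(gt[gt > 0])), function(k) {
    sel <- gt == k
    cand <- lab[sel]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    kk <- as.integer(names(which.max(table(cand))))
    sum(sel & lab == kk) / sum(sel | lab == kk)
  }, numeric(1))
}
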