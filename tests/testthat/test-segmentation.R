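test_that("otsu_threshold separates two-value images, rejects constants", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "constant")
})

test_that("otsu_threshold equals the exhaustive-scan oracle", {
  for (s in 1:20) {
    set.seed(s)
    mu <- sort(runif(2, 20, 230))
    x <- c(rnorm(500, mu[1], runif(1, 3, 20)),
           rnorm(500, mu[2], runif(1, 3, 20)))
    expect_equal(otsu_threshold(matrix(x, 50)), oracle_otsu(x),
                 tolerance = 1e-12)
  }
})

test_that("remove_edge_objects deletes exactly the border-touching blobs", {
  m <- matrix(0L, 12, 12)
  m[4:6, 4:6] <- 1L
  expect_equal(remove_edge_objects(m), m)
  m2 <- m; m2[1, 7:8] <- 1L # separate blob on row 1
  out <- remove_edge_objects(m2)
  expect_equal(out, m)
  # 5 blobs, 2 touching borders -> 3 remain (flood-fill oracle)
  m3 <- matrix(0L, 20, 20)
  m3[1:2, 2:3] <- 1L       # touches top
  m3[18:20, 10:11] <- 1L   # touches bottom
  m3[5:6, 5:6] <- 1L
  m3[10:11, 14:15] <- 1L
  m3[14:15, 3:4] <- 1L
  out3 <- remove_edge_objects(m3)
  expect_equal(oracle_component_count(out3), 3L)
})

test_that("watershed_split separates the two-disc phantom, keeps singles", {
  xx <- outer(rep(1, 50), 1:50); yy <- t(xx)
  # two discs radius 10, centres 16 px apart: overlapping single component
  blob <- matrix(as.integer((xx - 17)^2 + (yy - 25)^2 <= 100 |
                              (xx - 33)^2 + (yy - 25)^2 <= 100), 50)
  expect_equal(oracle_component_count(blob), 1L)
  ws <- watershed_split(blob)
  sizes <- tabulate(ws[ws > 0])
  expect_equal(length(sizes), 2L)
  expect_lt(abs(sizes[1] - sizes[2]) / max(sizes), 0.1)
  # watershed lines removed: union of labels within input mask
  expect_true(all(blob[ws > 0] == 1L))

  disc <- matrix(as.integer((xx - 25)^2 + (yy - 25)^2 <= 144), 50)
  ws1 <- watershed_split(disc)
  expect_equal(max(ws1), 1L)
  expect_equal(sum(ws1 > 0), sum(disc)) # nothing removed for one region
  # two disjoint discs: identical to connected components
  two <- matrix(as.integer((xx - 12)^2 + (yy - 12)^2 <= 36 |
                             (xx - 38)^2 + (yy - 38)^2 <= 36), 50)
  ws2 <- watershed_split(two)
  expect_equal(max(ws2), 2L)
  expect_equal(sum(ws2 > 0), sum(two))
  # empty mask
  expect_equal(max(watershed_split(matrix(0L, 10, 10))), 0L)
})

test_that("size_filter keeps the inclusive [min, max] pixel-count range", {
  lab <- matrix(0L, 40, 40)
  lab[2:3, 2:6] <- 1L            # 10 px
  lab[10:19, 10:19] <- 2L        # 100 px
  lab[21:40, 21:40] <- 3L        # 400 px
  out <- size_filter(lab, 25, 300)
  expect_equal(sort(unique(out[out > 0])), 1L)
  expect_equal(sum(out > 0), 100L)
  expect_equal(size_filter(lab, 1, Inf, relabel = FALSE), lab)
  # inclusive boundary: exactly 25 px survives bounds (25, 300)
  lab25 <- matrix(0L, 10, 10); lab25[2:6, 2:6] <- 1L
  expect_equal(sum(size_filter(lab25, 25, 300) > 0), 25L)
  expect_error(size_filter(lab, 10, 5), "min_px")
})

test_that("dilate_no_merge grows shells without merging labels", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  d1 <- dilate_no_merge(one, 1)
  expect_equal(sum(d1 == 1L), 9L) # 3x3 block
  two <- matrix(0L, 9, 11); two[5, 4] <- 1L; two[5, 8] <- 2L
  d5 <- dilate_no_merge(two, 5)
  expect_equal(sort(unique(d5[d5 > 0])), c(1L, 2L))
  expect_equal(oracle_component_count(matrix(as.integer(d5 == 1L), 9)), 1L)
  expect_equal(oracle_component_count(matrix(as.integer(d5 == 2L), 9)), 1L)
  # label count preserved on random label fields
  for (s in 1:5) {
    set.seed(s)
    lab <- matrix(0L, 30, 30)
    for (k in 1:4) {
      r <- sample(5:25, 1); c <- sample(5:25, 1)
      if (all(lab[max(1, r - 2):min(30, r + 2),
                  max(1, c - 2):min(30, c + 2)] == 0L)) lab[r, c] <- k
    }
    n0 <- length(unique(lab[lab > 0]))
    dd <- dilate_no_merge(lab, sample(1:6, 1))
    expect_equal(length(unique(dd[dd > 0])), n0)
  }
})

test_that("fill_holes closes interior holes only", {
  m <- matrix(0L, 10, 10); m[3:8, 3:8] <- 1L; m[5:6, 5:6] <- 0L
  out <- fill_holes(m)
  expect_equal(sum(out), 36L)
  # a bay open to the border is not a hole
  m2 <- matrix(0L, 10, 10); m2[3:8, 3:8] <- 1L; m2[1:5, 5] <- 0L
  expect_equal(fill_holes(m2), m2)
})

test_that("apply_exclusion removes labels by overlap fraction", {
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 1L; lab[7:9, 7:9] <- 2L
  none <- matrix(0L, 10, 10)
  expect_equal(apply_exclusion(lab, none), lab)
  full <- none; full[7:9, 7:9] <- 1L
  out <- apply_exclusion(lab, full)
  expect_equal(sort(unique(out[out > 0])), 1L)
  # 4/9 = 44% overlap at threshold 0.5 -> kept
  part <- none; part[2:3, 2:3] <- 1L
  expect_equal(apply_exclusion(lab, part, 0.5), lab)
  expect_error(apply_exclusion(lab, matrix(0L, 3, 3)), "dimensions")
})

test_that("end-to-end segmentation recovers non-touching synthetic scenes", {
  for (seed in c(2, 9)) {
    spec <- stage_preset("normal", 25, seed = seed, noise_sd = 0)
    sc <- render_scene(spec)
    lab <- segment_nuclei(extract_green(sc$image))
    expect_equal(max(lab), nrow(spec$nuclei))
    jac <- jaccard_per_truth(sc$truth$label_mask, lab)
    expect_gte(mean(jac), 0.9)
  }
})
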