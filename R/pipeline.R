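#' Build a pipeline run configuration
#'
#' Collects every tunable of the image -> segmentation -> morphometry ->
#' densitometry -> statistics chain in one serialisable list. Either
#' `images` (paths plus stage labels) or `synthetic` (stage presets) must
#' be provided.
#'
#' @param outdir output directory.
#' @param synthetic list: `stages` (character), `images_per_stage`,
#'   `nuclei_per_image`; or `NULL` when real images are given.
#' @param images optional `data.frame` with columns `image`, `blank`,
#'   `stage` (file paths + label per image).
#' @param seed integer master seed.
#' @param pixel_size_um micrometres per pixel (default 0.45).
#' @param od_max OD ceiling.
#' @param n_bins Otsu histogram bins.
#' @param min_px,max_px size-filter bounds. The published bounds for
#'   normal haemocytes are 25-300 px; the default upper bound here is 800
#'   because neoplastic nuclei (mean area > 400 px^2) would otherwise be
#'   discarded.
#' @param watershed,min_distance,dilate_iters segmentation settings.
#' @param bin_width,range_max,window,min_prominence ploidy-profile
#'   settings.
#' @param alpha significance level.
#' @param f_enter,f_remove stepwise-LDA thresholds.
#' @param Cp picograms per 1C of the primary standard.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, synthetic = list(stages = c("normal", "light",
                                                           "moderate",
                                                           "heavy"),
                                                images_per_stage = 3L,
                                                nuclei_per_image = 30L),
                       images = NULL, seed = 1L, pixel_size_um = 0.45,
                       od_max = 3, n_bins = 256L, min_px = 25L,
                       max_px = 800L, watershed = TRUE, min_distance = 5,
                       dilate_iters = 0L, bin_width = 0.2, range_max = 40,
                       window = 7L, min_prominence = 0.05, alpha = 0.05,
                       f_enter = 3.84, f_remove = 2.71, Cp = 0.96) {
  structure(list(outdir = outdir, synthetic = synthetic, images = images,
                 seed = as.integer(seed), pixel_size_um = pixel_size_um,
                 od_max = od_max, n_bins = as.integer(n_bins),
                 min_px = as.integer(min_px), max_px = as.integer(max_px),
                 watershed = watershed, min_distance = min_distance,
                 dilate_iters = as.integer(dilate_iters),
                 bin_width = bin_width, range_max = range_max,
                 window = as.integer(window),
                 min_prominence = min_prominence, alpha = alpha,
                 f_enter = f_enter, f_remove = f_remove, Cp = Cp),
            class = "run_config")
}

#' Serialise / restore a run configuration
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = I(17),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ints <- c("seed", "n_bins", "min_px", "max_px", "dilate_iters", "window")
  for (f in ints) x[[f]] <- as.integer(x[[f]])
  if (!is.null(x$synthetic)) {
    x$synthetic$images_per_stage <- as.integer(x$synthetic$images_per_stage)
    x$synthetic$nuclei_per_image <- as.integer(x$synthetic$nuclei_per_image)
  }
  structure(x, class = "run_config")
}

#' Run the full cytometry pipeline
#'
#' Per image: optical-density conversion, segmentation, morphometry and
#' densitometry; per run: a pooled feature table, the reference standard
#' calibrated from the images labelled `"normal"`, per-stage ploidy
#' profiles with detected peaks, group statistics (Welch t per feature for
#' normal vs the pooled diseased stages, one-way F across stages), a
#' stepwise-LDA confusion matrix for normal vs neoplastic and one across
#' stages, and a machine-readable JSON manifest.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with `features` (pooled table), `standard`,
#'   `profiles`, `stats`, `manifest`; all artefacts are also written under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  imgdir <- file.path(outdir, "images")
  dir.create(imgdir, showWarnings = FALSE)

  jobs <- assemble_jobs(config)
  feats <- list()
  counts <- list()
  for (j in seq_along(jobs)) {
    job <- jobs[[j]]
    od <- frames_to_od(job$image, job$blank,
                       pixel_size_um = config$pixel_size_um,
                       od_max = config$od_max)
    green <- extract_green(job$image, config$pixel_size_um)
    lab <- segment_nuclei(green, n_bins = config$n_bins,
                          watershed = config$watershed,
                          min_distance = config$min_distance,
                          min_px = config$min_px, max_px = config$max_px,
                          dilate_iters = config$dilate_iters)
    tab <- measure_all(lab, od, image_id = job$id, stage = job$stage)
    utils::write.csv(tab, file.path(imgdir, paste0(job$id, "_features.csv")),
                     row.names = FALSE)
    write_label_png(lab, file.path(imgdir, paste0(job$id, "_labels.png")))
    feats[[j]] <- tab
    counts[[job$id]] <- nrow(tab)
  }
  pooled <- do.call(rbind, feats)
  if (nrow(pooled) == 0L) stop("pipeline produced no nuclei", call. = FALSE)

  ref_tab <- pooled[pooled$stage == "normal", ]
  if (nrow(ref_tab) == 0L) {
    stop("no images labelled 'normal': cannot calibrate the reference",
         call. = FALSE)
  }
  standard <- calibrate_reference(ref_tab, Cp = config$Cp)
  pl <- ploidy(pooled$IOD, standard)
  pooled$ploidy <- pl$ploidy
  pooled$Cs_pg <- pl$Cs_pg
  utils::write.csv(pooled, file.path(outdir, "features_pooled.csv"),
                   row.names = FALSE)

  profiles <- list()
  peak_rows <- list()
  for (st in unique(pooled$stage)) {
    pr <- ploidy_profile(pooled$ploidy[pooled$stage == st],
                         bin_width = config$bin_width,
                         range_max = config$range_max,
                         window = config$window,
                         min_prominence = config$min_prominence)
    profiles[[st]] <- pr
    utils::write.csv(
      data.frame(bin_centre = pr$bin_centres, count = pr$counts,
                 smoothed = pr$smoothed),
      file.path(outdir, paste0("ploidy_profile_", st, ".csv")),
      row.names = FALSE)
    if (nrow(pr$peaks)) {
      pk <- pr$peaks
      pk$stage <- st
      peak_rows[[st]] <- pk
    }
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(location = numeric(0), height = numeric(0),
               prominence = numeric(0), stage = character(0))
  utils::write.csv(peaks, file.path(outdir, "ploidy_peaks.csv"),
                   row.names = FALSE)

  stats_out <- pipeline_stats(pooled, config)
  utils::write.csv(stats_out$descriptives,
                   file.path(outdir, "descriptives.csv"), row.names = FALSE)
  utils::write.csv(stats_out$tests, file.path(outdir, "feature_tests.csv"),
                   row.names = FALSE)
  if (!is.null(stats_out$lda2)) {
    utils::write.csv(as.data.frame(stats_out$lda2$confusion),
                     file.path(outdir, "confusion_normal_neoplastic.csv"),
                     row.names = FALSE)
  }
  if (!is.null(stats_out$lda_stage)) {
    utils::write.csv(as.data.frame(stats_out$lda_stage$confusion),
                     file.path(outdir, "confusion_stage.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("feulgenICM")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "outdir")],
    per_image_counts = counts,
    n_nuclei_total = nrow(pooled),
    reference = list(IODp = standard$IODp, Cp = standard$Cp,
                     n_reference = standard$n_reference))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(list(features = pooled, standard = standard,
                 profiles = profiles, peaks = peaks, stats = stats_out,
                 manifest = manifest))
}

assemble_jobs <- function(config) {
  jobs <- list()
  if (!is.null(config$synthetic) &&
      length(config$synthetic$stages) > 0) {
    syn <- config$synthetic
    k <- 0L
    for (st in syn$stages) {
      for (i in seq_len(syn$images_per_stage)) {
        k <- k + 1L
        spec <- stage_preset(st, syn$nuclei_per_image,
                             seed = config$seed + 1000L * k)
        sc <- render_scene(spec)
        jobs[[length(jobs) + 1L]] <-
          list(id = sprintf("%s_%02d", st, i), stage = st,
               image = sc$image, blank = sc$blank, truth = sc$truth)
      }
    }
  } else if (!is.null(config$images)) {
    for (i in seq_len(nrow(config$images))) {
      row <- config$images[i, ]
      if (!file.exists(row$image)) {
        stop(sprintf("input image not found: %s", row$image), call. = FALSE)
      }
      if (!file.exists(row$blank)) {
        stop(sprintf("blank image not found: %s", row$blank), call. = FALSE)
      }
      jobs[[length(jobs) + 1L]] <-
        list(id = tools::file_path_sans_ext(basename(row$image)),
             stage = row$stage,
             image = read_image_png(row$image),
             blank = read_image_png(row$blank))
    }
  } else {
    stop("config has neither synthetic presets nor input images",
         call. = FALSE)
  }
  jobs
}

pipeline_stats <- function(pooled, config) {
  feats <- intersect(descriptor_columns(), names(pooled))
  desc <- describe_features(pooled[, c(feats, "stage")], "stage",
                            features = feats)
  pooled$disease <- ifelse(pooled$stage == "normal", "normal", "neoplastic")
  two_groups <- length(unique(pooled$disease)) == 2L
  rows <- lapply(feats, function(f) {
    p_t <- NA_real_
    if (two_groups) {
      tt <- try(two_group_test(pooled, f, "disease",
                               groups = c("normal", "neoplastic")),
                silent = TRUE)
      if (!inherits(tt, "try-error")) p_t <- tt$p_value
    }
    data.frame(feature = f, p_welch = p_t, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  if (length(unique(pooled$stage)) >= 2L) {
    fstats <- multi_group_comparison(pooled[, c(feats, "stage")], "stage",
                                     features = feats,
                                     alpha = config$alpha)
    tests <- merge(tests, fstats[, c("feature", "F", "p_value")],
                   by = "feature", sort = FALSE)
    names(tests)[names(tests) == "p_value"] <- "p_anova"
  }
  lda2 <- NULL
  if (two_groups && min(table(pooled$disease)) > length(feats) + 2L) {
    lda2 <- stepwise_lda(pooled[, c(feats, "disease")], "disease",
                         features = feats, f_enter = config$f_enter,
                         f_remove = config$f_remove)
  }
  lda_stage <- NULL
  if (length(unique(pooled$stage)) >= 3L &&
      min(table(pooled$stage)) > length(feats) + 2L) {
    lda_stage <- stepwise_lda(pooled[, c(feats, "stage")], "stage",
                              features = feats, f_enter = config$f_enter,
                              f_remove = config$f_remove)
  }
  list(descriptives = desc, tests = tests, lda2 = lda2,
       lda_stage = lda_stage)
}

#' Write a small demonstration dataset
#'
#' Renders a fixture set (default: 4 stages x 3 images, ~50 nuclei each)
#' with ground truth: image PNGs, blank-field PNGs, label-mask PNGs and a
#' pooled truth CSV. Deterministic for a fixed seed.
#'
#' @param outdir writable output directory.
#' @param seed integer seed.
#' @param images_per_stage,n_nuclei layout of the fixture set.
#' @return Invisibly, a `data.frame` describing the written files (one row
#'   per image: `image`, `blank`, `labels`, `stage`).
#' @export
demo_dataset <- function(outdir, seed = 42L, images_per_stage = 3L,
                         n_nuclei = 50L) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory",
                                call. = FALSE)
  stages <- c("normal", "light", "moderate", "heavy")
  rows <- list()
  truth <- list()
  k <- 0L
  for (st in stages) {
    for (i in seq_len(images_per_stage)) {
      k <- k + 1L
      spec <- stage_preset(st, n_nuclei, seed = seed + 1000L * k)
      sc <- render_scene(spec, quantize = TRUE)
      id <- sprintf("%s_%02d", st, i)
      fimg <- file.path(outdir, paste0(id, ".png"))
      fblank <- file.path(outdir, paste0(id, "_blank.png"))
      flab <- file.path(outdir, paste0(id, "_labels.png"))
      write_image_png(sc$image, fimg)
      write_image_png(sc$blank, fblank)
      write_label_png(sc$truth$label_mask, flab)
      tt <- sc$truth$table
      tt$image_id <- id
      tt$stage <- st
      truth[[k]] <- tt
      rows[[k]] <- data.frame(image = fimg, blank = fblank, labels = flab,
                              stage = st, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, truth), file.path(outdir, "truth.csv"),
                   row.names = FALSE)
  invisible(do.call(rbind, rows))
}
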