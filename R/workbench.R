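# Orchestration: configuration-driven pipeline runs, artifact/report I/O,
# and canonical synthetic fixtures.

slide_png_write <- function(rgb, path) {
  # png::writePNG expects [row, col, channel] in 0..1
  png::writePNG(rgb / 255, target = path)
  invisible(path)
}

slide_png_read <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}

label_png_write <- function(label_map, path) {
  # class ids 1..4 stored as gray levels id/255 for a plain single-channel PNG
  png::writePNG(label_map / 255, target = path)
  invisible(path)
}

label_png_read <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write / read an optical movie as text artifacts
#'
#' The frames are stored as a plain CSV matrix (`n_frames` rows, one column
#' per pixel in column-major row,col order) plus a YAML metadata sidecar
#' (`fs`, `dx`, grid size, stimulation site, seed and truth parameters).
#'
#' @param movie An [optical_movie()].
#' @param stem Path stem; writes `<stem>.csv` and `<stem>.yaml`.
#' @return `read_movie()` returns an `optical_movie`.
#' @export
write_movie <- function(movie, stem) {
  d <- dim(movie$frames)
  utils::write.csv(matrix(movie$frames, d[1]), paste0(stem, ".csv"),
                   row.names = FALSE)
  meta <- list(fs = movie$fs, dx = movie$dx, n_frames = d[1], n_rows = d[2],
               n_cols = d[3], stim_xy = as.integer(movie$stim_xy),
               stim_time_ms = movie$stim_time_ms)
  if (!is.null(movie$truth)) meta$truth <- unclass(movie$truth)
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_movie
#' @export
read_movie <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  m <- as.matrix(utils::read.csv(paste0(stem, ".csv")))
  frames <- array(m, dim = c(meta$n_frames, meta$n_rows, meta$n_cols))
  optical_movie(frames, fs = meta$fs, dx = meta$dx,
                stim_xy = unlist(meta$stim_xy),
                stim_time_ms = meta$stim_time_ms)
}

#' Write / read an ECG trace as a two-column CSV
#'
#' Columns `time_s` and `mv`, plus a YAML sidecar with `fs` and any truth
#' parameters.
#'
#' @param ecg An `ecg_trace`.
#' @param stem Path stem; writes `<stem>.csv` and `<stem>.yaml`.
#' @return `read_ecg()` returns an `ecg_trace`.
#' @export
write_ecg <- function(ecg, stem) {
  t_s <- (seq_along(ecg$samples) - 1L) / ecg$fs
  utils::write.csv(data.frame(time_s = t_s, mv = ecg$samples),
                   paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(fs = ecg$fs)
  if (!is.null(ecg$truth)) meta$truth <- unclass(ecg$truth)
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_ecg
#' @export
read_ecg <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  df <- utils::read.csv(paste0(stem, ".csv"))
  ecg_trace(df$mv, fs = meta$fs)
}

run_config_schema <- function() {
  list(
    simulate_slide = c("fractions", "height_px", "width_px", "blob_scale",
                       "mode", "noise_sd", "illumination"),
    simulate_movie = c("cv_long", "cv_trans", "fiber_angle", "apd", "erp",
                       "dx", "fs", "noise_sd", "n_rows", "n_cols",
                       "duration_ms", "s2_interval_ms"),
    simulate_ecg = c("heart_rate", "pr", "qrs", "has_j_wave", "n_beats",
                     "fs", "noise_sd", "jitter_sd_ms"),
    fibrosis = c("slide_png", "palette_file", "tile_px", "n_tiles",
                 "compression_ratio", "compactness"),
    optical = c("movie_stem", "axis_angle", "temporal_smooth_ms",
                "spatial_smooth_px"),
    ecg = c("ecg_stem", "n_average", "threshold_ms", "pre_qrs", "post_qrs")
  )
}

#' Run a configured pipeline stage
#'
#' Executes one stage (`simulate_slide`, `simulate_movie`, `simulate_ecg`,
#' `fibrosis`, `optical` or `ecg`) from a configuration list, writes its
#' artifacts and a JSON run report into `out_dir`, and returns the report.
#' Unknown configuration keys are rejected. Reports contain no timestamps,
#' so identical configuration and seed reproduce byte-identical reports.
#'
#' @param config Named list with elements `task`, `seed` (integer), `params`
#'   (named list of task parameters) and optionally `out_dir`.
#' @return A `run_report` list: `task`, `seed`, `params`, `metrics`,
#'   `artifacts`, `package_version`.
#' @export
run_pipeline <- function(config) {
  if (!is.list(config) || is.null(config$task)) {
    cq_stop("config must be a list with a `task` field",
            class = "cardioquant_usage_error")
  }
  schema <- run_config_schema()
  if (!config$task %in% names(schema)) {
    cq_stop(sprintf("unknown task `%s`; known: %s", config$task,
                    paste(names(schema), collapse = ", ")),
            class = "cardioquant_usage_error")
  }
  top_keys <- setdiff(names(config), c("task", "seed", "params", "out_dir"))
  if (length(top_keys)) {
    cq_stop(sprintf("unknown config keys: %s", paste(top_keys, collapse = ", ")),
            class = "cardioquant_usage_error")
  }
  params <- config$params %||% list()
  bad <- setdiff(names(params), schema[[config$task]])
  if (length(bad)) {
    cq_stop(sprintf("unknown parameters for task %s: %s", config$task,
                    paste(bad, collapse = ", ")),
            class = "cardioquant_usage_error")
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("cq_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  metrics <- list()

  if (config$task == "simulate_slide") {
    fr <- unlist(params$fractions %||%
                   c(collagen = 0.3, rbc = 0.1, myocyte = 0.5, background = 0.1))
    truth <- trichrome_truth(fractions = fr,
                             noise_sd = params$noise_sd %||% 8, seed = seed)
    sl <- make_trichrome_slide(truth,
                               params$height_px %||% 600L,
                               params$width_px %||% 600L,
                               blob_scale = params$blob_scale %||% 60,
                               mode = params$mode %||% "blobs",
                               illumination = params$illumination %||% 0)
    slide_png_write(sl$rgb, file.path(out_dir, "slide.png"))
    label_png_write(sl$label_map, file.path(out_dir, "labels.png"))
    yaml::write_yaml(c(unclass(truth)[c("fractions", "noise_sd", "seed")],
                       list(class_ids = stats::setNames(1:4, tissue_class_levels()))),
                     file.path(out_dir, "slide.yaml"))
    artifacts <- c("slide.png", "labels.png", "slide.yaml")
    lf <- label_fractions(sl$label_map)
    metrics <- as.list(stats::setNames(lf$fraction, paste0("fraction_", lf$class)))
  } else if (config$task == "simulate_movie") {
    keep <- intersect(names(params),
                      c("cv_long", "cv_trans", "fiber_angle", "apd", "erp",
                        "dx", "fs", "noise_sd"))
    truth <- do.call(wave_truth, c(params[keep], list(seed = seed)))
    mv <- make_optical_movie(truth, params$n_rows %||% 48L,
                             params$n_cols %||% 48L,
                             params$duration_ms %||% 80,
                             s2_interval_ms = params$s2_interval_ms)
    write_movie(mv, file.path(out_dir, "movie"))
    artifacts <- c("movie.csv", "movie.yaml")
    metrics <- list(n_frames = dim(mv$frames)[1])
  } else if (config$task == "simulate_ecg") {
    keep <- intersect(names(params), c("heart_rate", "pr", "qrs", "has_j_wave",
                                       "n_beats", "fs", "noise_sd", "jitter_sd_ms"))
    truth <- do.call(ecg_truth, c(params[keep], list(seed = seed)))
    ecg <- make_ecg(truth)
    write_ecg(ecg, file.path(out_dir, "ecg"))
    artifacts <- c("ecg.csv", "ecg.yaml")
    metrics <- list(n_samples = length(ecg$samples))
  } else if (config$task == "fibrosis") {
    rgb <- slide_png_read(params$slide_png)
    palette <- if (!is.null(params$palette_file)) read_palette(params$palette_file)
      else palette_from_means()
    plan <- plan_tiles(dim(rgb)[1], dim(rgb)[2],
                       tile_px = params$tile_px %||% 50L,
                       n_tiles = params$n_tiles %||% 900L)
    res <- quantify_slide(rgb, palette, plan,
                          compression_ratio = params$compression_ratio %||% 50,
                          compactness = params$compactness %||% 10)
    utils::write.csv(res$per_tile, file.path(out_dir, "per_tile.csv"),
                     row.names = FALSE)
    artifacts <- "per_tile.csv"
    metrics <- c(as.list(res$aggregate),
                 list(fibrosis_fraction = res$fibrosis_fraction,
                      undefined = res$undefined))
  } else if (config$task == "optical") {
    mv <- read_movie(params$movie_stem)
    eps <- ep_summary(mv, axis_angle = params$axis_angle,
                      temporal_smooth_ms = params$temporal_smooth_ms %||% 0,
                      spatial_smooth_px = params$spatial_smooth_px %||% 0)
    utils::write.csv(as.data.frame(eps$activation$act_ms),
                     file.path(out_dir, "activation_ms.csv"), row.names = FALSE)
    artifacts <- "activation_ms.csv"
    metrics <- list(cv_long = eps$cv_long, cv_trans = eps$cv_trans,
                    apd80 = eps$apd80)
  } else if (config$task == "ecg") {
    if (!is.null(params$pre_qrs)) {
      cmp <- compare_qrs(unlist(params$pre_qrs), unlist(params$post_qrs),
                         threshold_ms = params$threshold_ms %||% 25)
      utils::write.csv(cmp$table, file.path(out_dir, "paired_qrs.csv"),
                       row.names = FALSE)
      artifacts <- "paired_qrs.csv"
      metrics <- list(p_value = cmp$p_value, n_robust = cmp$n_robust,
                      n_shortened = cmp$n_shortened,
                      mean_pre = cmp$mean_pre, mean_post = cmp$mean_post)
    } else {
      trace <- read_ecg(params$ecg_stem)
      iv <- ecg_intervals(trace, n_average = params$n_average %||% 100L)
      metrics <- list(pr = iv$pr, qrs = iv$qrs, heart_rate = iv$heart_rate)
    }
  }

  report <- list(task = config$task, seed = seed, params = params,
                 metrics = metrics, artifacts = artifacts,
                 package_version = as.character(utils::packageVersion("cardioquant")))
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the canonical synthetic test fixtures
#'
#' Writes four fixture families with known ground truth into `dir`: one
#' trichrome slide (PNG + label map + metadata), one small optical movie
#' (CSV + metadata), one murine ECG trace (CSV + metadata), and one
#' human-scale paired QRS cohort of 19 subjects of whom 13 are shortened
#' post versus pre (4 robustly) and 5 lengthened. A `manifest.json` lists
#' the families and files.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  sl <- make_trichrome_slide(trichrome_truth(seed = seed), 300, 300)
  slide_png_write(sl$rgb, file.path(dir, "slide.png"))
  label_png_write(sl$label_map, file.path(dir, "slide_labels.png"))
  yaml::write_yaml(unclass(sl$truth)[c("fractions", "noise_sd", "seed")],
                   file.path(dir, "slide.yaml"))

  mv <- make_optical_movie(wave_truth(seed = seed), 32, 32, duration_ms = 70)
  write_movie(mv, file.path(dir, "movie"))

  ecg <- make_ecg(ecg_truth(n_beats = 30, seed = seed))
  write_ecg(ecg, file.path(dir, "ecg_mouse"))

  cohort <- withr::with_seed(seed, {
    pre <- round(stats::rnorm(19, 150, 30))
    delta <- c(stats::runif(4, 26, 45),          # robust shorteners
               stats::runif(9, 2, 20),           # shortened, not robust
               -stats::runif(5, 2, 25),          # lengthened
               0)                                 # unchanged
    data.frame(subject = sprintf("S%02d", 1:19), pre = pre,
               post = round(pre - delta))
  })
  utils::write.csv(cohort, file.path(dir, "cohort_qrs.csv"), row.names = FALSE)

  manifest <- list(
    seed = seed,
    families = list(
      slide = c("slide.png", "slide_labels.png", "slide.yaml"),
      movie = c("movie.csv", "movie.yaml"),
      ecg_mouse = c("ecg_mouse.csv", "ecg_mouse.yaml"),
      cohort = "cohort_qrs.csv"
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
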