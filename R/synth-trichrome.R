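# Synthetic Masson-trichrome slide generator.
#
# Emulates a scanned trichrome section as a mosaic of four colour classes
# (collagen, red blood cells, myocytes, background) with known per-pixel
# ground truth, so the fibrosis pipeline can be validated without real
# whole-slide images.

#' Default trichrome class colours
#'
#' Mean RGB colours (0..255) for the four tissue classes, chosen to mimic a
#' Masson trichrome stain: collagen blue, red blood cells orange-red,
#' myocytes red-pink, background near-white. Rows are named in the fixed
#' class order `collagen, rbc, myocyte, background`.
#'
#' @return A 4 x 3 numeric matrix with class rownames.
#' @export
trichrome_palette_means <- function() {
  m <- rbind(
    collagen   = c(70, 90, 160),
    rbc        = c(200, 80, 40),
    myocyte    = c(170, 60, 80),
    background = c(245, 245, 245)
  )
  colnames(m) <- c("r", "g", "b")
  m
}

#' Ground-truth parameters for a synthetic trichrome slide
#'
#' @param fractions Named numeric vector of requested per-class area
#'   proportions for `collagen`, `rbc`, `myocyte`, `background`. Must lie in
#'   \[0, 1\] and sum to 1 (tolerance 1e-9).
#' @param palette_means 4 x 3 matrix of per-class mean RGB colours (0..255);
#'   defaults to [trichrome_palette_means()].
#' @param noise_sd Per-channel Gaussian colour noise SD in RGB units.
#' @param seed Integer seed; identical seed + parameters give identical
#'   slides.
#' @return A list of class `trichrome_truth`.
#' @export
trichrome_truth <- function(fractions = c(collagen = 0.3, rbc = 0.1,
                                          myocyte = 0.5, background = 0.1),
                            palette_means = trichrome_palette_means(),
                            noise_sd = 8, seed = 1L) {
  lv <- tissue_class_levels()
  if (is.null(names(fractions))) names(fractions) <- lv
  if (!setequal(names(fractions), lv)) {
    cq_stop("`fractions` must be named collagen, rbc, myocyte, background")
  }
  fractions <- fractions[lv]
  if (any(fractions < 0) || any(fractions > 1)) {
    cq_stop("class fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    cq_stop("class fractions must sum to 1")
  }
  if (noise_sd < 0) cq_stop("`noise_sd` must be >= 0")
  stopifnot(is.matrix(palette_means), dim(palette_means) == c(4L, 3L))
  structure(
    list(fractions = fractions, palette_means = palette_means,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "trichrome_truth"
  )
}

# Threshold a smooth field so that exactly k of the `eligible` pixels fall
# below the cut (k-th order statistic), giving near-exact realized fractions
# with contiguous blob geometry.
split_by_field <- function(field_vals, eligible, k) {
  sel <- logical(length(field_vals))
  if (k <= 0L) return(sel)
  idx <- which(eligible)
  if (k >= length(idx)) {
    sel[idx] <- TRUE
    return(sel)
  }
  ord <- order(field_vals[idx])
  sel[idx[ord[seq_len(k)]]] <- TRUE
  sel
}

#' Generate a synthetic trichrome slide with known labels
#'
#' Renders an RGB image whose pixels are drawn from per-class mean colours
#' plus Gaussian noise, together with the exact per-pixel label map.
#' Two placement modes are available: `"blobs"` (smooth random fields
#' thresholded at order statistics, giving contiguous tissue-like regions
#' whose realized fractions match the request to within 1 pixel per split)
#' and `"iid"` (per-pixel multinomial sampling, exact in expectation).
#'
#' @param truth A [trichrome_truth()] object.
#' @param height_px,width_px Slide size in pixels (>= 1).
#' @param blob_scale Characteristic blob diameter in pixels (`"blobs"` mode).
#' @param mode `"blobs"` (default) or `"iid"`.
#' @param illumination Relative amplitude of a left-to-right multiplicative
#'   illumination ramp (0 disables; 0.1 means +/-10 percent brightness).
#' @return A list of class `trichrome_slide` with elements `rgb`
#'   (`height_px x width_px x 3`, 0..255), `label_map` (integer matrix,
#'   1 = collagen, 2 = rbc, 3 = myocyte, 4 = background) and `truth`.
#' @examples
#' sl <- make_trichrome_slide(trichrome_truth(seed = 7), 120, 120)
#' table(sl$label_map) / (120 * 120)
#' @export
make_trichrome_slide <- function(truth, height_px, width_px, blob_scale = 60,
                                 mode = c("blobs", "iid"), illumination = 0) {
  if (!inherits(truth, "trichrome_truth")) cq_stop("`truth` must be a trichrome_truth")
  mode <- match.arg(mode)
  check_positive(height_px, "height_px"); check_positive(width_px, "width_px")
  check_positive(blob_scale, "blob_scale")
  h <- as.integer(height_px); w <- as.integer(width_px)
  n <- h * w
  fr <- truth$fractions

  withr::with_seed(truth$seed, {
    if (mode == "iid") {
      labels <- sample.int(4L, n, replace = TRUE, prob = fr)
      label_map <- matrix(labels, h, w)
    } else {
      # sequential order-statistic splits on independent smooth fields
      label_map <- matrix(4L, h, w)
      eligible <- rep(TRUE, n)
      remaining <- 1
      for (cls in 1:3) {
        k <- round(fr[cls] * n)
        f <- as.vector(smooth_field(h, w, blob_scale))
        sel <- split_by_field(f, eligible, min(k, sum(eligible)))
        label_map[sel] <- cls
        eligible <- eligible & !sel
        remaining <- remaining - fr[cls]
      }
      # class 4 (background) keeps the rest
    }
    base <- truth$palette_means[as.vector(label_map), , drop = FALSE]
    if (truth$noise_sd > 0) {
      base <- base + matrix(stats::rnorm(n * 3L, 0, truth$noise_sd), n, 3L)
    }
    if (illumination != 0) {
      ramp <- 1 + illumination * (rep(seq_len(w), each = h) / w - 0.5) * 2
      base <- base * ramp
    }
    rgb <- array(pmin(pmax(base, 0), 255), dim = c(h, w, 3L))
  })

  structure(list(rgb = rgb, label_map = label_map, truth = truth,
                 mode = mode, illumination = illumination),
            class = "trichrome_slide")
}

#' Realized class fractions of a label map
#'
#' @param label_map Integer matrix of class ids (1..4), e.g. from
#'   [make_trichrome_slide()] or [assign_classes()].
#' @return A tibble with one row per class: `class`, `pixels`, `fraction`.
#' @export
label_fractions <- function(label_map) {
  counts <- tally_classes(label_map)
  tibble::tibble(
    class = tissue_class_levels(),
    pixels = counts,
    fraction = counts / sum(counts)
  )
}

#' Pixels of a slide as a tidy L*a*b* table
#'
#' Flattens a synthetic slide into one row per pixel with its L*a*b* colour
#' and ground-truth class, the natural input for [train_palette()].
#'
#' @param slide A `trichrome_slide`.
#' @param sample_n Optional number of pixels to subsample (deterministic
#'   under the slide's seed offset); `NULL` keeps all pixels.
#' @return A tibble with columns `L`, `a`, `b`, `class`.
#' @export
slide_lab_pixels <- function(slide, sample_n = NULL) {
  stopifnot(inherits(slide, "trichrome_slide"))
  lab <- rgb_to_lab(matrix(slide$rgb, ncol = 3L))
  cls <- factor(tissue_class_levels()[as.vector(slide$label_map)],
                levels = tissue_class_levels())
  out <- tibble::tibble(L = lab[, 1], a = lab[, 2], b = lab[, 3], class = cls)
  if (!is.null(sample_n) && sample_n < nrow(out)) {
    idx <- withr::with_seed(slide$truth$seed + 1L,
                            sample.int(nrow(out), sample_n))
    out <- out[idx, ]
  }
  out
}
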