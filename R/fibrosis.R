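# Whole-slide trichrome fibrosis quantification.
#
# Four-step pipeline: (1) sampling — equally spaced square tiles spanning
# the slide; (2) preprocessing — SLIC superpixels, colours replaced by the
# superpixel mean, converted to L*a*b*; (3) quantization — a K-means colour
# palette trained once on labelled tiles and kept fixed; (4) calculation —
# nearest-centroid (Lloyd assignment) classification of every pixel and the
# fibrosis fraction collagen / (collagen + RBC + myocytes), background
# excluded.

#' Plan equally spaced square sampling tiles over a slide
#'
#' Lays out `n_tiles` windows of `tile_px` x `tile_px` pixels on an r x c
#' grid (r * c = n_tiles, with r/c as close as possible to the slide aspect
#' ratio; 30 x 30 for the defaults), equally spaced so the first and last
#' windows touch the slide margins. When the stride equals the tile size the
#' grid is contiguous and covers every pixel exactly once.
#'
#' @param slide_height,slide_width Slide extent in pixels.
#' @param tile_px Tile side length in pixels (default 50).
#' @param n_tiles Total number of sample windows (default 900).
#' @return A tibble of class `tile_plan` with columns `tile`, `row0`, `col0`
#'   (1-based upper-left corners) and attributes `tile_px`, `grid` (c(rows,
#'   cols)) and `level`.
#' @examples
#' plan <- plan_tiles(1500, 1500)
#' nrow(plan)        # 900
#' diff(unique(plan$row0))[1]  # stride 50: contiguous
#' @export
plan_tiles <- function(slide_height, slide_width, tile_px = 50L, n_tiles = 900L) {
  check_positive(slide_height, "slide_height")
  check_positive(slide_width, "slide_width")
  check_positive(tile_px, "tile_px")
  check_positive(n_tiles, "n_tiles")
  n_tiles <- as.integer(n_tiles)

  div <- which(n_tiles %% seq_len(n_tiles) == 0L)
  pairs <- cbind(r = div, c = n_tiles %/% div)
  fits <- pairs[, "r"] * tile_px <= slide_height &
    pairs[, "c"] * tile_px <= slide_width
  if (!any(fits)) {
    cq_stop(sprintf(
      "slide (%d x %d) too small for %d tiles of %d px",
      slide_height, slide_width, n_tiles, tile_px
    ), class = "cardioquant_size_error")
  }
  pairs <- pairs[fits, , drop = FALSE]
  score <- abs(log(pairs[, "r"] / pairs[, "c"]) - log(slide_height / slide_width))
  best <- pairs[which.min(score), ]
  r <- best[["r"]]; c <- best[["c"]]

  row0 <- if (r == 1L) 1L else as.integer(round(seq(1, slide_height - tile_px + 1, length.out = r)))
  col0 <- if (c == 1L) 1L else as.integer(round(seq(1, slide_width - tile_px + 1, length.out = c)))
  plan <- tibble::tibble(
    tile = seq_len(n_tiles),
    row0 = rep(row0, times = c),
    col0 = rep(col0, each = r)
  )
  attr(plan, "tile_px") <- as.integer(tile_px)
  attr(plan, "grid") <- c(rows = r, cols = c)
  attr(plan, "level") <- 1L
  class(plan) <- c("tile_plan", class(plan))
  plan
}

# SLIC superpixels: k-means in the 5-D feature space (L, a, b, y*m/S, x*m/S)
# where S is the expected superpixel spacing and m the compactness weight.
# Assignment uses full nearest-centre search (the grid sizes handled here
# make the classical 2S-window restriction unnecessary); connectivity is not
# enforced. Returns per-pixel superpixel labels.
slic_labels <- function(lab_mat, h, w, n_superpixels, compactness = 10,
                        max_iter = 10L) {
  n <- h * w
  k <- min(n_superpixels, n)
  if (k >= n) return(seq_len(n))
  S <- sqrt(n / k)
  y <- rep(seq_len(h), times = w)
  x <- rep(seq_len(w), each = h)
  feat <- cbind(lab_mat, y * compactness / S, x * compactness / S)

  # centre init on a near-square grid
  gr <- max(1L, round(sqrt(k * h / w)))
  gc <- ceiling(k / gr)
  cy <- (seq_len(gr) - 0.5) * h / gr
  cx <- (seq_len(gc) - 0.5) * w / gc
  init <- cbind(rep(cy, times = gc), rep(cx, each = gr))[seq_len(k), , drop = FALSE]
  idx0 <- (pmin(pmax(round(init[, 2]), 1), w) - 1L) * h +
    pmin(pmax(round(init[, 1]), 1), h)
  centres <- feat[idx0, , drop = FALSE]

  f2 <- rowSums(feat^2)
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(f2, rowSums(centres^2), "+") - 2 * feat %*% t(centres)
    lab <- max.col(-d2, ties.method = "first")
    if (identical(lab, assign_prev)) break
    assign_prev <- lab
    sums <- rowsum(feat, lab)
    cnt <- tabulate(lab, nbins = k)
    nonempty <- cnt > 0L
    centres[nonempty, ] <- sums / cnt[nonempty]
  }
  lab
}

#' Superpixel preprocessing of a tile
#'
#' Runs SLIC targeting `ceiling(n_pixels / compression_ratio)` superpixels,
#' replaces every pixel by its superpixel's mean colour, and returns the
#' result in L*a*b* (sRGB input, D65 white point). A compression ratio of 1
#' is the identity (every pixel its own superpixel).
#'
#' @param tile_rgb `h x w x 3` RGB array, 0..255.
#' @param compression_ratio Pixels per superpixel (default 50, i.e. a 1:50
#'   compression of a tile into superpixels).
#' @param compactness SLIC spatial regularization weight (default 10).
#' @param max_iter Maximum SLIC iterations.
#' @return `h x w x 3` L*a*b* array with attribute `n_superpixels`.
#' @export
superpixel_preprocess <- function(tile_rgb, compression_ratio = 50,
                                  compactness = 10, max_iter = 10L) {
  if (!is.array(tile_rgb) || length(dim(tile_rgb)) != 3L || dim(tile_rgb)[3] != 3L ||
      any(dim(tile_rgb)[1:2] < 1L)) {
    cq_stop("`tile_rgb` must be a non-empty h x w x 3 array")
  }
  if (compression_ratio < 1) cq_stop("`compression_ratio` must be >= 1")
  h <- dim(tile_rgb)[1]; w <- dim(tile_rgb)[2]
  n <- h * w
  lab_mat <- rgb_to_lab(matrix(tile_rgb, ncol = 3L))
  n_sp <- ceiling(n / compression_ratio)
  if (n_sp >= n) {
    out <- array(lab_mat, dim = c(h, w, 3L))
    attr(out, "n_superpixels") <- n
    return(out)
  }
  lab_sp <- slic_labels(lab_mat, h, w, n_sp, compactness, max_iter)
  means <- rowsum(lab_mat, lab_sp) / tabulate(lab_sp, nbins = max(lab_sp))[sort(unique(lab_sp))]
  smoothed <- means[match(lab_sp, sort(unique(lab_sp))), , drop = FALSE]
  out <- array(smoothed, dim = c(h, w, 3L))
  attr(out, "n_superpixels") <- n_sp
  attr(out, "labels") <- matrix(lab_sp, h, w)
  out
}

#' Train the four-class L*a*b* colour palette
#'
#' Fits seeded K-means with `k` clusters on pooled labelled training pixels
#' and maps each cluster to a tissue class by majority vote of the training
#' labels inside it. The resulting centroids are the frozen parameters of
#' the quantization step and are kept constant for all later slides.
#'
#' @param training A data frame with columns `L`, `a`, `b` and `class`
#'   (factor or character in `collagen, rbc, myocyte, background`), e.g.
#'   from [slide_lab_pixels()], pooled over the training tiles.
#' @param k Number of K-means clusters (default 4; larger k is allowed, the
#'   majority vote then maps several clusters onto one class and the
#'   class centroid is the pixel-weighted mean of its clusters).
#' @param seed Integer seed making the fit deterministic.
#' @return A `class_palette`: list with `centroids` (4 x 3 matrix, rows in
#'   fixed class order), `k`, and `training_meta`.
#' @export
train_palette <- function(training, k = 4L, seed = 1L) {
  lv <- tissue_class_levels()
  stopifnot(is.data.frame(training), all(c("L", "a", "b", "class") %in% names(training)))
  cls <- factor(as.character(training$class), levels = lv)
  if (anyNA(cls)) cq_stop("`training$class` contains labels outside the four tissue classes")
  if (!all(lv %in% cls)) {
    cq_stop(sprintf("training data must contain all four classes; missing: %s",
                    paste(setdiff(lv, unique(cls)), collapse = ", ")),
            class = "cardioquant_training_error")
  }
  if (k < 4L) cq_stop("`k` must be >= 4 (one cluster per class at minimum)")
  X <- as.matrix(training[, c("L", "a", "b")])

  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L))
  vote <- table(cluster = km$cluster, class = cls)
  cluster_class <- lv[apply(vote, 1L, which.max)]
  if (!setequal(unique(cluster_class), lv)) {
    if (k == 4L) {
      cq_stop(paste(
        "two K-means clusters map to the same tissue class;",
        "increase k, add training pixels, or change the seed"
      ), class = "cardioquant_ambiguity_error")
    }
    cq_stop(sprintf("no cluster maps to class: %s",
                    paste(setdiff(lv, unique(cluster_class)), collapse = ", ")),
            class = "cardioquant_ambiguity_error")
  }
  # pixel-weighted mean of the clusters voting for each class
  centroids <- matrix(NA_real_, 4L, 3L, dimnames = list(lv, c("L", "a", "b")))
  for (ci in seq_along(lv)) {
    members <- which(cluster_class == lv[ci])
    wts <- km$size[members]
    centroids[ci, ] <- colSums(km$centers[members, , drop = FALSE] * wts) / sum(wts)
  }
  if (any(!is.finite(centroids)) || any(centroids[, 1] < 0 | centroids[, 1] > 100)) {
    cq_stop("trained centroids out of range", class = "cardioquant_training_error")
  }
  structure(
    list(centroids = centroids, k = as.integer(k),
         training_meta = list(seed = as.integer(seed), n_pixels = nrow(X),
                              cluster_sizes = unname(km$size))),
    class = "class_palette"
  )
}

#' Palette with the generator's own class colours
#'
#' Builds a `class_palette` directly from known per-class mean RGB colours
#' (e.g. the synthetic-slide generator's), bypassing K-means training. This
#' is the oracle palette used to check that nearest-centroid assignment
#' reproduces a noise-free label map exactly.
#'
#' @param palette_means 4 x 3 RGB matrix in fixed class order.
#' @return A `class_palette`.
#' @export
palette_from_means <- function(palette_means = trichrome_palette_means()) {
  centroids <- rgb_to_lab(palette_means)
  dimnames(centroids) <- list(tissue_class_levels(), c("L", "a", "b"))
  structure(list(centroids = centroids, k = 4L,
                 training_meta = list(source = "known class means")),
            class = "class_palette")
}

#' Assign every pixel to its nearest palette class
#'
#' Lloyd assignment with frozen centroids: each pixel goes to the class of
#' the nearest centroid in Euclidean L*a*b* distance; ties break toward the
#' lowest class index (collagen < rbc < myocyte < background).
#'
#' @param tile_lab `h x w x 3` L*a*b* array (or `n x 3` matrix).
#' @param palette A `class_palette`.
#' @return Integer label matrix (or vector for matrix input); 1 = collagen,
#'   2 = rbc, 3 = myocyte, 4 = background.
#' @export
assign_classes <- function(tile_lab, palette) {
  stopifnot(inherits(palette, "class_palette"))
  is_img <- is.array(tile_lab) && length(dim(tile_lab)) == 3L
  m <- if (is_img) matrix(tile_lab, ncol = 3L) else as.matrix(tile_lab)
  cen <- palette$centroids
  d2 <- outer(rowSums(m^2), rowSums(cen^2), "+") - 2 * m %*% t(cen)
  lab <- max.col(-d2, ties.method = "first")
  if (is_img) matrix(lab, dim(tile_lab)[1], dim(tile_lab)[2]) else lab
}

#' Fibrosis fraction from a class-area tally
#'
#' `fibrosis = Area_collagen / (Area_collagen + Area_RBC + Area_myocytes)`;
#' background pixels are excluded from the denominator by construction, so
#' adding background never changes the value. A zero denominator (no tissue)
#' returns `NA` with attribute `undefined = TRUE` rather than 0.
#'
#' @param tally Named numeric vector (or 1-row data frame) with counts
#'   `collagen`, `rbc`, `myocyte` (a `background` entry is ignored).
#' @return The fraction in \[0, 1\], or flagged `NA` if undefined.
#' @examples
#' fibrosis_fraction(c(collagen = 10, rbc = 10, myocyte = 10, background = 999))
#' @export
fibrosis_fraction <- function(tally) {
  if (is.data.frame(tally)) tally <- unlist(tally[1, ])
  need <- c("collagen", "rbc", "myocyte")
  if (!all(need %in% names(tally))) {
    cq_stop("`tally` must contain collagen, rbc and myocyte counts")
  }
  v <- as.numeric(tally[need])
  if (any(v < 0)) cq_stop("tally counts must be >= 0")
  denom <- sum(v)
  if (denom == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  v[1] / denom
}

#' Quantify fibrosis over a whole slide
#'
#' Composes the four pipeline steps per tile — extract the window, SLIC
#' superpixel preprocessing into L*a*b*, nearest-centroid classification
#' against the frozen palette — then sums the per-tile class tallies and
#' computes the fibrosis fraction on the aggregate.
#'
#' @param slide A `trichrome_slide` or an `h x w x 3` RGB array (0..255).
#' @param palette A `class_palette`.
#' @param tile_plan A [plan_tiles()] plan whose windows lie inside the slide.
#' @param compression_ratio Pixels per superpixel (1 = no superpixel
#'   smoothing); see [superpixel_preprocess()].
#' @param compactness SLIC compactness.
#' @return A `fibrosis_result`: list with `per_tile` (tibble: tile, window,
#'   four counts, per-tile fraction), `aggregate` (named counts),
#'   `fibrosis_fraction`, `undefined` flag and `params`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
quantify_slide <- function(slide, palette, tile_plan,
                           compression_ratio = 50, compactness = 10) {
  rgb <- if (inherits(slide, "trichrome_slide")) slide$rgb else slide
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L)
  tp <- attr(tile_plan, "tile_px")
  if (is.null(tp)) cq_stop("`tile_plan` must come from plan_tiles()")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (any(tile_plan$row0 + tp - 1L > h) || any(tile_plan$col0 + tp - 1L > w)) {
    cq_stop("tile plan windows fall outside the slide",
            class = "cardioquant_size_error")
  }

  n <- nrow(tile_plan)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, tissue_class_levels()))
  for (i in seq_len(n)) {
    r0 <- tile_plan$row0[i]; c0 <- tile_plan$col0[i]
    tile <- rgb[r0:(r0 + tp - 1L), c0:(c0 + tp - 1L), , drop = FALSE]
    lab <- superpixel_preprocess(tile, compression_ratio, compactness)
    labels <- assign_classes(lab, palette)
    counts[i, ] <- tally_classes(labels)
  }
  per_tile <- tibble::tibble(
    tile = tile_plan$tile,
    row0 = tile_plan$row0,
    col0 = tile_plan$col0,
    collagen = counts[, 1], rbc = counts[, 2],
    myocyte = counts[, 3], background = counts[, 4]
  )
  tissue <- counts[, 1] + counts[, 2] + counts[, 3]
  per_tile$fraction <- ifelse(tissue > 0, counts[, 1] / tissue, NA_real_)

  aggregate <- colSums(counts)
  frac <- fibrosis_fraction(aggregate)
  structure(
    list(per_tile = per_tile, aggregate = aggregate,
         fibrosis_fraction = as.numeric(frac),
         undefined = isTRUE(attr(frac, "undefined")),
         params = list(tile_px = tp, n_tiles = n,
                       compression_ratio = compression_ratio,
                       compactness = compactness)),
    class = "fibrosis_result"
  )
}

#' @export
print.fibrosis_result <- function(x, ...) {
  cat("Fibrosis quantification over", x$params$n_tiles, "tiles of",
      x$params$tile_px, "px\n")
  cat("  aggregate counts:",
      paste(names(x$aggregate), x$aggregate, sep = "=", collapse = ", "), "\n")
  if (x$undefined) {
    cat("  fibrosis fraction: undefined (no tissue pixels)\n")
  } else {
    cat(sprintf("  fibrosis fraction: %.4f\n", x$fibrosis_fraction))
  }
  invisible(x)
}

#' Write / read a class palette as a YAML file
#'
#' @param palette A `class_palette`.
#' @param path File path.
#' @return `read_palette()` returns a `class_palette`.
#' @export
write_palette <- function(palette, path) {
  stopifnot(inherits(palette, "class_palette"))
  yaml::write_yaml(list(
    class_order = tissue_class_levels(),
    centroids_lab = lapply(seq_len(4), function(i) as.list(palette$centroids[i, ])),
    k = palette$k,
    training_meta = palette$training_meta
  ), path)
  invisible(path)
}

#' @rdname write_palette
#' @export
read_palette <- function(path) {
  y <- yaml::read_yaml(path)
  cen <- do.call(rbind, lapply(y$centroids_lab, function(r) unlist(r)))
  dimnames(cen) <- list(tissue_class_levels(), c("L", "a", "b"))
  structure(list(centroids = cen, k = as.integer(y$k),
                 training_meta = y$training_meta),
            class = "class_palette")
}
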