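test_that("tile plans are equally spaced grids that respect slide bounds", {
  plan <- plan_tiles(1500, 1500)
  expect_equal(nrow(plan), 900L)
  expect_equal(attr(plan, "grid"), c(rows = 30L, cols = 30L))
  # contiguous: stride (1500 - 50) / 29 = 50, covering every pixel once
  expect_equal(unique(diff(sort(unique(plan$row0)))), 50)
  expect_equal(min(plan$row0), 1L)
  expect_equal(max(plan$row0) + 50L - 1L, 1500L)

  # non-square slide picks a grid close to the aspect ratio
  plan2 <- plan_tiles(3000, 750, tile_px = 50, n_tiles = 900)
  g <- attr(plan2, "grid")
  expect_equal(unname(g[1] * g[2]), 900L)
  expect_gt(g[["rows"]], g[["cols"]])
  expect_true(all(plan2$row0 + 49 <= 3000) && all(plan2$col0 + 49 <= 750))

  expect_error(plan_tiles(40, 40, tile_px = 50),
               class = "cardioquant_size_error")
})

test_that("superpixel preprocessing averages within superpixels in L*a*b*", {
  sl <- make_trichrome_slide(trichrome_truth(seed = 2), 50, 50)
  out <- superpixel_preprocess(sl$rgb, compression_ratio = 50)
  expect_equal(attr(out, "n_superpixels"), 50L)  # ceil(2500 / 50)

  # constant tile -> constant output equal to the L*a*b* conversion
  const <- array(rep(c(120, 40, 200), each = 2500), dim = c(50, 50, 3))
  smoothed <- superpixel_preprocess(const, 50)
  expect_equal(matrix(smoothed, ncol = 3)[1, ],
               as.vector(rgb_to_lab(matrix(c(120, 40, 200), 1))),
               tolerance = 1e-8)
  expect_lt(max(apply(matrix(smoothed, ncol = 3), 2, stats::sd)), 1e-10)

  # averaging keeps every channel inside the input range
  half <- array(0, dim = c(40, 40, 3))
  half[1:20, , ] <- rep(c(60, 80, 170), each = 20 * 40)
  half[21:40, , ] <- rep(c(180, 70, 70), each = 20 * 40)
  lab_in <- matrix(rgb_to_lab(half), ncol = 3)
  lab_out <- matrix(superpixel_preprocess(half, 50), ncol = 3)
  for (ch in 1:3) {
    expect_gte(min(lab_out[, ch]), min(lab_in[, ch]) - 1e-9)
    expect_lte(max(lab_out[, ch]), max(lab_in[, ch]) + 1e-9)
  }

  # ratio 1 is the identity
  ident <- superpixel_preprocess(half, 1)
  expect_equal(array(rgb_to_lab(half), dim(half)), unclass(ident)[1:length(ident)],
               ignore_attr = TRUE)

  expect_error(superpixel_preprocess(array(0, c(0, 10, 3))),
               class = "cardioquant_param_error")
})

test_that("palette training recovers class colours and is deterministic", {
  sl <- make_trichrome_slide(trichrome_truth(noise_sd = 4, seed = 6), 250, 250)
  px <- slide_lab_pixels(sl, sample_n = 20000)
  pal <- train_palette(px, seed = 42)
  truth_lab <- rgb_to_lab(trichrome_palette_means())
  expect_lt(max(abs(pal$centroids - truth_lab)), 3)

  # determinism
  pal2 <- train_palette(px, seed = 42)
  expect_identical(pal$centroids, pal2$centroids)

  # exactly 4 distinct constant colours: K-means fixed point
  cols <- rbind(c(50, 20, 30), c(60, -40, 10), c(40, 60, -20), c(95, 0, 5))
  toy <- tibble::tibble(
    L = rep(cols[, 1], each = 50), a = rep(cols[, 2], each = 50),
    b = rep(cols[, 3], each = 50),
    class = rep(tissue_class_levels(), each = 50)
  )
  pal3 <- train_palette(toy, seed = 1)
  expect_equal(unname(pal3$centroids), unname(cols), tolerance = 1e-12)

  # class absent from training -> training error
  missing_cls <- px[px$class != "rbc", ]
  expect_error(train_palette(missing_cls),
               class = "cardioquant_training_error")
})

test_that("nearest-centroid assignment matches the declared tie and distance rules", {
  pal <- palette_from_means()
  # pixel exactly at a centroid
  expect_equal(assign_classes(pal$centroids["myocyte", , drop = FALSE], pal), 3L)
  # equidistant pixel breaks toward the lowest class index: use well-spread
  # centroids so the midpoint of classes 1 and 2 is a true two-way tie
  cen <- rbind(c(0, 0, 0), c(10, 0, 0), c(100, 60, 60), c(100, -60, -60))
  dimnames(cen) <- list(tissue_class_levels(), c("L", "a", "b"))
  pal_tie <- structure(list(centroids = cen, k = 4L,
                            training_meta = list(source = "synthetic")),
                       class = "class_palette")
  expect_equal(assign_classes(matrix(c(5, 0, 0), 1), pal_tie), 1L)

  # accuracy >= 0.99 on noisy synthetic tiles (sd 5 RGB units)
  sl <- make_trichrome_slide(trichrome_truth(noise_sd = 5, seed = 8), 200, 200)
  labels <- assign_classes(rgb_to_lab(sl$rgb), pal)
  expect_gte(mean(labels == sl$label_map), 0.99)
})

test_that("the fibrosis fraction excludes background and flags empty denominators", {
  expect_equal(fibrosis_fraction(c(collagen = 10, rbc = 10, myocyte = 10,
                                   background = 999)), 1 / 3)
  expect_equal(fibrosis_fraction(c(collagen = 10, rbc = 10, myocyte = 10,
                                   background = 0)), 1 / 3)
  expect_equal(fibrosis_fraction(c(collagen = 0, rbc = 5, myocyte = 5)), 0)
  out <- fibrosis_fraction(c(collagen = 0, rbc = 0, myocyte = 0,
                             background = 50))
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
  expect_error(fibrosis_fraction(c(collagen = -1, rbc = 0, myocyte = 0)),
               class = "cardioquant_param_error")
})

test_that("whole-slide quantification conserves pixels and recovers known shares", {
  # iid slide, equal fractions, true palette, no noise, no superpixel
  # smoothing: classification is perfect, so the fraction is exactly 1/3
  tr <- trichrome_truth(fractions = c(collagen = .25, rbc = .25,
                                      myocyte = .25, background = .25),
                        noise_sd = 0, seed = 4)
  sl <- make_trichrome_slide(tr, 300, 300, mode = "iid")
  plan <- plan_tiles(300, 300, tile_px = 50, n_tiles = 36)
  res <- quantify_slide(sl, palette_from_means(), plan, compression_ratio = 1)
  truth_counts <- tally_classes(sl$label_map)
  expect_equal(res$fibrosis_fraction,
               truth_counts[1] / sum(truth_counts[1:3]))  # exact on truth
  expect_equal(res$fibrosis_fraction, 1 / 3, tolerance = 0.01)

  # conservation on the contiguous plan
  tallies <- res$per_tile[, c("collagen", "rbc", "myocyte", "background")]
  expect_true(all(rowSums(tallies) == 50 * 50))
  expect_equal(sum(res$aggregate), 300 * 300)
  expect_equal(unname(res$aggregate), unname(colSums(as.matrix(tallies))))

  # all-background slide -> undefined aggregate fraction
  bg <- make_trichrome_slide(
    trichrome_truth(fractions = c(collagen = 0, rbc = 0, myocyte = 0,
                                  background = 1), noise_sd = 0, seed = 1),
    100, 100)
  res_bg <- quantify_slide(bg, palette_from_means(),
                           plan_tiles(100, 100, 50, 4), compression_ratio = 1)
  expect_true(res_bg$undefined)
  expect_true(is.na(res_bg$fibrosis_fraction))

  # recovery through the default pipeline (blobs + SLIC + noise)
  tr2 <- trichrome_truth(fractions = c(collagen = 0.24, rbc = 0.08,
                                       myocyte = 0.48, background = 0.20),
                         noise_sd = 8, seed = 9)
  sl2 <- make_trichrome_slide(tr2, 500, 500)
  res2 <- quantify_slide(sl2, palette_from_means(),
                         plan_tiles(500, 500, 50, 100))
  expect_lt(abs(res2$fibrosis_fraction - 0.30), 0.05)

  # determinism of the full pipeline
  res3 <- quantify_slide(sl2, palette_from_means(),
                         plan_tiles(500, 500, 50, 100))
  expect_identical(glance(res2), glance(res3))
})

test_that("palettes round-trip through YAML", {
  pal <- palette_from_means()
  f <- tempfile(fileext = ".yaml")
  write_palette(pal, f)
  pal2 <- read_palette(f)
  expect_equal(pal$centroids, pal2$centroids)
})
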