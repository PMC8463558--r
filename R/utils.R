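# Internal helpers shared across modules.
#
# Conventions used throughout the package:
#  * images are arrays indexed [row, col(, channel)], 1-based;
#  * movies are arrays indexed [frame, row, col], 1-based;
#  * times are milliseconds from the start of the recording;
#  * RGB channels are 0..255, optical voltages are normalized units.

cq_stop <- function(msg, class = "cardioquant_param_error", data = NULL) {
  cond <- structure(
    class = c(class, "cardioquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    cq_stop(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

#' Convert RGB colours to CIE L*a*b*
#'
#' Wrapper around [grDevices::convertColor()] assuming sRGB input with a
#' D65 white point. Accepts a matrix of colours (rows) or an image array.
#'
#' @param rgb Either an `n x 3` matrix of RGB values in 0..255, or an
#'   `h x w x 3` image array in 0..255.
#' @return The same shape as the input, with channels L (0..100), a, b.
#' @export
rgb_to_lab <- function(rgb) {
  if (is.array(rgb) && length(dim(rgb)) == 3L) {
    d <- dim(rgb)
    m <- matrix(rgb, ncol = 3L)
    lab <- grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
    return(array(lab, dim = d))
  }
  grDevices::convertColor(as.matrix(rgb) / 255, from = "sRGB", to = "Lab")
}

#' @rdname rgb_to_lab
#' @param lab L*a*b* colours, matrix or array, as produced by [rgb_to_lab()].
#' @export
lab_to_rgb <- function(lab) {
  if (is.array(lab) && length(dim(lab)) == 3L) {
    d <- dim(lab)
    m <- matrix(lab, ncol = 3L)
    rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB") * 255
    return(array(pmin(pmax(rgb, 0), 255), dim = d))
  }
  rgb <- grDevices::convertColor(as.matrix(lab), from = "Lab", to = "sRGB") * 255
  pmin(pmax(rgb, 0), 255)
}

# Smooth random field on an h x w grid: a sum of cosines with random
# low frequencies (characteristic wavelength ~ scale pixels), used by the
# blob placement mode of the slide generator. Deterministic under the
# caller's RNG state.
smooth_field <- function(h, w, scale, n_waves = 12L) {
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (j in seq_len(n_waves)) {
    k <- stats::runif(1, 0.5, 1.5) / scale
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1)
    f <- f + a * cos(2 * pi * k * (cos(th) * x + sin(th) * y) + ph)
  }
  f
}

# Separable Gaussian blur of a matrix via two banded matrix products.
# Kernel rows are renormalized so edges keep unit mass.
gauss_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  kern1 <- function(n) {
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > half] <- 0
    K / rowSums(K)
  }
  kern1(nrow(m)) %*% m %*% t(kern1(ncol(m)))
}

tally_classes <- function(labels, n_classes = 4L) {
  tabulate(as.integer(labels), nbins = n_classes)
}

tissue_class_levels <- function() c("collagen", "rbc", "myocyte", "background")
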