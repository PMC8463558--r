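# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fibrosis result into the per-tile table
#'
#' @param x A `fibrosis_result` from [quantify_slide()].
#' @param ... Unused.
#' @return Tibble with one row per tile: window corner, four class counts
#'   and the per-tile fibrosis fraction.
#' @export
tidy.fibrosis_result <- function(x, ...) x$per_tile

#' @rdname tidy.fibrosis_result
#' @export
glance.fibrosis_result <- function(x, ...) {
  tibble::tibble(
    fibrosis_fraction = x$fibrosis_fraction,
    undefined = x$undefined,
    collagen = x$aggregate[["collagen"]],
    rbc = x$aggregate[["rbc"]],
    myocyte = x$aggregate[["myocyte"]],
    background = x$aggregate[["background"]],
    n_tiles = x$params$n_tiles
  )
}

#' Tidy an EP summary
#'
#' @param x An `ep_summary`.
#' @param ... Unused.
#' @return One-row tibble with `cv_long`, `cv_trans`, `apd80`, `erp`.
#' @export
tidy.ep_summary <- function(x, ...) {
  tibble::tibble(cv_long = x$cv_long, cv_trans = x$cv_trans,
                 apd80 = x$apd80, erp = x$erp)
}

#' @rdname tidy.ep_summary
#' @export
glance.ep_summary <- function(x, ...) {
  tibble::tibble(
    cv_long = x$cv_long, cv_trans = x$cv_trans, apd80 = x$apd80, erp = x$erp,
    anisotropy = x$cv_long / x$cv_trans, axis_angle = x$axis_angle,
    r2_long = x$fit_diagnostics$long$r_squared,
    r2_trans = x$fit_diagnostics$trans$r_squared
  )
}

#' Tidy a paired QRS comparison
#'
#' @param x A `paired_ecg_comparison` from [compare_qrs()].
#' @param ... Unused.
#' @return The per-subject table (pre, post, delta, robust flag).
#' @export
tidy.paired_ecg_comparison <- function(x, ...) x$table

#' @rdname tidy.paired_ecg_comparison
#' @export
glance.paired_ecg_comparison <- function(x, ...) {
  tibble::tibble(
    n = x$n, mean_pre = x$mean_pre, sd_pre = x$sd_pre,
    mean_post = x$mean_post, sd_post = x$sd_post,
    n_shortened = x$n_shortened, n_lengthened = x$n_lengthened,
    n_robust = x$n_robust, statistic = x$statistic, p_value = x$p_value
  )
}

#' Plot an activation map as isochrone-coloured raster
#'
#' @param object An `activation_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activation_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$act_ms)),
                    col = seq_len(ncol(object$act_ms)))
  df$act_ms <- as.vector(object$act_ms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$act_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "activation (ms)", na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = "Activation map")
}

#' Plot per-tile fibrosis fractions over the slide layout
#'
#' @param object A `fibrosis_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fibrosis_result <- function(object, ...) {
  df <- object$per_tile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col0, y = .data$row0,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile(width = object$params$tile_px,
                       height = object$params$tile_px) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "tile fibrosis", na.value = "grey85",
                                  limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = sprintf("Per-tile fibrosis (aggregate %.3f)",
                                  object$fibrosis_fraction))
}

#' Plot an averaged beat with its fiducials
#'
#' @param object A `beat_template`.
#' @param intervals Optional `interval_set` measured from this template,
#'   whose fiducials are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beat_template <- function(object, intervals = NULL, ...) {
  t_ms <- (seq_along(object$samples) - 1L) / object$fs * 1000
  df <- data.frame(t_ms = t_ms, mv = object$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$mv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "mV",
                  title = sprintf("Averaged beat (n = %d)", object$n_averaged))
  if (!is.null(intervals)) {
    fid <- attr(intervals, "fiducials")
    marks <- data.frame(t_ms = (fid - 1L) / object$fs * 1000,
                        what = names(fid))
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$t_ms,
                                              colour = .data$what),
                                 linetype = "dashed")
  }
  p
}

#' Paired pre/post QRS plot
#'
#' One line per subject from pre to post; robust shorteners highlighted.
#'
#' @param object A `paired_ecg_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paired_ecg_comparison <- function(object, ...) {
  tab <- object$table
  long <- data.frame(
    subject = rep(tab$subject, 2L),
    time = rep(c("pre", "post"), each = nrow(tab)),
    qrs = c(tab$pre, tab$post),
    robust = rep(tab$robust, 2L)
  )
  long$time <- factor(long$time, levels = c("pre", "post"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$qrs,
                                     group = .data$subject,
                                     colour = .data$robust)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 name = sprintf(">= %g ms shortening",
                                                object$threshold_ms)) +
    ggplot2::labs(x = NULL, y = "QRS (ms)",
                  title = sprintf("Paired QRS, n = %d, Wilcoxon p = %.3g",
                                  object$n, object$p_value))
}
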