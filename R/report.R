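# Result containers and their broom-style tidiers and autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Per-slice SBR table with provenance attributes.
new_sbr_report <- function(tbl, background_coefficient = NA_real_) {
  structure(tbl,
            background_coefficient = background_coefficient,
            class = c("snspd_sbr_report", class(tibble::as_tibble(tbl))))
}

#' @export
print.snspd_sbr_report <- function(x, ...) {
  cat(sprintf("<snspd_sbr_report> %d slice-mode rows (background coefficient %.3g)\n",
              nrow(x), attr(x, "background_coefficient")))
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

#' Tidy an SBR report into its per-slice table
#'
#' @param x An `snspd_sbr_report` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble with one row per slice and mode.
#' @method tidy snspd_sbr_report
#' @export
tidy.snspd_sbr_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row-per-mode summary of an SBR report
#'
#' @param x An `snspd_sbr_report`.
#' @param ... Unused.
#' @return A tibble with `mode`, `n_slices`, `max_mean_sbr`,
#'   `depth_limit_um`, `limit_reached`.
#' @method glance snspd_sbr_report
#' @export
glance.snspd_sbr_report <- function(x, ...) {
  tbl <- tibble::as_tibble(unclass(x))
  dplyr::bind_rows(lapply(split(tbl, tbl$mode), function(d) {
    ok <- d[!d$empty_signal & is.finite(d$mean_sbr) & d$mean_sbr > 0, ]
    dl <- if (nrow(ok) >= 2) {
      suppressWarnings(depth_limit(
        tibble::tibble(depth_um = ok$depth_um, sbr = ok$mean_sbr)))
    } else {
      tibble::tibble(depth_limit_um = NA_real_, limit_reached = FALSE,
                     n_crossings = 0L)
    }
    tibble::tibble(mode = d$mode[1], n_slices = nrow(d),
                   max_mean_sbr = max(ok$mean_sbr, -Inf),
                   depth_limit_um = dl$depth_limit_um,
                   limit_reached = dl$limit_reached)
  }))
}

#' @method autoplot snspd_sbr_report
#' @export
autoplot.snspd_sbr_report <- function(object, ...) {
  tbl <- tidy(object)
  tbl <- tbl[is.finite(tbl$mean_sbr) & tbl$mean_sbr > 0, ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$depth_um, y = .data$mean_sbr,
                                    colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "depth (µm)", y = "mean SBR", colour = "mode") +
    ggplot2::theme_minimal()
}

#' Tidy a bias sweep
#'
#' @param x An `snspd_bias_sweep`.
#' @param ... Unused.
#' @return The sweep tibble (`bias_ua`, `counts`, `normalized`).
#' @method tidy snspd_bias_sweep
#' @export
tidy.snspd_bias_sweep <- function(x, ...) x$sweep

#' @method glance snspd_bias_sweep
#' @export
glance.snspd_bias_sweep <- function(x, ...) {
  tibble::tibble(i_c_estimate_ua = x$i_c_estimate_ua,
                 i_c_true_ua = x$i_c_true_ua,
                 n_points = nrow(x$sweep))
}

#' @method autoplot snspd_bias_sweep
#' @export
autoplot.snspd_bias_sweep <- function(object, ...) {
  ggplot2::ggplot(object$sweep,
                  ggplot2::aes(x = .data$bias_ua, y = .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$i_c_true_ua,
                        linetype = "dotted") +
    ggplot2::labs(x = "bias current (µA)", y = "normalized counts") +
    ggplot2::theme_minimal()
}

#' Tidy a count map into long form
#'
#' @param x An `snspd_count_map`.
#' @param ... Unused.
#' @return Tibble `row`, `col`, `normalized` (NA for unconnected pixels).
#' @method tidy snspd_count_map
#' @export
tidy.snspd_count_map <- function(x, ...) {
  m <- x$map
  tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 normalized = as.vector(m))
}

#' @method autoplot snspd_count_map
#' @export
autoplot.snspd_count_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$normalized)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "counts") +
    ggplot2::theme_minimal()
}

#' @method autoplot snspd_footprint
#' @export
autoplot.snspd_footprint <- function(object, ...) {
  m <- object$weights
  tbl <- tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                        col = rep(seq_len(ncol(m)), each = nrow(m)),
                        weight = as.vector(m))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$weight)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight",
                  subtitle = sprintf("spill-over %.1f%%",
                                     100 * object$spill_over)) +
    ggplot2::theme_minimal()
}

#' @method autoplot snspd_image
#' @export
autoplot.snspd_image <- function(object, ...) {
  m <- object$data
  tbl <- tibble::tibble(x = rep(seq_len(nrow(m)), times = ncol(m)),
                        y = rep(seq_len(ncol(m)), each = nrow(m)),
                        value = as.vector(m))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$mode) +
    ggplot2::theme_minimal()
}

#' Plot a timing-jitter histogram with its Gaussian fit
#'
#' @param jitter_fit Result of [jitter_histogram()].
#' @return A ggplot object.
#' @export
plot_jitter_histogram <- function(jitter_fit) {
  h <- jitter_fit$histogram
  mu <- h$delay_ps[which.max(h$count)]
  curve_tbl <- tibble::tibble(
    delay_ps = seq(min(h$delay_ps), max(h$delay_ps), length.out = 200))
  curve_tbl$count <- max(h$count) *
    exp(-(curve_tbl$delay_ps - mu)^2 / (2 * jitter_fit$sigma_ps^2))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$delay_ps, y = .data$count)) +
    ggplot2::geom_col(width = diff(h$delay_ps[1:2]), fill = "grey40") +
    ggplot2::geom_line(data = curve_tbl, colour = "red") +
    ggplot2::labs(x = "delay (ps)", y = "events",
                  subtitle = sprintf("FWHM %.1f ps", jitter_fit$fwhm_ps)) +
    ggplot2::theme_minimal()
}
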