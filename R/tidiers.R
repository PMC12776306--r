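#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Hill fit
#'
#' @param x A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return One-row tibble: `pH05`, `hill_n` (magnitude), `n_signed`,
#'   `residual_sse`, `converged`, `n_points`.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(pH05 = x$pH05, hill_n = x$hill_n, n_signed = x$n,
                 residual_sse = x$residual_sse, converged = x$converged,
                 n_points = x$n_points)
}

#' @rdname tidy.hill_fit
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) tidy.hill_fit(x)

#' Tidy an occupancy grid into a long voxel table
#'
#' @param x An `occupancy_grid`.
#' @param drop_zero Drop voxels with zero occupancy (default TRUE; the grid
#'   is mostly empty).
#' @param ... Unused.
#' @return Tibble: 0-based `ix`, `iy`, `iz`, voxel centers `x`, `y`, `z`
#'   (Angstrom), `occupancy`.
#' @method tidy occupancy_grid
#' @export
tidy.occupancy_grid <- function(x, drop_zero = TRUE, ...) {
  out <- threshold_voxels(x, iso = 0)
  if (drop_zero) out <- out[out$occupancy > 0, ]
  out
}

#' Tidy a slice map
#'
#' @param x A `slice_map`.
#' @param ... Unused.
#' @return Tibble: voxel centers `x`, `y` (Angstrom), `occupancy`.
#' @method tidy slice_map
#' @export
tidy.slice_map <- function(x, ...) {
  sp <- x$spec
  idx <- expand.grid(i = seq_len(nrow(x$values)), j = seq_len(ncol(x$values)))
  tibble::tibble(
    x = sp$origin[1] + (idx$i - 0.5) * sp$spacing_A,
    y = sp$origin[2] + (idx$j - 0.5) * sp$spacing_A,
    occupancy = as.vector(x$values)
  )
}

#' Plot a slice of an occupancy map
#'
#' 2D heat map of fractional occupancy in the chosen z layer, light-on-dark
#' as occupancy maps are usually shown.
#'
#' @param object A `slice_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slice_map
#' @export
autoplot.slice_map <- function(object, ...) {
  df <- tidy.slice_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$occupancy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  fill = "occupancy",
                  title = sprintf("Occupancy slice, z = %.1f Å",
                                  object$z_level_A)) +
    ggplot2::theme_minimal()
}

#' Plot a contact-number heatmap
#'
#' Residues-by-time heat map of per-frame contact numbers, rows ordered by
#' decreasing average contact number (the average annotated on the right
#' margin of the row labels).
#'
#' @param object Tibble from [contact_numbers()] (class is not required;
#'   call as `autoplot.contact_series(contacts)` or via
#'   [plot_contact_heatmap()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot contact_series
#' @export
autoplot.contact_series <- function(object, ...) {
  avg <- average_contacts(object)
  lev <- rev(avg$residue)
  lab <- rev(sprintf("%s  (%.2f)", avg$residue,
                     avg$average_contact_number))
  df <- dplyr::mutate(object,
                      residue = factor(.data$residue, levels = lev,
                                       labels = lab))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$residue,
                                   fill = .data$n_contacts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = NULL, fill = "contacts",
                  title = "Lipid-residue contact numbers") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.contact_series
#' @param contacts Tibble from [contact_numbers()].
#' @export
plot_contact_heatmap <- function(contacts) autoplot.contact_series(contacts)

#' Plot a fitted pH-activation curve
#'
#' The normalized dose-response points with the fitted Hill curve (bounded
#' in `[0,1]`) and the fitted midpoint marked.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  rng <- range(object$data$pH)
  curve <- tibble::tibble(
    pH = seq(rng[1] - 0.2, rng[2] + 0.2, length.out = 200)
  )
  curve$normalized_response <- hill_curve(curve$pH, object$pH05, object$n)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$pH, .data$normalized_response)) +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$pH05, linetype = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "pH", y = "normalized response",
                  title = sprintf("pH0.5 = %.2f, Hill n = %.1f",
                                  object$pH05, object$hill_n)) +
    ggplot2::theme_minimal()
}

#' Plot residence statistics
#'
#' Event counts and mean/longest durations per residue as a faceted bar
#' chart, the quick visual check on a residence-lifetime table.
#'
#' @param stats Tibble from [residence_stats()].
#' @return A ggplot.
#' @export
plot_residence <- function(stats) {
  df <- stats |>
    tidyr::pivot_longer(cols = c("n_events", "mean_duration_ns",
                                 "longest_duration_ns"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(
      .data$metric, levels = c("n_events", "mean_duration_ns",
                               "longest_duration_ns"),
      labels = c("Total events", "Mean duration (ns)",
                 "Longest event (ns)")))
  ggplot2::ggplot(df, ggplot2::aes(.data$residue, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sweep with its decay annotation
#'
#' @param trace A `sweep_trace`.
#' @param decay Optional `decay_result` for the same sweep; marks the peak
#'   and the 1/e crossing.
#' @return A ggplot.
#' @export
plot_sweep <- function(trace, decay = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(trace),
                       ggplot2::aes(.data$time_s, .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current",
                  title = attr(trace, "sweep_id")) +
    ggplot2::theme_minimal()
  if (!is.null(decay) && isTRUE(decay$crossed)) {
    p <- p +
      ggplot2::geom_vline(xintercept = decay$peak_time_s, linetype = 3) +
      ggplot2::geom_vline(xintercept = decay$peak_time_s + decay$t_1e_s,
                          linetype = 2, colour = "red")
  }
  p
}
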