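# broom-style tidiers and ggplot2 visualisations.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation: the hourly series
#'
#' @param x A `cav_simulation`.
#' @param ... Unused.
#' @return The hourly series tibble with scenario label and seed attached.
#' @export
tidy.cav_simulation <- function(x, ...) {
  dplyr::mutate(x$series, scenario = x$scenario$label, seed = x$seed,
                .before = 1L)
}

#' One-row summary of a simulation
#'
#' @param x A `cav_simulation`.
#' @param ... Unused.
#' @return A one-row tibble: hours simulated, termination reason, final
#'   areas, lumen-area reduction and final NS-index.
#' @export
glance.cav_simulation <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  ns <- tryCatch(ns_index(x$section)$ns_index, error = function(e) NA_real_)
  tibble::tibble(
    scenario = x$scenario$label, seed = x$seed, hours = s$t[n],
    termination = x$termination,
    lumen_area = s$lumen_area[n], intima_area = s$intima_area[n],
    media_area = s$media_area[n],
    lumen_reduction_pct = 100 * (1 - s$lumen_area[n] / s$lumen_area[1L]),
    ns_index = ns)
}

#' @export
tidy.cav_replicates <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(i)
    dplyr::mutate(tidy(x[[i]]), replicate = i, .before = 1L))
}

#' @export
glance.cav_replicates <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(i)
    dplyr::mutate(glance(x[[i]]), replicate = i, .before = 1L))
}

#' @export
tidy.gamma_calibration <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$gamma_star <- attr(x, "gamma_star")
  out
}

#' @export
glance.gamma_calibration <- function(x, ...) {
  tibble::tibble(gamma_star = attr(x, "gamma_star"),
                 n_grid = nrow(x), reps = x$reps[1L])
}

#' @export
tidy.prcc_result <- function(x, ...) tibble::as_tibble(x)

# occupancy palette loosely matching the published cross-section rendering
.OCC_COLOURS <- c(lumen = "white", SMC = "#d73027", ECM = "#fee090",
                  IEL = "#1a1a1a", MP = "#7b3294", exterior = "grey85")

#' Plot a vessel cross-section
#'
#' Raster of the lattice occupancy (lumen, SMC, ECM, IEL, MP, exterior) in
#' real-space coordinates.
#'
#' @param object A `vessel_section`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vessel_section <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$occupant)) +
    ggplot2::geom_tile(width = 1, height = sqrt(3) / 2) +
    ggplot2::scale_fill_manual(values = .OCC_COLOURS, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Plot the time course of a simulation
#'
#' Areas (lumen, intima, media) and intimal contents (SMC, ECM, MP) over the
#' follow-up.
#'
#' @param object A `cav_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cav_simulation <- function(object, ...) {
  s <- tidyr::pivot_longer(object$series, -"t",
                           names_to = "quantity", values_to = "sites")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$t / 24, y = .data$sites)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "sites",
                  title = object$scenario$label)
}

#' PRCC heatmap
#'
#' Parameters x outputs tile map of the partial rank correlation
#' coefficients, one panel per horizon, significant entries starred.
#'
#' @param x A `prcc_result` from [sensitivity_study].
#' @return A ggplot object.
#' @export
plot_prcc <- function(x) {
  df <- tibble::as_tibble(x)
  df$label <- ifelse(df$significant, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$output, y = .data$parameter,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", limits = c(-1, 1)) +
    ggplot2::facet_wrap(~horizon,
                        labeller = ggplot2::as_labeller(
                          function(h) paste0(as.numeric(h) / 168, " wk"))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PRCC")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL
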