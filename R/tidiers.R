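#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a wave orbit into its sampled trajectory
#'
#' @param x A `wave_orbit`.
#' @param ... Unused.
#' @return A tibble with columns `z`, `a`, `b`, `i`.
#' @export
tidy.wave_orbit <- function(x, ...) x$data

#' One-row summary of a wave orbit
#'
#' @param x A `wave_orbit`.
#' @param ... Unused.
#' @return A tibble with `c`, `r`, `i_minus_inf`, `i_plus_inf`, `limit_sum`
#'   (`i_minus_inf + i_plus_inf`, 2 for admissible waves), `z0`, `a_z0`,
#'   `i_z0`, `converged`, `nonneg`, `n`.
#' @export
glance.wave_orbit <- function(x, ...) {
  tibble::tibble(
    c = x$params$c, r = x$params$r,
    i_minus_inf = x$i_minus_inf,
    i_plus_inf = x$i_plus_inf_observed,
    limit_sum = x$i_minus_inf + x$i_plus_inf_observed,
    z0 = x$z0, a_z0 = x$a_z0, i_z0 = x$i_z0,
    converged = x$converged, nonneg = x$nonneg, n = nrow(x$data))
}

#' Tidy a PDE run into long format
#'
#' @param x A `pde_run`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `x`, `A`, `I` (one row per node and
#'   snapshot).
#' @export
tidy.pde_run <- function(x, ...) {
  nt <- length(x$times)
  tibble::tibble(
    t = rep(x$times, each = x$grid$n),
    x = rep(x$grid$x, times = nt),
    A = as.numeric(t(x$A)),
    I = as.numeric(t(x$I)))
}

#' One-row summary of a PDE run
#'
#' @param x A `pde_run`.
#' @param level Front threshold for the summary statistics.
#' @param ... Unused.
#' @return A tibble with `t_end`, `speed_estimate`, `plateau_estimate`,
#'   `min_A`, `min_I`, `instability`.
#' @export
glance.pde_run <- function(x, level = 0.01, ...) {
  tf <- track_front(x, level = level)
  pl <- plateau_density(x, level = level)
  tibble::tibble(
    t_end = max(x$times),
    speed_estimate = tf$speed_estimate,
    plateau_estimate = pl$plateau_estimate,
    min_A = min(x$A), min_I = min(x$I),
    instability = x$instability)
}

#' Tidy a spectrum into a tibble of eigenvalues
#'
#' @param x A `spectrum_result`.
#' @param ... Unused.
#' @return A tibble with `re`, `im`, `translational` (logical marker).
#' @export
tidy.spectrum_result <- function(x, ...) {
  tibble::tibble(
    re = Re(x$eigenvalues), im = Im(x$eigenvalues),
    translational = seq_along(x$eigenvalues) == x$translational_index)
}

#' One-row summary of a spectrum
#'
#' @param x A `spectrum_result`.
#' @param ... Unused.
#' @export
glance.spectrum_result <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, n = x$n,
    translational_re = Re(x$translational_eigenvalue),
    translational_im = Im(x$translational_eigenvalue),
    max_real_excl_translation = x$max_real_excl_translation)
}

#' Plot a wave orbit
#'
#' Profiles of the active density, its derivative and the inactive density
#' against the phase variable, with the turning point marked.
#'
#' @param object A `wave_orbit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wave_orbit <- function(object, ...) {
  d <- tidy(object)
  long <- tibble::tibble(
    z = rep(d$z, 3),
    value = c(d$a, d$b, d$i),
    component = rep(c("a (active)", "b = a'", "i (inactive)"),
                    each = nrow(d)))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$value,
                                          colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (comoving coordinate)", y = NULL,
                  title = sprintf("Traveling-wave orbit, c = %g, r = %g",
                                  object$params$c, object$params$r)) +
    ggplot2::theme_minimal()
  if (is.finite(object$z0))
    p <- p + ggplot2::geom_vline(xintercept = object$z0, linetype = 2,
                                 colour = "grey40")
  p
}

#' Plot snapshots of a PDE run
#'
#' @param object A `pde_run`.
#' @param snapshots Indices of snapshots to draw (default: 5 spread evenly).
#' @param ... Unused.
#' @return A ggplot object with `A` and `I` profiles per time.
#' @export
autoplot.pde_run <- function(object, snapshots = NULL, ...) {
  nt <- length(object$times)
  if (is.null(snapshots))
    snapshots <- unique(round(seq(1, nt, length.out = 5)))
  d <- tidy(object)
  d <- d[d$t %in% object$times[snapshots], ]
  long <- tibble::tibble(
    t = rep(d$t, 2), x = rep(d$x, 2),
    density = c(d$A, d$I),
    species = rep(c("A (active)", "I (inactive)"), each = nrow(d)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$density,
                                     colour = factor(.data$t))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(colour = "t", x = "x", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a trapping triangle in the reduced phase plane
#'
#' @param object A `wave_triangle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wave_triangle <- function(object, ...) {
  v <- object$vertices
  ggplot2::ggplot(v, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_polygon(fill = "orange", alpha = 0.4, colour = "black") +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("Trapping triangle, c = %g, i = %g",
                                  object$c, object$i),
                  x = "a", y = "b") +
    ggplot2::theme_minimal()
}

#' Plot a computed spectrum in the complex plane
#'
#' @param object A `spectrum_result`.
#' @param ... Unused.
#' @return A ggplot object; the translational mode is highlighted.
#' @export
autoplot.spectrum_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$re, y = .data$im,
                                  colour = .data$translational)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "steelblue",
                                            "TRUE" = "red")) +
    ggplot2::labs(x = "Re", y = "Im",
                  title = sprintf("Spectrum of weighted linearization, alpha = %g",
                                  object$alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
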