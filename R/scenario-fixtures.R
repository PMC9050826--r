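#' Resample a wave orbit onto arbitrary abscissae
#'
#' Monotone cubic interpolation of the sampled components on the orbit's
#' span; beyond the span the tails are extended analytically with the decay
#' rates of the limiting linearizations (left: growth at
#' \eqn{\lambda_+(i_{-\infty})}; right: decay at \eqn{\mu_{+\infty}}, or the
#' sub-exponential form \eqn{\propto z e^{-cz/2}} in the critical case), so
#' the resampled profile has no kinks at the truncation points.
#'
#' @param orbit A `wave_orbit`.
#' @param z Query abscissae.
#' @return A list with vectors `a`, `b`, `i` at `z`.
#' @export
resample_orbit <- function(orbit, z) {
  stopifnot(inherits(orbit, "wave_orbit"))
  d <- orbit$data
  zl <- d$z[1]; zr <- d$z[nrow(d)]
  fa <- stats::splinefun(d$z, d$a, method = "monoH.FC")
  fb <- stats::splinefun(d$z, d$b, method = "monoH.FC")
  fi <- stats::splinefun(d$z, d$i, method = "monoH.FC")
  a <- fa(z); b <- fb(z); i <- fi(z)
  p <- orbit$params
  left <- z < zl
  if (any(left)) {
    mu_l <- if (is.finite(orbit$i_minus_inf))
      -p$c / 2 + sqrt(p$c^2 / 4 + orbit$i_minus_inf - 1) else NA_real_
    if (is.finite(mu_l)) {
      dzl <- z[left] - zl
      a[left] <- d$a[1] * exp(mu_l * dzl)
      b[left] <- d$b[1] * exp(mu_l * dzl)
      i0 <- if (is.finite(orbit$i_minus_inf)) orbit$i_minus_inf else d$i[1]
      i[left] <- i0 + (d$i[1] - i0) * exp(mu_l * dzl)
    } else {
      a[left] <- d$a[1]; b[left] <- d$b[1]; i[left] <- d$i[1]
    }
  }
  right <- z > zr
  if (any(right)) {
    dr <- decay_rate(p, orbit$i_plus_inf_observed)
    dzr <- z[right] - zr
    if (isTRUE(dr$sub_exponential) && zr > 0) {
      # a ~ C z e^{-cz/2}
      fac <- (z[right] / zr) * exp(-p$c / 2 * dzr)
      a[right] <- d$a[nrow(d)] * fac
      b[right] <- d$b[nrow(d)] * fac
    } else {
      mu_r <- if (is.finite(dr$mu)) dr$mu else -p$c / 2
      a[right] <- d$a[nrow(d)] * exp(mu_r * dzr)
      b[right] <- d$b[nrow(d)] * exp(mu_r * dzr)
    }
    iend <- orbit$i_plus_inf_observed
    mu_i <- if (is.finite(dr$mu)) dr$mu else -p$c / 2
    i[right] <- iend + (d$i[nrow(d)] - iend) * exp(mu_i * dzr)
  }
  list(a = a, b = b, i = i)
}

#' Gaussian-bump PDE scenario
#'
#' Initial fields for the self-organization run: a Gaussian heap of active
#' particles on a zero inactive background (see
#' [initial_condition_gaussian()]), optionally duplicated into two mirrored
#' heaps to produce two outgoing fronts.
#'
#' @inheritParams initial_condition_gaussian
#' @param two_bumps If `TRUE`, superpose a second heap mirrored at the domain
#'   midpoint.
#' @return List with fields `A`, `I`.
#' @export
make_bump <- function(grid, amplitude = 0.5, center = 0, width = 1,
                      two_bumps = FALSE) {
  f <- initial_condition_gaussian(grid, amplitude, width, center)
  if (two_bumps) {
    mid <- (grid$x_min + grid$x_max) / 2
    f2 <- initial_condition_gaussian(grid, amplitude, width,
                                     2 * mid - center)
    f$A <- f$A + f2$A
  }
  f
}

#' Starting state inside (or beyond) the attractor
#'
#' Returns \eqn{(\mathrm{fraction}\cdot a^*(i_0),\, 0,\, i_0)}. Fractions in
#' `[0, 1]` lie in the proven attractor of the stable set; fractions above 1
#' are allowed but flagged, for must-fail boundary exploration.
#'
#' @param i0 Inactive density in `[i_c, 1)`.
#' @param fraction Multiple of the attractor bound `a_star(i0)`.
#' @inheritParams wave_vector_field
#' @return List with `state` (numeric triple) and `in_attractor` flag.
#' @export
make_attractor_start <- function(i0, fraction, params) {
  params <- as_model_params(params)
  ic <- critical_density(params$c)
  if (i0 < ic - 1e-12 || i0 >= 1)
    stop("`i0` must lie in [i_c, 1)", call. = FALSE)
  if (fraction < 0) stop("`fraction` must be non-negative", call. = FALSE)
  amax <- a_star(max(i0, ic), params)
  list(state = c(fraction * amax, 0, i0),
       in_attractor = fraction <= 1)
}

#' Perturbed traveling-wave initial fields
#'
#' Resamples a computed wave profile onto a PDE grid and adds a seeded,
#' compactly supported random perturbation with an exponential envelope
#' (smoothed node noise scaled to the requested amplitude). Amplitude 0
#' returns the pure wave, whose PDE evolution is a rigid shift at speed `c`
#' up to discretization error.
#'
#' @param orbit A converged `wave_orbit`.
#' @param grid A [grid_1d()].
#' @param amplitude Sup-norm of the perturbation added to `A`.
#' @param decay Envelope rate: the perturbation is damped by
#'   `exp(-decay * |x - x_center|)` outside its support center.
#' @param center Center of the perturbation (defaults to the profile maximum).
#' @param support_width Half-width of the compact support.
#' @param offset Shift applied to the profile so the wave sits inside the
#'   domain (defaults to a quarter of the domain).
#' @param seed Integer seed for the perturbation noise.
#' @return List with fields `A`, `I` and the `offset` used.
#' @export
make_perturbed_wave <- function(orbit, grid, amplitude = 0, decay = 1,
                                center = NULL, support_width = 10,
                                offset = NULL, seed = 0L) {
  stopifnot(inherits(orbit, "wave_orbit"), inherits(grid, "grid_1d"),
            amplitude >= 0)
  if (!orbit$converged) stop("`orbit` must be converged", call. = FALSE)
  if (is.null(offset))
    offset <- grid$x_min + 0.25 * (grid$x_max - grid$x_min)
  prof <- resample_orbit(orbit, grid$x - offset)
  A <- prof$a; I <- prof$i
  if (amplitude > 0) {
    if (is.null(center)) center <- grid$x[which.max(A)]
    rng <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      stats::rnorm(grid$n)
    })
    noise <- stats::filter(rng, rep(1 / 9, 9), sides = 2)
    noise[is.na(noise)] <- 0
    env <- exp(-decay * abs(grid$x - center))
    env[abs(grid$x - center) > support_width] <- 0
    pert <- as.numeric(noise) * env
    if (max(abs(pert)) > 0) pert <- pert * (amplitude / max(abs(pert)))
    if (any(A + pert < 0))
      stop("perturbation amplitude makes A negative; reduce it",
           call. = FALSE)
    A <- A + pert
  }
  list(A = A, I = I, offset = offset)
}

#' Admissible parameter sweep for the wave family
#'
#' Cartesian product of speeds, production rates and left limits, split into
#' admissible combinations (\eqn{i_{-\infty} \in (1, 2 - i_c(c)]}, the range
#' for which a non-negative wave exists) and inadmissible ones kept as
#' must-fail cases.
#'
#' @param c_values,r_values,i_minus_inf_values Numeric vectors.
#' @return A tibble with columns `c`, `r`, `i_minus_inf`, `i_c`,
#'   `admissible`.
#' @examples
#' parameter_grid(c(1, 2), 0, c(1.2, 1.5, 1.9))
#' @export
parameter_grid <- function(c_values, r_values, i_minus_inf_values) {
  if (!length(c_values) || !length(r_values) || !length(i_minus_inf_values))
    return(tibble::tibble(c = numeric(), r = numeric(),
                          i_minus_inf = numeric(), i_c = numeric(),
                          admissible = logical()))
  stopifnot(all(c_values > 0), all(r_values >= 0))
  g <- expand.grid(c = c_values, r = r_values,
                   i_minus_inf = i_minus_inf_values,
                   KEEP.OUT.ATTRS = FALSE)
  g <- tibble::as_tibble(g)
  g$i_c <- critical_density(g$c)
  g$admissible <- g$i_minus_inf > 1 & g$i_minus_inf <= 2 - g$i_c + 1e-12
  g
}

#' Write/read orbit samples as CSV
#'
#' Plain-text round trip for orbit trajectories at full double precision.
#'
#' @param orbit A `wave_orbit`.
#' @param path File path.
#' @return `read_orbit_csv` returns a tibble with columns `z, a, b, i`.
#' @export
write_orbit_csv <- function(orbit, path) {
  stopifnot(inherits(orbit, "wave_orbit"))
  df <- as.data.frame(orbit$data)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_orbit_csv
#' @export
read_orbit_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
}

#' Write/read PDE fields as CSV
#'
#' @param fields List with vectors `A`, `I`.
#' @param grid A [grid_1d()].
#' @param path File path.
#' @return `read_fields_csv` returns a tibble with columns `x, A, I`.
#' @export
write_fields_csv <- function(fields, grid, path) {
  df <- data.frame(x = grid$x, A = fields$A, I = fields$I)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fields_csv
#' @export
read_fields_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
}
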