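#' Configuration for orbit shooting and integration
#'
#' @param epsilon Initial offset along the unit unstable direction. Small
#'   enough that the linearization error O(epsilon^2) is negligible; a
#'   convergence study over `1e-6 ... 1e-8` is part of the test suite.
#' @param rel_tol,abs_tol Integrator tolerances (deSolve `lsoda`/`lsodar`).
#' @param z_max Maximum phase-time span.
#' @param conv_tol Convergence declared when `max(|a|, |b|)` drops below this.
#' @param dz Output sampling step of the orbit.
#' @param tail_fit_window Fraction of the samples (from each end) used when
#'   fitting exponential tail rates.
#' @param blowup |state| beyond which integration aborts as diverged.
#' @return A list of class `shooting_config`.
#' @export
shooting_config <- function(epsilon = 1e-7, rel_tol = 1e-10, abs_tol = 1e-12,
                            z_max = 200, conv_tol = 1e-10, dz = 0.05,
                            tail_fit_window = 0.2, blowup = 1e3) {
  stopifnot(epsilon > 0, conv_tol > 0, is.finite(z_max), z_max > 0, dz > 0,
            tail_fit_window > 0, tail_fit_window <= 0.5)
  structure(list(epsilon = epsilon, rel_tol = rel_tol, abs_tol = abs_tol,
                 z_max = z_max, conv_tol = conv_tol, dz = dz,
                 tail_fit_window = tail_fit_window, blowup = blowup),
            class = "shooting_config")
}

rhs_wave <- function(z, y, parms) {
  a <- y[1]; b <- y[2]; i <- y[3]
  list(c(b,
         a * (a + i) - a - parms$c * b,
         -(1 / parms$c) * a * (a + i + parms$r)))
}

#' Starting state on the unstable manifold
#'
#' The admissible left limits form the unstable set
#' \eqn{\{(0,0,i) : i \in (1, 2 - i_c]\}}; each such point has a
#' one-dimensional unstable manifold whose non-negative branch is the unique
#' candidate for the left tail of a wave. The shooting start is
#' \eqn{(0, 0, i_{-\infty}) + \epsilon\, \hat e_+} with \eqn{\hat e_+} the
#' unit unstable direction oriented toward positive active density.
#'
#' @inheritParams wave_vector_field
#' @param i_minus_inf Left-limit inactive density in \eqn{(1, 2 - i_c]}.
#' @param cfg A [shooting_config()].
#' @return Numeric triple `(a, b, i)`.
#' @export
init_on_unstable_manifold <- function(params, i_minus_inf,
                                      cfg = shooting_config(),
                                      allow_inadmissible = FALSE) {
  params <- as_model_params(params)
  ic <- critical_density(params$c)
  if (i_minus_inf <= 1 ||
      (!allow_inadmissible && i_minus_inf > 2 - ic + 1e-12))
    stop("`i_minus_inf` must lie in (1, 2 - i_c] for an admissible wave",
         call. = FALSE)
  e <- unstable_direction(params, i_minus_inf, unit = TRUE)
  if (e[1] < 0) e <- -e
  c(0, 0, i_minus_inf) + cfg$epsilon * e
}

#' Integrate a wave orbit from a given state
#'
#' Integrates the comoving ODE system with an adaptive stiff/non-stiff solver.
#' The first downward crossing of \eqn{b = 0} (the turning point, where the
#' active density attains its unique maximum) is located by event
#' root-finding; integration then continues until `max(|a|, |b|)` falls below
#' `cfg$conv_tol` or `z_max` is exhausted. The observed right limit is the
#' final inactive density, refined by one application of the closed-form
#' [limit_map()] at the final small-amplitude state (removing the
#' finite-truncation bias) whenever `|b|` is small there.
#'
#' @param state0 Initial `(a, b, i)` triple.
#' @inheritParams init_on_unstable_manifold
#' @param i_minus_inf Prescribed left limit to record (or `NA` for orbits not
#'   started on an unstable manifold).
#' @return A `wave_orbit` object; see [tidy.wave_orbit()] for the sampled
#'   trajectory and [glance.wave_orbit()] for the one-row summary. Fields:
#'   `data` (tibble `z, a, b, i`), `params`, `i_minus_inf`,
#'   `i_plus_inf_observed`, `z0`, `a_z0`, `i_z0` (turning point; `NA` if none
#'   detected), `converged`, `diverged`, `nonneg` (min a and min i above
#'   `-10 * abs_tol`).
#' @export
integrate_orbit <- function(state0, params, cfg = shooting_config(),
                            i_minus_inf = NA_real_) {
  params <- as_model_params(params)
  s0 <- check_state(state0)
  parms <- list(c = params$c, r = params$r)

  z0 <- a_z0 <- i_z0 <- NA_real_
  diverged <- FALSE
  pieces <- list()
  state <- s0
  z_start <- 0

  # phase 1: locate first b = 0 crossing (only if b can turn, i.e. b0 > 0
  # or the orbit starts off the b = 0 plane moving up)
  if (s0[2] > 0) {
    times <- seq(0, cfg$z_max, by = cfg$dz)
    sol <- deSolve::lsodar(y = s0, times = times, func = rhs_wave,
                           parms = parms, rtol = cfg$rel_tol,
                           atol = cfg$abs_tol,
                           rootfunc = function(z, y, p) y[2])
    m <- unname(as.matrix(sol))
    pieces[[1]] <- m
    z_end <- m[nrow(m), 1]
    if (!is.null(attr(sol, "iroot")) || z_end < times[length(times)]) {
      # terminated at the root: the first (downward) b = 0 crossing
      z0 <- z_end
      a_z0 <- m[nrow(m), 2]
      i_z0 <- m[nrow(m), 4]
    }
    state <- m[nrow(m), 2:4]
    z_start <- z_end
  }

  # phase 2: continue until convergence, z_max, or blow-up, in chunks
  chunk <- max(10 * cfg$dz, min(25, cfg$z_max / 8))
  converged <- max(abs(state[1]), abs(state[2])) < cfg$conv_tol
  while (!diverged && (!converged || length(pieces) == 0L) &&
         z_start < cfg$z_max - 1e-9) {
    z_stop <- min(z_start + chunk, cfg$z_max)
    times <- seq(z_start, z_stop, by = cfg$dz)
    if (length(times) < 2L) break
    sol <- try(deSolve::lsoda(y = state, times = times, func = rhs_wave,
                              parms = parms, rtol = cfg$rel_tol,
                              atol = cfg$abs_tol), silent = TRUE)
    if (inherits(sol, "try-error")) { diverged <- TRUE; break }
    m <- unname(as.matrix(sol))
    if (any(!is.finite(m)) || max(abs(m[, 2:4])) > cfg$blowup) {
      m <- m[apply(is.finite(m), 1, all) &
               apply(abs(m[, 2:4, drop = FALSE]) <= cfg$blowup, 1, all), ,
             drop = FALSE]
      diverged <- TRUE
    }
    pieces[[length(pieces) + 1L]] <- if (length(pieces)) m[-1, , drop = FALSE] else m
    if (nrow(m) == 0) break
    state <- m[nrow(m), 2:4]
    z_start <- m[nrow(m), 1]
    converged <- max(abs(state[1]), abs(state[2])) < cfg$conv_tol
  }

  traj <- do.call(rbind, pieces)
  data <- tibble::tibble(z = traj[, 1], a = traj[, 2],
                         b = traj[, 3], i = traj[, 4])

  nonneg <- min(data$a) >= -10 * cfg$abs_tol - 10 * cfg$conv_tol &&
    min(data$i) >= -10 * cfg$abs_tol - 10 * cfg$conv_tol
  a_end <- data$a[nrow(data)]; b_end <- data$b[nrow(data)]
  i_end <- data$i[nrow(data)]
  i_plus <- if (converged && abs(b_end) < 1e-6) {
    # closed-form refinement: treat the final state as a fresh (a0, 0, i0)
    limit_map(max(a_end, 0), i_end, params)
  } else i_end

  structure(list(data = data, params = params,
                 i_minus_inf = i_minus_inf,
                 i_plus_inf_observed = i_plus,
                 z0 = z0, a_z0 = a_z0, i_z0 = i_z0,
                 converged = converged, diverged = diverged,
                 nonneg = nonneg, cfg = cfg),
            class = "wave_orbit")
}

#' Construct a traveling wave by unstable-manifold shooting
#'
#' High-level constructor of the heteroclinic orbit from
#' \eqn{(0, 0, i_{-\infty})} to \eqn{(0, 0, i_{+\infty})} with
#' \eqn{i_{+\infty} = 2 - i_{-\infty}}. For the critical wave
#' (\eqn{i_{+\infty} = i_c} with vanishing discriminant, e.g. \eqn{c = 2},
#' \eqn{i_{-\infty} = 2}) the tail decays only like \eqn{z e^{-cz/2}};
#' the convergence threshold is relaxed to `1e-8` and the span enlarged
#' automatically unless a configuration is supplied.
#'
#' @param c Wave speed > 0.
#' @param r Inactive production rate >= 0.
#' @param i_minus_inf Left-limit inactive density in \eqn{(1, 2 - i_c]}.
#' @param cfg Optional [shooting_config()]; defaults adapt to the critical
#'   case.
#' @param allow_inadmissible If `TRUE`, also shoot from left limits beyond
#'   \eqn{2 - i_c}, for which no non-negative wave exists (the orbit spirals
#'   and its active density goes negative); used for must-fail exploration.
#' @return A `wave_orbit`, see [integrate_orbit()].
#' @examples
#' \donttest{
#' w <- shoot_wave(2, 0, 1.8)
#' glance(w)
#' }
#' @export
shoot_wave <- function(c, r = 0, i_minus_inf, cfg = NULL,
                       allow_inadmissible = FALSE) {
  params <- model_params(c, r)
  if (is.null(cfg)) {
    i_plus_expected <- 2 - i_minus_inf
    disc_plus <- c^2 / 4 + i_plus_expected - 1
    critical <- abs(disc_plus) < 1e-10
    cfg_def <- shooting_config()
    # span budget from the linear rates: growth out of the left state at
    # lambda_plus(i_minus_inf), decay into the right state at |mu_plus_inf|
    lam <- -c / 2 + sqrt(c^2 / 4 + i_minus_inf - 1)
    z_grow <- log(0.3 / cfg_def$epsilon) / lam
    z_decay <- if (disc_plus > 1e-10)
      log(0.3 / cfg_def$conv_tol) / (c / 2 - sqrt(disc_plus))
    else 3 * log(0.3 / 1e-8) / c   # sub-exponential tail allowance
    z_need <- 1.5 * (z_grow + z_decay)
    cfg <- if (critical)
      shooting_config(conv_tol = 1e-8, z_max = max(400, z_need))
    else shooting_config(z_max = max(200, z_need))
  }
  s0 <- init_on_unstable_manifold(params, i_minus_inf, cfg,
                                  allow_inadmissible = allow_inadmissible)
  integrate_orbit(s0, params, cfg, i_minus_inf = i_minus_inf)
}

#' Orbit started inside the attractor of the stable set
#'
#' Integrates from \eqn{(a_0, 0, i_0)} with \eqn{i_0 \in [i_c, 1)} and
#' \eqn{a_0 \in [0, a^*(i_0)]}: such orbits stay non-negative, have
#' \eqn{b \le 0} throughout, and converge to
#' \eqn{(0, 0, \mathrm{limit\_map}(a_0, i_0))}. Inputs outside the proven
#' attractor are integrated anyway but flagged, for boundary exploration.
#'
#' @param a0,i0 Initial active/inactive densities.
#' @inheritParams init_on_unstable_manifold
#' @return A `wave_orbit` with extra field `in_attractor`.
#' @export
attractor_orbit <- function(a0, i0, params, cfg = shooting_config()) {
  params <- as_model_params(params)
  ic <- critical_density(params$c)
  stopifnot(a0 >= 0)
  in_attractor <- i0 >= ic - 1e-12 && i0 < 1 &&
    a0 <= a_star(max(i0, ic), params) + 1e-12
  orb <- integrate_orbit(c(a0, 0, i0), params, cfg)
  orb$in_attractor <- in_attractor
  orb$z0 <- 0; orb$a_z0 <- a0; orb$i_z0 <- i0
  orb
}

#' @export
print.wave_orbit <- function(x, ...) {
  cat(sprintf("<wave_orbit>  c = %g, r = %g\n", x$params$c, x$params$r))
  cat(sprintf("  i_-inf = %s, i_+inf (observed) = %.6g\n",
              format(x$i_minus_inf), x$i_plus_inf_observed))
  if (is.finite(x$z0))
    cat(sprintf("  turning point: z0 = %.4f, a = %.6g, i = %.6g\n",
                x$z0, x$a_z0, x$i_z0))
  cat(sprintf("  converged: %s, non-negative: %s, samples: %d\n",
              x$converged, x$nonneg, nrow(x$data)))
  invisible(x)
}
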