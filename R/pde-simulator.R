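#' One-dimensional uniform grid
#'
#' @param x_min,x_max Domain bounds.
#' @param dx Grid spacing (the node count is chosen so the spacing is exactly
#'   `(x_max - x_min)/(n - 1)`, as close to `dx` as possible).
#' @return A list of class `grid_1d` with `x_min`, `x_max`, `n`, `dx`, `x`.
#' @examples
#' g <- grid_1d(0, 400, dx = 0.1)
#' @export
grid_1d <- function(x_min = 0, x_max = 400, dx = 0.1) {
  stopifnot(x_max > x_min, dx > 0)
  n <- max(3L, as.integer(round((x_max - x_min) / dx)) + 1L)
  structure(list(x_min = x_min, x_max = x_max, n = n,
                 dx = (x_max - x_min) / (n - 1L),
                 x = seq(x_min, x_max, length.out = n)),
            class = "grid_1d")
}

#' Gaussian initial heap of active particles
#'
#' The self-organization scenario: a compact heap
#' \eqn{A(x, 0) = \mathrm{amplitude}\cdot e^{-((x - center)/width)^2}} of
#' active particles on a zero inactive background (the reference case is
#' amplitude 1/2, width 1, center 0, i.e. \eqn{A(x,0) = \tfrac12 e^{-x^2}},
#' \eqn{I \equiv 0}).
#'
#' @param grid A [grid_1d()].
#' @param amplitude Peak height, >= 0.
#' @param width Gaussian length scale.
#' @param center Peak location.
#' @return A list with numeric vectors `A` and `I` on the grid.
#' @export
initial_condition_gaussian <- function(grid, amplitude = 0.5, width = 1,
                                       center = 0) {
  stopifnot(inherits(grid, "grid_1d"), amplitude >= 0, width > 0)
  list(A = amplitude * exp(-((grid$x - center) / width)^2),
       I = numeric(grid$n))
}

# second-order central Laplacian with reflecting (no-flux) ends via ghost
# nodes mirrored across the boundary
laplacian_reflect <- function(u, dx) {
  n <- length(u)
  (c(u[2], u[-n]) - 2 * u + c(u[-1], u[n - 1])) / dx^2
}

#' Advance the reaction-diffusion system in time
#'
#' Method-of-lines solver for
#' \deqn{A_t = A_{xx} + A - A(A+I), \qquad I_t = A(A+I) + rA}
#' with no-flux (reflecting) boundaries. Time stepping is Strang splitting:
#' a Crank-Nicolson half/full step for the diffusion of `A` (sparse LU
#' factorized once) around a classical RK4 step for the local reaction.
#' The scheme is second order in `dx` and in `dt`; states \eqn{(0, K)} are
#' preserved exactly, and `I` is non-decreasing in time pointwise since
#' \eqn{I_t = A(A+I) + rA \ge 0} for non-negative fields. Negative values are
#' never clipped: negativity beyond tolerance is a scheme failure and is
#' reported, not masked.
#'
#' @param fields List with vectors `A`, `I` (e.g. from
#'   [initial_condition_gaussian()]).
#' @param params A [model_params()]; only `r` enters the dynamics, `c` is
#'   carried along as the frame/reference speed for comoving comparisons.
#' @param grid A [grid_1d()].
#' @param t_end Final time.
#' @param dt Time step; default `0.25 * dx`, well inside the reaction
#'   stability limit (diffusion is unconditionally stable under
#'   Crank-Nicolson).
#' @param n_out Number of output snapshots (including t = 0).
#' @return A `pde_run` object: `grid`, `times`, matrices `A`, `I`
#'   (`n_out` rows, one per time; columns are grid nodes), `params`, and
#'   `instability` flag (`TRUE` aborts the stepping when `max |A| > 10`).
#' @examples
#' \donttest{
#' g <- grid_1d(0, 80, dx = 0.2)
#' run <- run_simulation(initial_condition_gaussian(g), model_params(2, 0),
#'                       g, t_end = 25)
#' }
#' @export
run_simulation <- function(fields, params, grid, t_end, dt = NULL,
                           n_out = 51L) {
  params <- as_model_params(params)
  stopifnot(inherits(grid, "grid_1d"), t_end > 0,
            length(fields$A) == grid$n, length(fields$I) == grid$n)
  if (is.null(dt)) dt <- 0.25 * grid$dx
  n_steps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / n_steps
  out_every <- max(1L, round(n_steps / (n_out - 1L)))
  n <- grid$n; dx <- grid$dx; r <- params$r

  # Crank-Nicolson operators for a diffusion half-step of length dt/2:
  # (I - dt/4 L) A_new = (I + dt/4 L) A_old, L with reflecting ends
  Lmat <- Matrix::bandSparse(n, n,
    k = c(-1, 0, 1),
    diagonals = list(rep(1, n - 1), rep(-2, n), rep(1, n - 1))) / dx^2
  Lmat[1, 2] <- 2 / dx^2        # ghost-node mirror at the ends
  Lmat[n, n - 1] <- 2 / dx^2
  Id <- Matrix::Diagonal(n)
  th <- dt / 4
  Alhs <- Id - th * Lmat
  Arhs <- Id + th * Lmat
  LU <- Matrix::lu(Alhs)

  react <- function(A, I) {
    AI <- A * (A + I)
    list(dA = A - AI, dI = AI + r * A)
  }
  rk4_reaction <- function(A, I, h) {
    k1 <- react(A, I)
    k2 <- react(A + h / 2 * k1$dA, I + h / 2 * k1$dI)
    k3 <- react(A + h / 2 * k2$dA, I + h / 2 * k2$dI)
    k4 <- react(A + h * k3$dA, I + h * k3$dI)
    list(A = A + h / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA),
         I = I + h / 6 * (k1$dI + 2 * k2$dI + 2 * k3$dI + k4$dI))
  }
  diffuse_half <- function(A) as.numeric(Matrix::solve(LU, Arhs %*% A))

  A <- as.numeric(fields$A); I <- as.numeric(fields$I)
  times <- 0
  Aout <- list(A); Iout <- list(I)
  instability <- FALSE
  for (s in seq_len(n_steps)) {
    A <- diffuse_half(A)
    st <- rk4_reaction(A, I, dt)
    A <- diffuse_half(st$A); I <- st$I
    if (max(abs(A)) > 10 || any(!is.finite(A)) || any(!is.finite(I))) {
      instability <- TRUE
      warning("instability detected (max |A| > 10); run aborted",
              call. = FALSE)
      break
    }
    if (s %% out_every == 0L || s == n_steps) {
      times <- c(times, s * dt)
      Aout[[length(Aout) + 1L]] <- A
      Iout[[length(Iout) + 1L]] <- I
    }
  }
  structure(list(grid = grid, times = times,
                 A = do.call(rbind, Aout), I = do.call(rbind, Iout),
                 params = params, dt = dt, instability = instability),
            class = "pde_run")
}

#' @export
print.pde_run <- function(x, ...) {
  cat(sprintf("<pde_run>  x in [%g, %g] (n = %d, dx = %g), t in [0, %g] (%d snapshots)\n",
              x$grid$x_min, x$grid$x_max, x$grid$n, x$grid$dx,
              max(x$times), length(x$times)))
  if (x$instability) cat("  ** instability detected; run truncated **\n")
  invisible(x)
}

#' Track the invasion front and estimate its asymptotic speed
#'
#' The front position at each output time is the rightmost point where `A`
#' crosses `level` (linear interpolation between nodes). Pulled fronts
#' approach their asymptotic speed slowly, with a \eqn{1/t} speed correction
#' (logarithmic position shift); the speed estimate therefore fits
#' \eqn{x_f(t) = c\,t - k\log t + d} by least squares over the last half of
#' the time window. A plain linear slope is also reported.
#'
#' @param run A `pde_run`.
#' @param level Threshold on `A` defining the front.
#' @param fit_fraction Final fraction of output times used in the fit.
#' @return List with `front` (tibble `t`, `x_front`), `speed_estimate`
#'   (log-corrected), `speed_linear`, `boundary_warning` (`TRUE` when the
#'   front came within 10 cells of the right boundary; positions beyond that
#'   point are dropped).
#' @export
track_front <- function(run, level = 0.01, fit_fraction = 0.5) {
  stopifnot(inherits(run, "pde_run"), level > 0)
  x <- run$grid$x
  pos <- vapply(seq_along(run$times), function(k) {
    A <- run$A[k, ]
    above <- which(A >= level)
    if (!length(above)) return(NA_real_)
    jr <- max(above)
    if (jr == length(x)) return(x[jr])
    # interpolate the downward crossing between node jr and jr + 1
    x[jr] + (level - A[jr]) / (A[jr + 1] - A[jr]) * (x[jr + 1] - x[jr])
  }, numeric(1))
  front <- tibble::tibble(t = run$times, x_front = pos)
  guard <- run$grid$x_max - 10 * run$grid$dx
  boundary_warning <- any(is.finite(pos) & pos > guard)
  front_ok <- front[is.finite(front$x_front) & front$x_front <= guard, ]
  if (nrow(front_ok) < 5L)
    return(list(front = front, speed_estimate = NA_real_,
                speed_linear = NA_real_, boundary_warning = boundary_warning))
  tmin <- stats::quantile(front_ok$t, 1 - fit_fraction)
  fo <- front_ok[front_ok$t >= tmin & front_ok$t > 0, ]
  lin <- stats::lm(x_front ~ t, data = fo)
  corr <- stats::lm(x_front ~ t + log(t), data = fo)
  list(front = front,
       speed_estimate = unname(stats::coef(corr)["t"]),
       speed_linear = unname(stats::coef(lin)["t"]),
       boundary_warning = boundary_warning)
}

#' Plateau density of inactive particles behind the front
#'
#' Averages the final-time `I` field over the window
#' `[x_front - 2 * margin, x_front - margin]`, restricted to points where the
#' active density has effectively vanished (`A < a_tol`). Behind the front
#' the system has reached its steady state \eqn{(0, I_\infty)}; starting from
#' a compact heap on an empty background the growth process leaves
#' \eqn{I = 2} behind.
#'
#' @param run A `pde_run`.
#' @param margin Distance defining the averaging window.
#' @param level Front threshold passed to [track_front()].
#' @param a_tol Active density below which a point counts as separated.
#' @return List with `plateau_estimate` and `status` (`"ok"` or
#'   `"not-yet-separated"`).
#' @export
plateau_density <- function(run, margin = 25, level = 0.01, a_tol = 1e-6) {
  stopifnot(inherits(run, "pde_run"))
  tf <- track_front(run, level = level)
  xf <- tf$front$x_front
  xf <- xf[is.finite(xf)]
  if (!length(xf))
    return(list(plateau_estimate = NA_real_, status = "not-yet-separated"))
  xfin <- xf[length(xf)]
  k <- length(run$times)
  sel <- run$grid$x >= xfin - 2 * margin & run$grid$x <= xfin - margin &
    run$A[k, ] < a_tol
  if (!any(sel) || xfin < 2 * margin)
    return(list(plateau_estimate = NA_real_, status = "not-yet-separated"))
  list(plateau_estimate = mean(run$I[k, sel]), status = "ok")
}

#' Compare a PDE front with a traveling-wave profile in the comoving frame
#'
#' Interpolates the wave orbit onto the grid, shifts it so its active-density
#' maximum coincides with the maximum of the final PDE snapshot, and reports
#' sup-norm discrepancies of `A` vs `a` and `I` vs `i` over a window around
#' the front. The shift is then polished over `+/- 2 dx` so the reported
#' discrepancy is a local optimum.
#'
#' @param run A converged `pde_run`.
#' @param orbit A `wave_orbit` with the same `(c, r)`.
#' @param half_width Half-width of the comparison window around the front.
#' @param snapshot Row index of the snapshot to compare (default: last).
#' @return List with `sup_A`, `sup_I`, `shift`, `window` (x-range used).
#' @export
comoving_profile_compare <- function(run, orbit, half_width = 20,
                                     snapshot = NULL) {
  stopifnot(inherits(run, "pde_run"), inherits(orbit, "wave_orbit"))
  if (abs(run$params$c - orbit$params$c) > 1e-12 ||
      abs(run$params$r - orbit$params$r) > 1e-12)
    stop("`run` and `orbit` must share (c, r)", call. = FALSE)
  if (is.null(snapshot)) snapshot <- length(run$times)
  A <- run$A[snapshot, ]; I <- run$I[snapshot, ]
  x <- run$grid$x
  x_peak_pde <- x[which.max(A)]
  z_peak_orb <- orbit$data$z[which.max(orbit$data$a)]
  win <- abs(x - x_peak_pde) <= half_width
  sups <- function(shift) {
    prof <- resample_orbit(orbit, x - shift)
    c(sup_A = max(abs(A[win] - prof$a[win])),
      sup_I = max(abs(I[win] - prof$i[win])))
  }
  shift0 <- x_peak_pde - z_peak_orb
  shifts <- shift0 + seq(-2 * run$grid$dx, 2 * run$grid$dx,
                         by = run$grid$dx / 4)
  vals <- vapply(shifts, function(s) max(sups(s)), numeric(1))
  bst <- which.min(vals)
  s <- sups(shifts[bst])
  list(sup_A = unname(s["sup_A"]), sup_I = unname(s["sup_I"]),
       shift = shifts[bst], discrepancy = vals[bst],
       window = c(x_peak_pde - half_width, x_peak_pde + half_width))
}
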