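# quadrature on orbit samples: cubic-spline resample onto a uniform grid,
# then composite Simpson (sampled orbits are smooth, so the spline error
# is far below the identity tolerances)
quad_samples <- function(z, y, refine = 4L) {
  stopifnot(length(z) == length(y), length(z) >= 3L)
  sf <- stats::splinefun(z, y, method = "natural")
  n <- refine * (length(z) - 1L)
  if (n %% 2L == 1L) n <- n + 1L               # even interval count
  zz <- seq(z[1], z[length(z)], length.out = n + 1L)
  h <- zz[2] - zz[1]
  yy <- sf(zz)
  w <- rep(c(4, 2), length.out = n - 1L)
  h / 3 * (yy[1] + yy[n + 1L] + sum(w * yy[2:n]))
}

orbit_window <- function(orbit, z1, z2) {
  d <- orbit$data
  keep <- d$z >= z1 - 1e-12 & d$z <= z2 + 1e-12
  if (sum(keep) < 5L)
    stop("window [z1, z2] contains too few orbit samples", call. = FALSE)
  d[keep, ]
}

#' Integral identities along a wave orbit
#'
#' Between two phase-times with vanishing \eqn{b}, the wave system implies
#' three integral identities for \eqn{\mathcal{A}(t) = \int_{z_1}^t a\,dz}:
#' \deqn{\int a(a+i)\,dz = \mathcal{A}(z_2) + c\,[a(z_2) - a(z_1)],}
#' \deqn{i(z_1) - i(z_2) = \tfrac{1+r}{c}\,\mathcal{A}(z_2) + a(z_2) - a(z_1),}
#' \deqn{\int a(a+i)\,dz = [i(z_2) + a(z_2)]\,\mathcal{A}(z_2)
#'   + \tfrac{1+r}{2c}\mathcal{A}(z_2)^2 + \tfrac{a(z_1)^2 - a(z_2)^2}{2c}.}
#' All integrals are evaluated by quadrature on the orbit samples; the three
#' absolute residuals measure self-consistency of the computed orbit. The
#' endpoint terms \eqn{a(z_2) - a(z_1)} vanish on the full span of a
#' heteroclinic orbit (the active density vanishes at both limits), leaving
#' the familiar mass-transfer relation
#' \eqn{i_{-\infty} - i_{+\infty} = \tfrac{1+r}{c}\int a\,dz}; on a
#' half-window ending at the turning point they do not, and dropping them
#' breaks the identity by exactly \eqn{a(z_0)}.
#'
#' @param orbit A `wave_orbit`.
#' @param z1,z2 Window endpoints; `b` must be below `b_tol` at both (e.g. the
#'   two ends of a converged orbit, or the left tail and the turning point).
#'   Defaults to the full sampled span.
#' @param b_tol Tolerance on `|b|` at the endpoints.
#' @return Named numeric triple of absolute residuals
#'   (`flux`, `mass_transfer`, `energy`).
#' @export
integral_identities <- function(orbit, z1 = NULL, z2 = NULL, b_tol = 1e-6) {
  stopifnot(inherits(orbit, "wave_orbit"))
  d <- orbit$data
  if (is.null(z1)) z1 <- d$z[1]
  if (is.null(z2)) z2 <- d$z[nrow(d)]
  w <- orbit_window(orbit, z1, z2)
  b1 <- w$b[1]; b2 <- w$b[nrow(w)]
  if (abs(b1) > b_tol || abs(b2) > b_tol)
    stop(sprintf("endpoints must have |b| <= %g (got %g, %g)",
                 b_tol, abs(b1), abs(b2)), call. = FALSE)
  cc <- orbit$params$c; r <- orbit$params$r
  a1 <- w$a[1]; a2 <- w$a[nrow(w)]
  i1 <- w$i[1]; i2 <- w$i[nrow(w)]
  if (max(abs(w$a)) == 0) return(c(flux = 0, mass_transfer = 0, energy = 0))
  A2 <- quad_samples(w$z, w$a)
  Iaa <- quad_samples(w$z, w$a * (w$a + w$i))
  c(flux = abs(Iaa - (A2 + cc * (a2 - a1))),
    mass_transfer = abs((i1 - i2) - (1 + r) / cc * A2 - (a2 - a1)),
    energy = abs(Iaa - ((i2 + a2) * A2 + (1 + r) / (2 * cc) * A2^2 +
                          (a1^2 - a2^2) / (2 * cc))))
}

#' Shape verification of a wave orbit
#'
#' A bounded non-negative wave has a strictly decreasing inactive density and
#' an active density with a unique local (and global) maximum, attained at
#' the turning point where \eqn{b = a'} first vanishes.
#'
#' @param orbit A `wave_orbit`.
#' @param tol Tolerance for monotonicity violations of `i` and for negativity
#'   of `a` and `i`.
#' @return A list with `i_monotone_violations` (count of increases of `i`
#'   beyond `tol`), `n_maxima_a` (interior local maxima of `a` above noise),
#'   `min_a`, `min_i`, `z_at_max_a`, and `pass`.
#' @export
verify_shape <- function(orbit, tol = 1e-9) {
  stopifnot(inherits(orbit, "wave_orbit"))
  d <- orbit$data
  di <- diff(d$i)
  viol <- sum(di > tol)
  a <- d$a
  amax <- max(a)
  n_max <- 0L
  if (amax > 0) {
    noise <- max(1e-6 * amax, 100 * orbit$cfg$conv_tol)
    s <- sign(diff(a))
    s <- s[s != 0]
    # count descents following ascents among significant samples
    asig <- a > noise
    ii <- which(asig)
    if (length(ii) >= 3L) {
      aa <- a[ii]
      da <- diff(aa)
      n_max <- sum(da[-length(da)] > 0 & da[-1] < 0)
    }
    if (n_max == 0L && any(asig)) n_max <- 1L  # monotone rise to the boundary
  }
  constant <- amax <= max(10 * orbit$cfg$conv_tol, 1e-12)
  pass <- viol == 0L && min(d$a) >= -tol && min(d$i) >= -tol &&
    (constant || n_max == 1L)
  list(i_monotone_violations = viol, n_maxima_a = n_max,
       min_a = min(d$a), min_i = min(d$i),
       z_at_max_a = d$z[which.max(a)], pass = pass)
}

#' Exponential tail rates of a wave orbit
#'
#' Fits \eqn{\log a} linearly in \eqn{z} over a window at either end of the
#' orbit and compares with the analytic rates
#' \eqn{\mu_{\pm\infty} = -c/2 + \sqrt{c^2/4 + i_{\pm\infty} - 1}}
#' (the left tail grows at \eqn{\lambda_+(i_{-\infty}) > 0}, the right tail
#' decays at \eqn{\mu_{+\infty} < 0}). In the critical case (vanishing
#' discriminant at the right limit) the decay is of order
#' \eqn{z e^{-cz/2}}; the fit then uses \eqn{\log(a/z)} and is compared to
#' \eqn{-c/2}.
#'
#' @param orbit A converged `wave_orbit`.
#' @param side `"left"` or `"right"`.
#' @param window Fraction of samples used (defaults to the shooting
#'   configuration's `tail_fit_window`).
#' @return List with `status` (`"ok"` or `"insufficient-data"`), `rate`
#'   (fitted), `expected` (analytic), `sub_exponential`, `n` (points used).
#' @export
tail_rate_fit <- function(orbit, side = c("right", "left"), window = NULL) {
  stopifnot(inherits(orbit, "wave_orbit"))
  side <- match.arg(side)
  if (is.null(window)) window <- orbit$cfg$tail_fit_window
  d <- orbit$data
  n <- nrow(d)
  k <- max(3L, floor(window * n))
  idx <- if (side == "left") seq_len(k) else seq.int(n - k + 1L, n)
  dd <- d[idx, ]
  dd <- dd[dd$a > 0, ]
  if (nrow(dd) < 30L)
    return(list(status = "insufficient-data", rate = NA_real_,
                expected = NA_real_, sub_exponential = NA, n = nrow(dd)))
  if (side == "left") {
    expected <- decay_rate(orbit$params, orbit$i_minus_inf)
    # left tail: a grows out of the fixed point at rate lambda_plus > 0
    exp_rate <- -orbit$params$c / 2 +
      sqrt(orbit$params$c^2 / 4 + orbit$i_minus_inf - 1)
    fit <- stats::lm(log(a) ~ z, data = dd)
    return(list(status = "ok", rate = unname(stats::coef(fit)[2]),
                expected = exp_rate, sub_exponential = FALSE, n = nrow(dd)))
  }
  dr <- decay_rate(orbit$params, orbit$i_plus_inf_observed)
  if (isTRUE(dr$sub_exponential) ||
      abs(orbit$params$c^2 / 4 + orbit$i_plus_inf_observed - 1) < 1e-6) {
    # critical tail a ~ C (z - s) e^{-cz/2}: the phase origin of the orbit is
    # arbitrary, so the linear offset s is profiled out by least squares
    # before reading off the exponential rate
    dd <- dd[dd$z > 0, ]
    rss <- function(s) {
      f <- stats::lm(log(a) - log(z - s) ~ z, data = dd)
      sum(stats::resid(f)^2)
    }
    s_hat <- stats::optimize(rss, c(0, min(dd$z) - 1))$minimum
    fit <- stats::lm(log(a) - log(z - s_hat) ~ z, data = dd)
    return(list(status = "ok", rate = unname(stats::coef(fit)[2]),
                expected = -orbit$params$c / 2, sub_exponential = TRUE,
                n = nrow(dd)))
  }
  fit <- stats::lm(log(a) ~ z, data = dd)
  list(status = "ok", rate = unname(stats::coef(fit)[2]),
       expected = dr$mu, sub_exponential = FALSE, n = nrow(dd))
}

#' Turning-point consistency of a shooting orbit
#'
#' At the first \eqn{b = 0} crossing the orbit state must satisfy the
#' closed-form relation of [turning_point_active()], together with
#' \eqn{a_{z_0} + i_{z_0} \le 1}, \eqn{i_{z_0} \in (i_c, 1)},
#' \eqn{i_{z_0} > 2 - i_{-\infty}}, and membership in the attractor bound
#' \eqn{a_{z_0} \le a^*(i_{z_0})}.
#'
#' @param orbit A `wave_orbit` with a detected turning point and a prescribed
#'   left limit.
#' @return A list with `residual` (absolute difference between the measured
#'   and closed-form active density at the turning point) and logical checks
#'   `sum_le_one`, `i_z0_in_range`, `i_z0_above_mirror`, `below_a_star`.
#' @export
turning_point_consistency <- function(orbit) {
  stopifnot(inherits(orbit, "wave_orbit"))
  if (!is.finite(orbit$z0) || !is.finite(orbit$i_minus_inf))
    stop("orbit has no detected turning point / prescribed left limit",
         call. = FALSE)
  p <- orbit$params
  ic <- critical_density(p$c)
  tp <- turning_point_active(orbit$i_z0, orbit$i_minus_inf, p)
  if (!tp$admissible)
    stop("turning-point relation inadmissible for this orbit", call. = FALSE)
  list(residual = abs(orbit$a_z0 - tp$a_z0),
       sum_le_one = orbit$a_z0 + orbit$i_z0 <= 1 + 1e-9,
       i_z0_in_range = orbit$i_z0 > ic - 1e-9 && orbit$i_z0 < 1,
       i_z0_above_mirror = orbit$i_z0 > 2 - orbit$i_minus_inf - 1e-9,
       below_a_star = orbit$a_z0 <= a_star(max(orbit$i_z0, ic), p) + 1e-9)
}
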