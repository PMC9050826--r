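#' Vector field of the traveling-wave ODE system
#'
#' Right-hand side of the comoving first-order system for a state
#' \eqn{(a, b, i)} with \eqn{b = a'}:
#' \deqn{a' = b, \quad b' = a(a+i) - a - cb, \quad i' = -\tfrac{1}{c} a(a+i+r).}
#' Every point \eqn{(0, 0, K)} is a fixed point, so the system carries a
#' continuum of equilibria rather than isolated ones.
#'
#' @param params A [model_params()] object.
#' @param state Numeric triple `(a, b, i)`.
#' @return Numeric triple `(a', b', i')`.
#' @examples
#' wave_vector_field(model_params(2, 0), c(0.1, 0, 0.5))
#' @export
wave_vector_field <- function(params, state) {
  params <- as_model_params(params)
  s <- check_state(state)
  a <- s[1]; b <- s[2]; i <- s[3]
  c(b,
    a * (a + i) - a - params$c * b,
    -(1 / params$c) * a * (a + i + params$r))
}

#' Jacobian of the traveling-wave vector field
#'
#' @inheritParams wave_vector_field
#' @return A 3x3 numeric matrix; at a fixed point `(0, 0, K)` its third
#'   column vanishes, reflecting the continuum of equilibria (the
#'   linearization is degenerate there, with a zero eigenvalue along the
#'   inactive direction).
#' @examples
#' wave_jacobian(model_params(2, 0), c(0, 0, 1.8))
#' @export
wave_jacobian <- function(params, state) {
  params <- as_model_params(params)
  s <- check_state(state)
  a <- s[1]; i <- s[3]; cc <- params$c; r <- params$r
  matrix(c(0,                       1,   0,
           2 * a + i - 1,         -cc,   a,
           -(2 * a + i + r) / cc,   0,  -a / cc),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("a", "b", "i"), c("a", "b", "i")))
}

#' Eigen-system of the linearization at a fixed point (0, 0, K)
#'
#' The eigenvalues are \eqn{\lambda_0 = 0} and
#' \eqn{\lambda_\pm = -c/2 \pm \sqrt{c^2/4 + K - 1}}. For \eqn{K > 1} the
#' fixed point has a one-dimensional unstable manifold; for \eqn{K < 1} it is
#' stable (in the hyperbolic directions). When the discriminant
#' \eqn{c^2/4 + K - 1} vanishes the two nonzero eigenvalues collide at
#' \eqn{-c/2} with algebraic multiplicity 2 but geometric multiplicity 1;
#' the `degenerate` flag is set and only the single eigen-direction is
#' returned (no fabricated second vector). A negative discriminant gives a
#' complex pair (`is_complex = TRUE`), the spiraling regime that rules out
#' non-negative waves.
#'
#' @inheritParams wave_vector_field
#' @param K Inactive density of the fixed point (any real value).
#' @return A list of class `eigensystem` with elements `lambda0` (always 0),
#'   `lambda_plus`, `lambda_minus` (complex when `is_complex`),
#'   `discriminant`, `vectors` (3-column matrix: directions for
#'   `lambda0`, `lambda_plus`, `lambda_minus`; the latter two are `NA` in the
#'   complex case and collapse to one column flagged by `degenerate`),
#'   `is_complex`, `degenerate`.
#' @examples
#' fixed_point_eigensystem(model_params(2, 0), K = 2)
#' fixed_point_eigensystem(model_params(2, 0), K = 0)$degenerate
#' @export
fixed_point_eigensystem <- function(params, K) {
  params <- as_model_params(params)
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K))
  cc <- params$c; r <- params$r
  disc <- cc^2 / 4 + K - 1
  e0 <- c(a = 0, b = 0, i = 1)     # along the continuum of fixed points
  tol <- 1e-12 * max(1, cc^2)
  if (disc < -tol) {
    lp <- complex(real = -cc / 2, imaginary = sqrt(-disc))
    lm <- Conj(lp)
    vectors <- cbind(e0 = e0, e_plus = c(NA, NA, NA), e_minus = c(NA, NA, NA))
    out <- list(lambda0 = 0, lambda_plus = lp, lambda_minus = lm,
                discriminant = disc, vectors = vectors,
                is_complex = TRUE, degenerate = FALSE)
  } else if (disc <= tol) {
    lam <- -cc / 2
    # single eigen-direction for the repeated root (geometric multiplicity 1)
    v <- eigvec_at_fixed_point(cc, r, K, lam)
    vectors <- cbind(e0 = e0, e_repeated = v)
    out <- list(lambda0 = 0, lambda_plus = lam, lambda_minus = lam,
                discriminant = disc, vectors = vectors,
                is_complex = FALSE, degenerate = TRUE)
  } else {
    sq <- sqrt(disc)
    lp <- -cc / 2 + sq
    lm <- -cc / 2 - sq
    vp <- eigvec_at_fixed_point(cc, r, K, lp)
    vm <- eigvec_at_fixed_point(cc, r, K, lm)
    vectors <- cbind(e0 = e0, e_plus = vp, e_minus = vm)
    out <- list(lambda0 = 0, lambda_plus = lp, lambda_minus = lm,
                discriminant = disc, vectors = vectors,
                is_complex = FALSE, degenerate = FALSE)
  }
  structure(out, class = "eigensystem")
}

# eigenvector of D_{(0,0,K)} for a nonzero eigenvalue lambda:
# rows (0,1,0), (K-1,-c,0), (-(K+r)/c,0,0); v = (1, lambda, -(K+r)/(c*lambda))
eigvec_at_fixed_point <- function(cc, r, K, lambda) {
  if (abs(lambda) < 1e-300) return(c(a = 0, b = 0, i = 1))
  c(a = 1, b = lambda, i = -(K + r) / (cc * lambda))
}

#' @export
print.eigensystem <- function(x, ...) {
  cat("<eigensystem>  lambda0 = 0, lambda+ =", format(x$lambda_plus),
      ", lambda- =", format(x$lambda_minus),
      if (x$is_complex) " (complex pair)" else if (x$degenerate) " (repeated)" else "",
      "\n")
  invisible(x)
}

#' Critical limiting inactive density
#'
#' \eqn{i_c(c) = \max\{0, 1 - c^2/4\}}: the smallest right-limit inactive
#' density for which a non-negative traveling wave of speed `c` can exist
#' (below it the linearization at the right limit has complex eigenvalues and
#' the active density would spiral through negative values).
#'
#' @param c Wave speed, > 0 (vectorized).
#' @return `max(0, 1 - c^2/4)`, same length as `c`.
#' @examples
#' critical_density(c(1, 2, 3))
#' @export
critical_density <- function(c) {
  stopifnot(is.numeric(c), all(is.finite(c)))
  if (any(c <= 0)) stop("wave speed `c` must be positive", call. = FALSE)
  pmax(0, 1 - c^2 / 4)
}

#' Minimal wave speed admitting full invasion
#'
#' Smallest speed `c` for which the critical density vanishes, i.e. for which
#' a wave with right limit \eqn{i_{+\infty} = 0} (invasion into empty space)
#' is admissible. Found by bisection on `critical_density(c) > 0`.
#'
#' @param tol Bisection half-width at termination.
#' @return The minimal speed (a single number).
#' @examples
#' minimal_invasion_speed()
#' @export
minimal_invasion_speed <- function(tol = 1e-12) {
  lo <- 1e-8              # i_c > 0 here
  hi <- 64                # i_c = 0 here
  stopifnot(critical_density(lo) > 0, critical_density(hi) == 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (critical_density(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Asymptotic decay/growth rate of the active density at a limiting state
#'
#' Rate \eqn{\mu = -c/2 + \sqrt{c^2/4 + i_{lim} - 1}} of the active component
#' approaching a limit with inactive density `i_limit`. At the left limit
#' (`i_limit` > 1) this is positive: the wave grows out of the unstable state.
#' At the right limit it is negative. When the discriminant vanishes the decay
#' is sub-exponential, of order \eqn{z e^{-cz/2}} (flagged); when it is
#' negative no real rate exists (spiraling, flagged).
#'
#' @inheritParams wave_vector_field
#' @param i_limit Limiting inactive density.
#' @return List with `mu` (rate; `NA` when spiraling), `sub_exponential`,
#'   and `spiraling` flags.
#' @examples
#' decay_rate(model_params(2, 0), 0.2)
#' decay_rate(model_params(2, 0), 0)$sub_exponential
#' @export
decay_rate <- function(params, i_limit) {
  params <- as_model_params(params)
  stopifnot(is.numeric(i_limit), length(i_limit) == 1L, is.finite(i_limit))
  cc <- params$c
  disc <- cc^2 / 4 + i_limit - 1
  tol <- 1e-12 * max(1, cc^2)
  if (disc < -tol) {
    list(mu = NA_real_, sub_exponential = FALSE, spiraling = TRUE)
  } else if (disc <= tol) {
    list(mu = -cc / 2, sub_exponential = TRUE, spiraling = FALSE)
  } else {
    list(mu = -cc / 2 + sqrt(disc), sub_exponential = FALSE, spiraling = FALSE)
  }
}

#' Unstable eigen-direction at a left-limit fixed point
#'
#' Direction of the one-dimensional unstable manifold of \eqn{(0,0,i_{-\infty})}
#' for \eqn{i_{-\infty} > 1}, in the printed component form
#' \deqn{e_+ = \left(-\lambda_-,\; i_{-\infty}-1,\;
#'   \tfrac{1}{c}(r + i_{-\infty})\,\lambda_-/\lambda_+\right),}
#' whose first two components are positive and whose third is negative:
#' leaving the fixed point, the active density grows while inactive density
#' falls. Not unit-normalized; set `unit = TRUE` for the normalized copy.
#'
#' @inheritParams wave_vector_field
#' @param i_minus_inf Left-limit inactive density, must be > 1.
#' @param unit If `TRUE`, return the vector scaled to Euclidean length 1
#'   (orientation kept: positive a-component).
#' @return Numeric 3-vector `(a, b, i)`.
#' @examples
#' unstable_direction(model_params(2, 0), 2)
#' @export
unstable_direction <- function(params, i_minus_inf, unit = FALSE) {
  params <- as_model_params(params)
  stopifnot(is.numeric(i_minus_inf), length(i_minus_inf) == 1L,
            is.finite(i_minus_inf))
  if (i_minus_inf <= 1)
    stop("no unstable manifold: `i_minus_inf` must exceed 1", call. = FALSE)
  es <- fixed_point_eigensystem(params, i_minus_inf)
  lp <- es$lambda_plus; lm <- es$lambda_minus
  v <- c(a = -lm,
         b = i_minus_inf - 1,
         i = (params$r + i_minus_inf) / params$c * lm / lp)
  if (unit) v <- v / sqrt(sum(v^2))
  v
}

#' Closed-form right limit of an orbit started on the b = 0 plane
#'
#' For a trajectory launched at \eqn{(a_0, 0, i_0)} that stays non-negative
#' and converges, the limiting inactive density is
#' \deqn{i_{+\infty}(a_0, i_0) = 1 - \sqrt{(i_0 + a_0 - 1)^2 +
#'   \tfrac{1+r}{c^2}(a_0^2 + 2 c^2 a_0)}.}
#' It is decreasing in \eqn{a_0} on \eqn{[0, 1 - i_0]} and satisfies
#' `limit_map(0, i0) = i0`.
#'
#' @param a0,i0 Initial active and inactive densities (vectorized).
#' @inheritParams wave_vector_field
#' @return Numeric vector of limiting inactive densities.
#' @examples
#' limit_map(0.1, 0.5, model_params(2, 0))
#' @export
limit_map <- function(a0, i0, params) {
  params <- as_model_params(params)
  stopifnot(is.numeric(a0), is.numeric(i0), all(is.finite(a0)),
            all(is.finite(i0)))
  if (any(a0 < 0)) stop("`a0` must be non-negative", call. = FALSE)
  cc <- params$c; r <- params$r
  1 - sqrt((i0 + a0 - 1)^2 + (1 + r) / cc^2 * (a0^2 + 2 * cc^2 * a0))
}

#' Initial active density reaching the critical right limit
#'
#' The unique \eqn{a_0 = \alpha(i_0)} for which `limit_map(a0, i0)` equals the
#' critical density \eqn{i_c}:
#' \deqn{\alpha(i_0) = \frac{c^2}{1 + c^2 + r}\Big\{-(i_0 + r) +
#'   \sqrt{(i_0 + r)^2 + \tfrac{c^2 + 1 + r}{c^2}
#'   \big((1 - i_c)^2 - (1 - i_0)^2\big)}\Big\}.}
#'
#' @inheritParams limit_map
#' @return Numeric vector, with `alpha_threshold(i_c) = 0`.
#' @examples
#' alpha_threshold(0.5, model_params(2, 0))
#' @export
alpha_threshold <- function(i0, params) {
  params <- as_model_params(params)
  stopifnot(is.numeric(i0), all(is.finite(i0)))
  cc <- params$c; r <- params$r
  ic <- critical_density(cc)
  if (any(i0 < ic - 1e-12) || any(i0 >= 1))
    stop("`i0` must lie in [i_c, 1)", call. = FALSE)
  i0 <- pmax(i0, ic)
  cc^2 / (1 + cc^2 + r) *
    (-(i0 + r) + sqrt((i0 + r)^2 +
       (cc^2 + 1 + r) / cc^2 * ((1 - ic)^2 - (1 - i0)^2)))
}

#' Upper bound for the initial active density in the attractor
#'
#' \eqn{a^*(i_0) = \min\{\alpha(i_0), 1 - i_0\}}: orbits from
#' \eqn{(a_0, 0, i_0)} with \eqn{a_0 \le a^*(i_0)} stay non-negative and
#' converge to \eqn{(0, 0, i_{+\infty}(a_0, i_0))}.
#'
#' @inheritParams limit_map
#' @return Numeric vector in `[0, 1 - i0]`.
#' @examples
#' a_star(0.5, model_params(2, 0))
#' @export
a_star <- function(i0, params) {
  pmin(alpha_threshold(i0, params), 1 - i0)
}

#' Active density at the turning point of a shooting orbit
#'
#' At the first phase-time \eqn{z_0} with \eqn{b(z_0) = 0}, the active
#' density of the heteroclinic orbit from \eqn{(0,0,i_{-\infty})} satisfies
#' \deqn{a_{z_0} = \frac{c^2}{c^2 + 1 + r}\Big\{-(i_{z_0} + r) +
#'   \sqrt{(i_{z_0} + r)^2 + \tfrac{c^2 + 1 + r}{c^2}
#'   \big((i_{-\infty} - 1)^2 - (1 - i_{z_0})^2\big)}\Big\},}
#' which is positive exactly when \eqn{(i_{-\infty}-1)^2 > (1 - i_{z_0})^2}.
#'
#' @param i_z0 Inactive density at the turning point.
#' @param i_minus_inf Left-limit inactive density.
#' @inheritParams wave_vector_field
#' @return List with `a_z0` and flag `admissible` (`FALSE` with `a_z0 = NA`
#'   when the radicand structure puts the turning point out of reach,
#'   `(i_minus_inf - 1)^2 < (1 - i_z0)^2`).
#' @examples
#' turning_point_active(0.6, 1.8, model_params(2, 0))
#' @export
turning_point_active <- function(i_z0, i_minus_inf, params) {
  params <- as_model_params(params)
  stopifnot(is.numeric(i_z0), length(i_z0) == 1L, is.finite(i_z0),
            is.numeric(i_minus_inf), length(i_minus_inf) == 1L,
            is.finite(i_minus_inf))
  cc <- params$c; r <- params$r
  gap <- (i_minus_inf - 1)^2 - (1 - i_z0)^2
  if (gap < -1e-14)
    return(list(a_z0 = NA_real_, admissible = FALSE))
  gap <- max(gap, 0)
  a <- cc^2 / (cc^2 + 1 + r) *
    (-(i_z0 + r) + sqrt((i_z0 + r)^2 + (cc^2 + 1 + r) / cc^2 * gap))
  list(a_z0 = a, admissible = TRUE)
}
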