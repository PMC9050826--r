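#' Reduced planar vector field at frozen inactive density
#'
#' The \eqn{(\bar a, \bar b)} subsystem obtained from the wave system by
#' freezing \eqn{i(z) = i}:
#' \deqn{\bar a' = \bar b, \qquad \bar b' = \bar a(\bar a + i - 1) - c \bar b.}
#' Its only fixed points are \eqn{(0,0)} and \eqn{(1-i, 0)}. Because neither
#' \eqn{b} nor \eqn{b'} of the full system depends on \eqn{i'}, the reduced
#' field equals the first two components of [wave_vector_field()] evaluated
#' at \eqn{(\bar a, \bar b, i)}.
#'
#' @param c Wave speed, > 0.
#' @param i Frozen inactive density.
#' @param p Numeric pair \eqn{(\bar a, \bar b)}.
#' @return Numeric pair \eqn{(\bar a', \bar b')}.
#' @examples
#' reduced_vector_field(2, 0.5, c(0.25, 0))
#' @export
reduced_vector_field <- function(c, i, p) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c), c > 0,
            is.numeric(i), length(i) == 1L, is.finite(i))
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
    stop("`p` must be a finite numeric pair", call. = FALSE)
  a <- p[1]; b <- p[2]
  c(b, a * (a + i - 1) - c * b)
}

#' Eigen-data of the reduced subsystem at its two fixed points
#'
#' At the origin the eigenvalues are
#' \eqn{\lambda_\pm(i) = -c/2 \pm \sqrt{c^2/4 + i - 1}} with eigenvectors
#' \eqn{l_\pm(i) = (\lambda_\mp, 1-i)}; these coincide with the nonzero
#' eigenvalues of the full linearization at \eqn{(0,0,i)}. At
#' \eqn{(1-i, 0)} the eigenvalues are
#' \eqn{\beta_\pm(i) = -c/2 \pm \sqrt{c^2/4 + 1 - i}} (a saddle:
#' \eqn{\beta_- < 0 < \beta_+} for \eqn{i < 1}) with eigenvectors
#' \eqn{r_\pm(i) = (-\beta_\mp, 1-i)}.
#'
#' @inheritParams reduced_vector_field
#' @return A list of class `reduced_eigen` with `lambda_plus`, `lambda_minus`,
#'   `l_plus`, `l_minus`, `beta_plus`, `beta_minus`, `r_plus`, `r_minus`,
#'   `degenerate` (`TRUE` when \eqn{\lambda_+ = \lambda_-}, i.e. `i` at the
#'   critical density with algebraic multiplicity 2, geometric multiplicity 1),
#'   and `is_complex` (`TRUE` below the critical density, the spiraling case).
#' @examples
#' reduced_eigensystem(2, 0.5)
#' reduced_eigensystem(2, 0)$degenerate
#' @export
reduced_eigensystem <- function(c, i) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c), c > 0,
            is.numeric(i), length(i) == 1L, is.finite(i))
  disc0 <- c^2 / 4 + i - 1       # at the origin
  disc1 <- c^2 / 4 + 1 - i       # at (1 - i, 0)
  tol <- 1e-12 * max(1, c^2)
  bp <- -c / 2 + sqrt(disc1)
  bm <- -c / 2 - sqrt(disc1)
  out <- list(beta_plus = bp, beta_minus = bm,
              r_plus = c(-bm, 1 - i), r_minus = c(-bp, 1 - i))
  if (disc0 < -tol) {
    out$lambda_plus <- complex(real = -c / 2, imaginary = sqrt(-disc0))
    out$lambda_minus <- Conj(out$lambda_plus)
    out$l_plus <- out$l_minus <- c(NA_real_, NA_real_)
    out$is_complex <- TRUE; out$degenerate <- FALSE
  } else if (disc0 <= tol) {
    lam <- -c / 2
    out$lambda_plus <- out$lambda_minus <- lam
    # single eigen-direction (lambda_mp = lambda itself here)
    out$l_plus <- out$l_minus <- c(lam, 1 - i)
    out$is_complex <- FALSE; out$degenerate <- TRUE
  } else {
    sq <- sqrt(disc0)
    out$lambda_plus <- -c / 2 + sq
    out$lambda_minus <- -c / 2 - sq
    out$l_plus <- c(out$lambda_minus, 1 - i)
    out$l_minus <- c(out$lambda_plus, 1 - i)
    out$is_complex <- FALSE; out$degenerate <- FALSE
  }
  structure(out[c("lambda_plus", "lambda_minus", "l_plus", "l_minus",
                  "beta_plus", "beta_minus", "r_plus", "r_minus",
                  "is_complex", "degenerate")],
            class = "reduced_eigen")
}

#' Build the trapping triangle of the reduced subsystem
#'
#' The invariant region \eqn{T_c(i)} is the convex hull of the two fixed
#' points \eqn{(0,0)} and \eqn{(1-i, 0)} together with the apex \eqn{C(i)},
#' the intersection of the half-lines \eqn{\{-p\, l_+(i) : p \ge 0\}} and
#' \eqn{\{(1-i, 0) - q\, r_+(i) : q \ge 0\}}. The apex lies strictly below
#' the \eqn{\bar a}-axis; trajectories entering the triangle stay inside it
#' with \eqn{\bar a \ge 0} and \eqn{\bar b \le 0}.
#'
#' @inheritParams reduced_vector_field
#' @return A list of class `wave_triangle`: `vertices` (tibble with columns
#'   `vertex` in `p0`/`p1`/`apex`, `a`, `b`, counterclockwise order
#'   `p0, apex, p1`), internal angles `gamma_l` and `gamma_r` (radians) at
#'   `p0` and `p1`, half-line parameters `p`, `q`, flags, and `c`, `i`.
#'   For `i` at the critical density with a repeated eigenvalue the triangle
#'   is flagged `degenerate` (half-line directions from the single
#'   eigenvector).
#' @examples
#' build_triangle(2, 0.5)
#' @export
build_triangle <- function(c, i) {
  ic <- critical_density(c)
  if (i < ic - 1e-12 || i >= 1)
    stop("`i` must lie in [i_c, 1) for the trapping triangle", call. = FALSE)
  red <- reduced_eigensystem(c, max(i, ic))
  lp <- as.numeric(red$l_plus)   # direction of the left edge (negated)
  rp <- as.numeric(red$r_plus)
  # apex solves -p * l_plus = (1-i, 0) - q * r_plus  for p, q >= 0
  M <- cbind(-lp, rp)
  rhs <- c(1 - i, 0)
  sol <- solve(M, rhs)
  p <- sol[1]; q <- sol[2]
  apex <- -p * lp
  verts <- tibble::tibble(
    vertex = c("p0", "apex", "p1"),                  # counterclockwise
    a = c(0, apex[1], 1 - i),
    b = c(0, apex[2], 0))
  angle_at <- function(v, w1, w2) {
    u1 <- w1 - v; u2 <- w2 - v
    acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)))
  }
  gamma_l <- angle_at(c(0, 0), apex, c(1 - i, 0))
  gamma_r <- angle_at(c(1 - i, 0), apex, c(0, 0))
  structure(list(vertices = verts, gamma_l = gamma_l, gamma_r = gamma_r,
                 p = p, q = q, degenerate = red$degenerate, c = c, i = i),
            class = "wave_triangle")
}

#' @export
print.wave_triangle <- function(x, ...) {
  cat(sprintf("<wave_triangle>  c = %g, i = %g%s\n", x$c, x$i,
              if (x$degenerate) "  (degenerate)" else ""))
  cat(sprintf("  apex = (%.6g, %.6g); gamma_l = %.4f, gamma_r = %.4f rad\n",
              x$vertices$a[2], x$vertices$b[2], x$gamma_l, x$gamma_r))
  invisible(x)
}

#' Point-in-triangle test
#'
#' Closed convex-hull membership for the trapping triangle, via barycentric
#' sign tests with a small absolute slack for boundary points.
#'
#' @param triangle A [build_triangle()] object.
#' @param p Numeric pair, or a 2-column matrix of points (rows).
#' @param tol Absolute slack applied to the edge tests.
#' @return Logical vector, one entry per point.
#' @examples
#' tr <- build_triangle(2, 0.5)
#' triangle_contains(tr, c(0.1, -0.01))
#' @export
triangle_contains <- function(triangle, p, tol = 1e-12) {
  stopifnot(inherits(triangle, "wave_triangle"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  v <- cbind(triangle$vertices$a, triangle$vertices$b)  # ccw: p0, apex, p1
  inside <- rep(TRUE, nrow(p))
  for (k in 1:3) {
    e1 <- v[k, ]; e2 <- v[k %% 3 + 1, ]
    # ccw orientation: interior has non-negative cross product with each edge
    cr <- (e2[1] - e1[1]) * (p[, 2] - e1[2]) - (e2[2] - e1[2]) * (p[, 1] - e1[1])
    inside <- inside & (cr >= -tol)
  }
  inside
}

#' Numerical certificate of triangle invariance
#'
#' Samples the three edges of \eqn{T_c(i)} (excluding a small neighborhood of
#' the two fixed-point vertices, where the flux legitimately vanishes) and
#' evaluates the inner product of the reduced vector field with the inward
#' normal. A non-negative minimum certifies that the flow does not leave the
#' triangle; on the two eigenvector edges the inner product is strictly
#' positive away from the vertices.
#'
#' @inheritParams reduced_vector_field
#' @param n_samples Sample points per edge.
#' @param exclude Fraction of each edge length excluded at fixed-point
#'   vertices.
#' @return A list with `status` (`"ok"` or `"degenerate"`), `min_flux`,
#'   `min_flux_by_edge` (named: `left`, `right`, `axis`), and `pass`
#'   (`min_flux >= -1e-12`).
#' @examples
#' invariance_scan(2, 0.3, n_samples = 50)$pass
#' @export
invariance_scan <- function(c, i, n_samples = 200, exclude = 1e-6) {
  tr <- build_triangle(c, i)
  if (tr$degenerate)
    return(list(status = "degenerate", min_flux = NA_real_,
                min_flux_by_edge = NULL, pass = NA))
  v <- cbind(tr$vertices$a, tr$vertices$b)  # p0, apex, p1 (ccw)
  p0 <- v[1, ]; apex <- v[2, ]; p1 <- v[3, ]
  inward_normal <- function(e1, e2) {
    t <- e2 - e1
    n <- c(-t[2], t[1])          # left normal of ccw edge points inward
    n / sqrt(sum(n^2))
  }
  edge_min <- function(e1, e2, cut1, cut2) {
    n <- inward_normal(e1, e2)
    s <- seq(cut1, 1 - cut2, length.out = n_samples)
    flux <- vapply(s, function(t) {
      pt <- e1 + t * (e2 - e1)
      sum(reduced_vector_field(c, i, pt) * n)
    }, numeric(1))
    min(flux)
  }
  ex <- exclude
  mins <- c(
    left  = edge_min(p0, apex, ex, 0),    # p0 is a fixed point
    right = edge_min(apex, p1, 0, ex),    # p1 is a fixed point
    axis  = edge_min(p1, p0, ex, ex))     # both endpoints are fixed points
  list(status = "ok", min_flux = min(mins), min_flux_by_edge = mins,
       pass = min(mins) >= -1e-12)
}

#' Nestedness of trapping triangles
#'
#' The triangles grow as the frozen density decreases: for
#' \eqn{i_c \le i_1 < i_2 < 1}, \eqn{T_c(i_2) \subseteq T_c(i_1)}. Checked
#' vertexwise with [triangle_contains()].
#'
#' @inheritParams reduced_vector_field
#' @param i1,i2 Frozen densities with `i1 <= i2`.
#' @return `TRUE` iff all vertices of the inner triangle lie in the outer one.
#' @examples
#' nestedness_scan(2, 0.1, 0.5)
#' @export
nestedness_scan <- function(c, i1, i2) {
  if (i1 > i2) stop("need i1 <= i2", call. = FALSE)
  outer <- build_triangle(c, i1)
  inner <- build_triangle(c, i2)
  all(triangle_contains(outer, cbind(inner$vertices$a, inner$vertices$b),
                        tol = 1e-9))
}
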