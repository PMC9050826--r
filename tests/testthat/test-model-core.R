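test_that("vector field matches hand-computed values and fixed-point structure", {
  p <- model_params(2, 0)
  # direct substitution: a' = b, b' = a(a+i) - a - cb, i' = -(1/c) a(a+i+r)
  expect_equal(wave_vector_field(p, c(0.1, 0, 0.5)), c(0, -0.04, -0.03),
               tolerance = 1e-14)
  # continuum of fixed points (0, 0, K)
  for (K in c(0, 0.5, 1, 1.7, 3))
    expect_equal(wave_vector_field(p, c(0, 0, K)), c(0, 0, 0))
  # (1 - i, 0, i) kills b' but not i': the reduced fixed point is not a
  # fixed point of the full system
  for (i in c(0.2, 0.5, 0.8)) {
    f <- wave_vector_field(p, c(1 - i, 0, i))
    expect_equal(f[2], 0, tolerance = 1e-14)
    expect_equal(f[3], -(1 / p$c) * (1 - i) * (1 + p$r), tolerance = 1e-14)
    expect_true(abs(f[3]) > 0)
  }
  expect_error(wave_vector_field(p, c(NA, 0, 0)), "finite")
  expect_error(model_params(-1, 0), "positive")
  expect_error(model_params(2, -0.5), "non-negative")
})

test_that("jacobian agrees with finite differences of the vector field", {
  set.seed(11)
  p <- model_params(1.7, 0.4)
  h <- 1e-5
  worst <- 0
  for (k in 1:100) {
    s <- runif(3, -1, 2)
    J <- wave_jacobian(p, s)
    Jfd <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- numeric(3); e[j] <- h
      Jfd[, j] <- (wave_vector_field(p, s + e) - wave_vector_field(p, s - e)) / (2 * h)
    }
    worst <- max(worst, max(abs(J - Jfd)))
  }
  expect_lt(worst, 1e-6)
})

test_that("jacobian at a fixed point has the degenerate structure", {
  p <- model_params(2, 0.5)
  K <- 1.3
  J <- wave_jacobian(p, c(0, 0, K))
  expect_equal(unname(J),
               matrix(c(0, 1, 0,
                        K - 1, -2, 0,
                        -(K + 0.5) / 2, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(sum(diag(J)), -p$c)
  expect_equal(unname(J[, 3]), c(0, 0, 0))  # zero eigenvalue direction
})

test_that("fixed-point eigensystem solves the characteristic quadratic", {
  for (cc in c(1, 1.5, 2, 3)) {
    p <- model_params(cc, 0)
    for (K in c(0, 0.3, 1, 1.5, 2, 2.5)) {
      es <- fixed_point_eigensystem(p, K)
      expect_identical(es$lambda0, 0)
      if (!es$is_complex) {
        for (lam in c(es$lambda_plus, es$lambda_minus))
          expect_lt(abs(lam^2 + cc * lam - (K - 1)), 1e-12)
        expect_lte(es$lambda_minus, es$lambda_plus)
      }
    }
  }
})

test_that("eigen-residuals vanish for returned eigenpairs", {
  for (cc in c(1.3, 2, 2.6)) {
    p <- model_params(cc, 0.7)
    for (K in c(0.2, 0.9, 1.4, 2)) {
      es <- fixed_point_eigensystem(p, K)
      if (es$is_complex) next
      J <- wave_jacobian(p, c(0, 0, K))
      lams <- c(0, es$lambda_plus, if (!es$degenerate) es$lambda_minus)
      for (j in seq_along(lams)) {
        v <- es$vectors[, j]
        expect_lt(sqrt(sum((J %*% v - lams[j] * v)^2)),
                  1e-10 * sqrt(sum(v^2)))
      }
    }
  }
})

test_that("degenerate and complex eigen cases are flagged, not fabricated", {
  p <- model_params(2, 0)
  # repeated root at K = 0, c = 2: single eigen-direction only
  es <- fixed_point_eigensystem(p, 0)
  expect_true(es$degenerate)
  expect_equal(es$lambda_plus, -1)
  expect_equal(es$lambda_minus, -1)
  expect_equal(ncol(es$vectors), 2L)  # e0 plus the one repeated direction
  # K = 1: lambda_plus = 0, lambda_minus = -c
  es1 <- fixed_point_eigensystem(p, 1)
  expect_equal(es1$lambda_plus, 0)
  expect_equal(es1$lambda_minus, -2)
  # complex case representable, not an error
  esc <- fixed_point_eigensystem(model_params(1, 0), 0.2)
  expect_true(esc$is_complex)
  expect_equal(Re(esc$lambda_plus), -0.5)
  # c = 2, K = 2: roots of lambda^2 + 2 lambda - 1
  es2 <- fixed_point_eigensystem(p, 2)
  expect_equal(es2$lambda_plus, -1 + sqrt(2), tolerance = 1e-12)
  expect_equal(es2$lambda_minus, -1 - sqrt(2), tolerance = 1e-12)
})

test_that("critical density formula and minimal invasion speed", {
  expect_equal(critical_density(2), 0)
  expect_equal(critical_density(3), 0)
  expect_equal(critical_density(1), 0.75)
  expect_error(critical_density(-1), "positive")
  expect_equal(minimal_invasion_speed(), 2, tolerance = 1e-10)
})

test_that("decay rates match the limiting eigenvalues and flag edge cases", {
  p <- model_params(2, 0)
  d0 <- decay_rate(p, 0)
  expect_equal(d0$mu, -1)
  expect_true(d0$sub_exponential)
  expect_equal(decay_rate(p, 0.2)$mu, -1 + sqrt(0.2), tolerance = 1e-12)
  expect_equal(decay_rate(p, 1.8)$mu, -1 + sqrt(1.8), tolerance = 1e-12)
  expect_true(decay_rate(model_params(1, 0), 0.2)$spiraling)
  # equality with lambda_plus whenever the discriminant is non-negative
  for (cc in c(1.4, 2, 2.5)) {
    pp <- model_params(cc, 0.3)
    for (K in c(0.7, 1, 1.6, 2.2)) {
      dr <- decay_rate(pp, K)
      if (!dr$spiraling)
        expect_equal(dr$mu, fixed_point_eigensystem(pp, K)$lambda_plus,
                     tolerance = 1e-12)
    }
  }
})

test_that("unstable direction has the printed form and sign structure", {
  p <- model_params(2, 0)
  e <- unstable_direction(p, 2)
  expect_equal(unname(e), c(1 + sqrt(2), 1, (-1 - sqrt(2)) / (-1 + sqrt(2))),
               tolerance = 1e-12)
  # eigen-residual against the jacobian
  for (i_m in c(1.2, 1.6, 2)) {
    for (r in c(0, 1)) {
      pp <- model_params(2, r)
      v <- unstable_direction(pp, i_m)
      es <- fixed_point_eigensystem(pp, i_m)
      J <- wave_jacobian(pp, c(0, 0, i_m))
      expect_lt(sqrt(sum((J %*% v - es$lambda_plus * v)^2)),
                1e-10 * sqrt(sum(v^2)))
      expect_gt(v[1], 0); expect_gt(v[2], 0); expect_lt(v[3], 0)
    }
  }
  expect_error(unstable_direction(p, 0.9), "unstable")
  u <- unstable_direction(p, 1.8, unit = TRUE)
  expect_equal(sum(u^2), 1)
})

test_that("limit map: fixed values, monotonicity, and range", {
  p <- model_params(2, 0)
  expect_equal(limit_map(0.1, 0.5, p), 1 - sqrt(0.16 + 0.2025),
               tolerance = 1e-14)
  # limit_map(0, i0) = i0
  for (i0 in c(0.1, 0.5, 0.9)) expect_equal(limit_map(0, i0, p), i0)
  # decreasing in a0 on [0, 1 - i0]; value stays in [i_c, i0] up to a_star
  for (cc in c(1.5, 2, 3)) {
    for (r in c(0, 1)) {
      pp <- model_params(cc, r)
      ic <- critical_density(cc)
      for (i0 in seq(max(ic, 0.05) + 0.02, 0.95, length.out = 4)) {
        a_grid <- seq(0, 1 - i0, length.out = 25)
        v <- limit_map(a_grid, i0, pp)
        expect_true(all(diff(v) < 0))
        amax <- a_star(i0, pp)
        inside <- a_grid <= amax + 1e-12
        expect_true(all(v[inside] >= ic - 1e-10))
        expect_true(all(v[inside] <= i0 + 1e-10))
      }
    }
  }
})

test_that("alpha threshold is the root of the limit map at i_c", {
  p <- model_params(2, 0)
  expect_equal(alpha_threshold(0.5, p), 0.8 * (-0.5 + sqrt(1.1875)),
               tolerance = 1e-12)
  # alpha(i_c) = 0 (taking a speed with i_c > 0)
  p1 <- model_params(1, 0)
  expect_equal(alpha_threshold(critical_density(1), p1), 0, tolerance = 1e-12)
  # round trip: limit_map(alpha(i0), i0) = i_c
  for (cc in c(1.2, 1.8, 2, 2.7)) {
    for (r in c(0, 0.5, 2)) {
      pp <- model_params(cc, r)
      ic <- critical_density(cc)
      for (i0 in seq(max(ic, 0.02) + 0.01, 0.97, length.out = 5)) {
        expect_lt(abs(limit_map(alpha_threshold(i0, pp), i0, pp) - ic), 1e-10)
      }
    }
  }
  expect_error(alpha_threshold(1.0, p), "i_c")
})

test_that("a_star is the minimum of its two branches and bounded", {
  p <- model_params(2, 0)
  expect_equal(a_star(0.5, p), min(alpha_threshold(0.5, p), 0.5))
  expect_equal(a_star(0.5, p), 0.4717798, tolerance = 1e-6)
  p1 <- model_params(1, 0)
  expect_equal(a_star(critical_density(1), p1), 0, tolerance = 1e-12)
  for (i0 in seq(0.05, 0.95, by = 0.1))
    expect_lte(a_star(i0, p), 1 - i0)
})

test_that("turning-point formula: zero case and admissibility flag", {
  p <- model_params(2, 0)
  # vanishing second term under the root: a = 0 exactly
  expect_equal(turning_point_active(0.4, 1.6, p)$a_z0, 0, tolerance = 1e-12)
  # equals alpha_threshold when i_minus_inf = 2 - i_c
  ic <- critical_density(2)
  tp <- turning_point_active(0.5, 2 - ic, p)
  expect_equal(tp$a_z0, alpha_threshold(0.5, p), tolerance = 1e-12)
  # inadmissible radicand structure flagged
  expect_false(turning_point_active(0.9, 1.05, p)$admissible)
})
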