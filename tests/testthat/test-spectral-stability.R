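# a constant profile (a = 0, i = K) makes the operator block-triangular with
# constant coefficients, so a periodic discretization must reproduce the
# discrete Fourier symbols of the two blocks exactly
test_that("periodic constant-coefficient spectrum matches the Fourier symbol", {
  K <- 0.2; n <- 64; L <- 20
  op <- assemble_weighted_operator(NULL, params2, alpha = 0,
                                   z_min = 0, z_max = L, n = n,
                                   profile = list(a = 0, i = K),
                                   periodic = TRUE)
  ev <- eigen(as.matrix(op$matrix), only.values = TRUE)$values
  h <- op$h
  k <- 2 * pi * (0:(n - 1)) / (n * h)
  symA <- -(2 - 2 * cos(k * h)) / h^2 + 1i * params2$c * sin(k * h) / h +
    (1 - K)
  symI <- params2$c * (exp(1i * k * h) - 1) / h
  expected <- c(symA, symI)
  # match as multisets via nearest-neighbour distances (conjugate pairs make
  # a lexicographic sort order unstable under round-off)
  dmat <- abs(outer(ev, expected, "-"))
  expect_lt(max(apply(dmat, 1, min)), 1e-8)
  expect_lt(max(apply(dmat, 2, min)), 1e-8)
})

test_that("operator structure: no diffusion stencil in the inactive block", {
  w <- cached_wave(2, 0, 1.8)
  op <- assemble_weighted_operator(w, params2, alpha = 0.5,
                                   z_min = w$z0 - 20, z_max = w$z0 + 20,
                                   n = 60)
  M <- as.matrix(op$matrix)
  n <- op$n
  II <- M[(n + 1):(2 * n), (n + 1):(2 * n)]
  # bidiagonal transport: nothing below the diagonal, no curvature stencil
  expect_true(all(abs(II[lower.tri(II)]) == 0))
  expect_identical(dim(M), as.integer(c(2 * n, 2 * n)))
  # reaction Jacobian on the diagonal of the coupling blocks
  expect_equal(diag(M[1:n, (n + 1):(2 * n)]), -op$profile_a)
  expect_equal(diag(M[(n + 1):(2 * n), 1:n]),
               2 * op$profile_a + op$profile_i + params2$r)
  expect_error(assemble_weighted_operator(w, params2, alpha = 100,
                                          z_min = 0, z_max = 40, n = 50),
               "alpha")
})

test_that("weight similarity is consistent with explicit weighting", {
  # on a short domain the explicitly weighted matrix W L W^-1 must act like
  # the alpha-transformed assembly on decayed test vectors
  w <- cached_wave(2, 0, 1.8)
  alpha <- 0.4
  zc <- w$z0
  op0 <- assemble_weighted_operator(w, params2, alpha = 0,
                                    z_min = zc - 8, z_max = zc + 8, n = 160)
  opA <- assemble_weighted_operator(w, params2, alpha = alpha,
                                    z_min = zc - 8, z_max = zc + 8, n = 160)
  Wv <- exp(alpha * (op0$z - zc))
  set.seed(42)
  M0 <- as.matrix(op0$matrix); MA <- as.matrix(opA$matrix)
  for (k in 1:20) {
    v <- rnorm(2 * length(op0$z))
    lhs <- MA %*% (c(Wv, Wv) * v)
    rhs <- c(Wv, Wv) * (M0 %*% v)
    # agreement up to the O(h^2) stencil commutation error
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 2e-2)
  }
})

test_that("spectrum of a diagonal test operator is its diagonal", {
  op <- structure(list(matrix = Matrix::Diagonal(10, x = -(1:10)),
                       z = 1:5, alpha = 0, params = params2,
                       profile_a = numeric(5), profile_i = numeric(5),
                       h = 1, n = 5, periodic = FALSE),
                  class = "operator_discretization")
  sp <- compute_spectrum(op)
  expect_equal(sort(Re(sp$eigenvalues)), sort(-(10:1)))
})

test_that("critical wave in the c/2-weighted space is spectrally stable", {
  w <- cached_wave(2, 0, 2)
  op <- assemble_weighted_operator(w, params2, alpha = 1,
                                   z_min = w$z0 - 60, z_max = w$z0 + 60,
                                   n = 800)
  sp <- compute_spectrum(op)
  # translational eigenvalue near zero
  expect_lt(abs(sp$translational_eigenvalue), 0.02)
  rep <- stability_report(sp, tol = 0.05)
  expect_true(rep$pass)
  expect_lte(rep$max_real_excl_translation, 0.05)
  expect_identical(nrow(rep$rightmost), 10L)
  # verdict machinery on synthetic spectra
  fake <- structure(list(eigenvalues = rep(-1 + 0i, 4), translational_index = 1L,
                         translational_eigenvalue = -1 + 0i,
                         max_real_excl_translation = -1, alpha = 0, n = 2),
                    class = "spectrum_result")
  expect_true(stability_report(fake)$pass)
  fake$max_real_excl_translation <- 1
  expect_false(stability_report(fake)$pass)
})

test_that("without the weight the spectrum reaches the closed right half-plane", {
  w <- cached_wave(2, 0, 2)
  op <- assemble_weighted_operator(w, params2, alpha = 0,
                                   z_min = w$z0 - 60, z_max = w$z0 + 60,
                                   n = 400)
  sp <- compute_spectrum(op)
  expect_gte(max(Re(sp$eigenvalues)), 0)
  # the mode most aligned with the profile derivative sits near the origin
  # relative to the spectral radius of the discretization
  expect_lt(abs(sp$translational_eigenvalue), 0.2)
})

test_that("rightmost eigenvalues self-converge under grid refinement", {
  w <- cached_wave(2, 0, 2)
  span <- c(w$z0 - 50, w$z0 + 50)
  right5 <- function(n) {
    op <- assemble_weighted_operator(w, params2, alpha = 1,
                                     z_min = span[1], z_max = span[2], n = n)
    ev <- compute_spectrum(op)$eigenvalues
    ev <- ev[Im(ev) >= -1e-10]          # one of each conjugate pair
    head(ev[order(Re(ev), decreasing = TRUE)], 5)
  }
  e1 <- right5(150); e2 <- right5(300); e4 <- right5(600)
  err1 <- max(abs(e1 - e4)); err2 <- max(abs(e2 - e4))
  expect_lt(err2, 0.6 * err1)   # ~second-order: doubling n halves the error
})

test_that("stability verdict is robust to the truncation span", {
  # the weighted essential spectrum touches 0 at its edge; the rightmost
  # discretized modes are edge modes of that continuum and approach 0 from
  # the left at the Dirichlet rate O(1/L^2) as the span grows, so the
  # quantity that must be truncation-robust is the verdict, not the exact
  # edge-mode positions
  w <- cached_wave(2, 0, 2)
  top <- function(half) {
    n <- round(half * 10)  # keep h fixed while the domain grows
    op <- assemble_weighted_operator(w, params2, alpha = 1,
                                     z_min = w$z0 - half, z_max = w$z0 + half,
                                     n = n)
    compute_spectrum(op)$max_real_excl_translation
  }
  t1 <- top(40); t2 <- top(60); t3 <- top(90)
  expect_true(all(c(t1, t2, t3) <= 0.05))          # verdict stable
  expect_true(all(diff(c(t1, t2, t3)) > 0))        # approach from the left
  # O(1/L^2) truncation scaling: successive movements shrink accordingly
  expect_lt(abs(t3 - t2), abs(t2 - t1))
  expect_lt(abs(t3 - t2), 2.5e-2)
})

test_that("spectrum tidiers expose eigenvalues and the translation marker", {
  w <- cached_wave(2, 0, 2)
  op <- assemble_weighted_operator(w, params2, alpha = 1,
                                   z_min = w$z0 - 40, z_max = w$z0 + 40,
                                   n = 120)
  sp <- compute_spectrum(op)
  td <- tidy(sp)
  expect_identical(nrow(td), 240L)
  expect_identical(sum(td$translational), 1L)
  expect_identical(nrow(glance(sp)), 1L)
  expect_s3_class(autoplot(sp), "ggplot")
})
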