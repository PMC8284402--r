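test_that("Fresnel propagator: identity, round trip, unitarity, composition", {
  set.seed(1)
  n <- 64
  u <- wavefield(matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)),
                        n), PIX)
  u0 <- fresnel_propagate(u, WL, 0)
  expect_lt(max(Mod(u0$values - u$values)), 1e-12)

  ufwd <- fresnel_propagate(u, WL, 0.2)
  uback <- fresnel_propagate(ufwd, WL, -0.2)
  expect_lt(max(Mod(uback$values - u$values)), 1e-10)

  # unitarity: mean intensity (Parseval) conserved
  expect_lt(abs(mean(intensity(ufwd)) - mean(intensity(u))), 1e-12)

  # composition
  u12 <- fresnel_propagate(fresnel_propagate(u, WL, 0.07), WL, 0.13)
  u3 <- fresnel_propagate(u, WL, 0.2)
  expect_lt(max(Mod(u12$values - u3$values)), 1e-10)

  # linearity
  set.seed(2)
  v <- wavefield(matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)),
                        n), PIX)
  lhs <- fresnel_propagate(wavefield(2 * u$values - 3i * v$values, PIX),
                           WL, 0.1)$values
  rhs <- 2 * fresnel_propagate(u, WL, 0.1)$values -
    3i * fresnel_propagate(v, WL, 0.1)$values
  expect_lt(max(Mod(lhs - rhs)), 1e-10)
})

test_that("Fresnel propagator reproduces the analytic Gaussian solution", {
  n <- 256; w <- 16 * PIX; d <- 0.05
  cy <- (n + 1) / 2
  x <- (matrix(seq_len(n), n, n, byrow = TRUE) - cy) * PIX
  y <- (matrix(seq_len(n), n, n) - cy) * PIX
  u0 <- exp(-(x^2 + y^2) / w^2)
  # closed form: u(r, D) = (w^2 / a) exp(-r^2 / a), a = w^2 + i*lambda*D/pi
  a <- w^2 + 1i * WL * d / pi
  ua <- (w^2 / a) * exp(-(x^2 + y^2) / a)
  un <- fresnel_propagate(wavefield(u0, PIX), WL, d)$values
  expect_lt(max(Mod(un - ua)) / max(Mod(ua)), 1e-6)
})

test_that("padded propagation suppresses wrap-around for non-periodic fields", {
  # a pure phase tilt is a tilted plane wave: |u|^2 stays 1 under exact
  # propagation, so any intensity structure is a boundary artifact. The
  # periodic (unpadded) operator sees a phase jump at the frame edge and
  # produces strong fringes; reflect-padding must suppress them.
  n <- 64
  ramp <- matrix(seq(0, 3, length.out = n), n, n)
  u <- wavefield(exp(1i * ramp), PIX)
  art_pad <- max(abs(intensity(fresnel_propagate(u, WL, 0.3,
                                                 pad = TRUE)) - 1))
  art_nopad <- max(abs(intensity(fresnel_propagate(u, WL, 0.3)) - 1))
  expect_lt(art_pad, art_nopad / 5)
  expect_identical(dim(fresnel_propagate(u, WL, 0.3, pad = TRUE)$values),
                   dim(u$values))
})

test_that("intensity is |u|^2 and invisible for pure phase at contact", {
  n <- 16
  expect_equal(intensity(wavefield(matrix(1 + 0i, n, n), PIX)),
               matrix(1, n, n))
  set.seed(3)
  ph <- matrix(runif(n^2, -pi, pi), n)
  expect_equal(intensity(wavefield(exp(1i * ph), PIX)), matrix(1, n, n),
               tolerance = 1e-14)
  expect_equal(intensity(wavefield(matrix(2i, n, n), PIX)),
               matrix(4, n, n))
})

test_that("CTF forward model: trivial, single-mode exact, Fresnel limit", {
  n <- 128
  zero <- object_maps(matrix(0, n, n), NULL, PIX)
  expect_equal(ctf_forward(zero, WL, 0.2), matrix(1, n, n),
               tolerance = 1e-14)

  # single phase mode: I = 1 + 2 eps sin(chi(f0)) cos(2 pi f0 x), exact
  eps <- 1e-3; k0 <- 8
  f0 <- k0 / (n * PIX)
  xg <- (matrix(seq_len(n), n, n, byrow = TRUE) - 1) * PIX
  obj <- object_maps(eps * cos(2 * pi * f0 * xg), NULL, PIX)
  d <- 0.15
  chi0 <- pi * WL * d * f0^2
  expected <- 1 + 2 * eps * sin(chi0) * cos(2 * pi * f0 * xg)
  expect_equal(ctf_forward(obj, WL, d), expected, tolerance = 1e-12)

  # weak-object limit: agrees with the full Fresnel intensity
  objw <- weak_object(n, phi_max = 1e-3, b_max = 5e-4)
  ifres <- intensity(fresnel_propagate(as_wavefield(objw), WL, 0.1))
  expect_lt(max(abs(ctf_forward(objw, WL, 0.1) - ifres)), 1e-5)
})

test_that("TIE forward model: trivial cases and large-F Fresnel limit", {
  n <- 128
  # constant phase -> I = I0; D = 0 -> I0 exactly
  b <- pmax(grf(n, 6, 0.01, 5) + 0.01, 0)
  obj <- object_maps(matrix(0.3, n, n), b, PIX)
  i0 <- exp(-2 * b)
  expect_equal(tie_forward(obj, WL, 0.2), i0, tolerance = 1e-12)
  obj2 <- weak_object(n)
  expect_equal(tie_forward(obj2, WL, 0), exp(-2 * obj2$B),
               tolerance = 1e-14)

  # pure-phase single mode at F = 50: within 1% of the Fresnel intensity
  a_px <- 16
  f0 <- 1 / (a_px * PIX)
  d <- (a_px * PIX)^2 / (WL * 50)
  xg <- (matrix(seq_len(n), n, n, byrow = TRUE) - 1) * PIX
  objm <- object_maps(0.05 * cos(2 * pi * f0 * xg), NULL, PIX)
  it <- tie_forward(objm, WL, d)
  ifr <- intensity(fresnel_propagate(as_wavefield(objm), WL, d))
  expect_lt(max(abs(it - ifr)) / max(abs(ifr - 1)), 0.01)
})

test_that("forward models conserve flux (DC Fourier coefficient)", {
  n <- 64
  obj <- weak_object(n)
  i0 <- exp(-2 * obj$B)
  for (d in c(0.05, 0.2)) {
    expect_lt(abs(mean(intensity(fresnel_propagate(as_wavefield(obj),
                                                   WL, d))) - mean(i0)),
              1e-10)
    expect_lt(abs(mean(tie_forward(obj, WL, d)) - mean(i0)), 1e-10)
  }
  # ctf_forward conserves the DC of its own linearized contact image
  ictf0 <- ctf_forward(obj, WL, 0)
  expect_lt(abs(mean(ctf_forward(obj, WL, 0.2)) - mean(ictf0)), 1e-10)
})

test_that("wavefield and object_maps validate their invariants", {
  expect_error(wavefield(matrix(1 + 0i, 4, 4), PIX), "8 x 8")
  expect_error(wavefield(matrix(NaN + 0i, 8, 8), PIX), "finite")
  expect_error(wavefield(matrix(1 + 0i, 8, 8), c(1e-6, 2e-6)), "square")
  expect_error(object_maps(matrix(0, 8, 8), matrix(-1, 8, 8), PIX),
               "non-negative")
  obj <- object_maps(matrix(-0.5, 8, 8), matrix(0.2, 8, 8), PIX)
  u <- as_wavefield(obj)
  expect_true(all(Mod(u$values) <= 1))  # B >= 0 <=> |u| <= 1
})
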