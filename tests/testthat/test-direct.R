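# Primary oracle suite: each filter-based method must exactly invert its own
# linearized forward model (up to the unobservable f = 0 component), and
# recover known truth from full-Fresnel simulations in its validity regime.

zero_mean <- function(x) x - mean(x)

test_that("WTIE inverts the weak-TIE forward model and handles trivia", {
  n <- 128; d <- 0.02
  flat <- hologram_stack(matrix(1, n, n), d, PIX, WL)
  expect_equal(wtie(flat)$phi, matrix(0, n, n), tolerance = 1e-12)

  phi <- grf(n, 4, 0.01, 10)
  chi <- chirp_phase(n, n, PIX, WL, d)
  iw <- 1 + Re(holopr:::ifft2(2 * chi * holopr:::fft2(phi)))
  r <- wtie(hologram_stack(iw, d, PIX, WL), alpha = 0)
  expect_lt(max(abs(r$phi - zero_mean(phi))) / max(abs(phi)), 1e-8)

  expect_error(wtie(hologram_stack(matrix(1, n, n), 0, PIX, WL)),
               "degenerate")
})

test_that("WTIE single-mode recovery factor matches the closed form", {
  n <- 64; d <- 0.05; k0 <- 6
  f0 <- k0 / (n * PIX)
  xg <- (matrix(seq_len(n), n, n, byrow = TRUE) - 1) * PIX
  eps <- 0.002
  phi <- eps * cos(2 * pi * f0 * xg)
  chi <- chirp_phase(n, n, PIX, WL, d)
  iw <- 1 + Re(holopr:::ifft2(2 * chi * holopr:::fft2(phi)))
  for (alpha in c(0, 1e-5, 1e-4)) {
    r <- wtie(hologram_stack(iw, d, PIX, WL), alpha = alpha)
    gain <- 2 * pi * WL * d * f0^2
    expect_equal(max(r$phi), eps * gain / (gain + alpha),
                 tolerance = 1e-6)
  }
  # alpha-monotonicity of the recovered amplitude
  amps <- vapply(c(0, 1e-5, 1e-4, 1e-3), function(a)
    max(wtie(hologram_stack(iw, d, PIX, WL), alpha = a)$phi), numeric(1))
  expect_true(all(diff(amps) <= 0))
})

test_that("TIE-HOM inverts its own filter and recovers disc thickness", {
  n <- 128; gam <- 100
  flat <- hologram_stack(matrix(1, n, n), 0.02, PIX, WL)
  rf <- tiehom(flat, gam)
  expect_equal(rf$phi, matrix(0, n, n), tolerance = 1e-12)
  expect_equal(rf$B, matrix(0, n, n), tolerance = 1e-12)

  # apply the filter g_D to a known exp(-2B): exact recovery
  b <- pmax(grf(n, 4, 0.01, 4) + 0.01, 0)
  i0 <- exp(-2 * b)
  g <- 1 + pi * WL * 0.02 * gam * freq_squared_grid(n, n, PIX)
  ih <- Re(holopr:::ifft2(g * holopr:::fft2(i0)))
  r <- tiehom(hologram_stack(ih, 0.02, PIX, WL), gam)
  expect_lt(max(abs(r$B - b)), 1e-10)
  expect_lt(max(abs(r$phi + gam * b)), 1e-8)  # phi = -gamma * B

  # multi-distance least squares reduces to the same answer
  d2 <- 0.035
  g2 <- 1 + pi * WL * d2 * gam * freq_squared_grid(n, n, PIX)
  ih2 <- Re(holopr:::ifft2(g2 * holopr:::fft2(i0)))
  rm2 <- tiehom(hologram_stack(list(ih, ih2), c(0.02, d2), PIX, WL), gam)
  expect_lt(max(abs(rm2$B - b)), 1e-9)

  # full Fresnel simulation of a homogeneous disc at F(edge) = 10:
  # max thickness error <= 2 %
  n2 <- 256
  tmax <- 2e-6
  beta <- 0.02 * WL / (2 * pi * tmax)   # B_max = 0.02
  ph <- make_disc_phantom(c(n2, n2), c(n2 / 2, n2 / 2), 50, tmax,
                          gam * beta, beta, PIX, edge_sigma = 2)
  d10 <- (4 * PIX)^2 / (WL * 10)        # F(4 px feature) = 10
  st <- simulate_fresnel(project_phantom(ph, WL), d10)
  rh <- tiehom(st, gam, beta = beta)
  expect_lt(max(abs(rh$thickness - ph$thickness)) / max(ph$thickness),
            0.02)
})

test_that("CTF retrieval: trivia, self-consistency, Fresnel recovery", {
  n <- 128
  flat <- hologram_stack(list(matrix(1, n, n), matrix(1, n, n)),
                         c(0.1, 0.15), PIX, WL)
  rf <- ctf_retrieve(flat)
  expect_equal(rf$phi, matrix(0, n, n), tolerance = 1e-12)
  expect_equal(rf$B, matrix(0, n, n), tolerance = 1e-12)

  # data generated by ctf_forward, two distances, alpha = 0: exact inverse
  obj <- weak_object(n)
  ds <- c(0.10, 0.15)
  imgs <- lapply(ds, function(d) ctf_forward(obj, WL, d))
  r <- ctf_retrieve(hologram_stack(imgs, ds, PIX, WL), alpha = 0)
  expect_lt(max(abs(r$phi - zero_mean(obj$phi))), 1e-9)
  expect_lt(max(abs(r$B - obj$B)), 1e-9)

  # Fresnel-simulated weak phantom, 3 distances: NRMSE(phi) <= 2 %
  n2 <- 256
  obj2 <- weak_object(n2, phi_max = 0.01, b_max = 0.005)
  st3 <- simulate_fresnel(obj2, c(0.10, 0.15, 0.22))
  expect_lt(nrmse(ctf_retrieve(st3, alpha = 1e-8)$phi, obj2$phi), 0.02)
})

test_that("NRMSE decreases as distances are added (1 -> 2 -> 4)", {
  n <- 256
  obj <- weak_object(n)
  sets <- list(0.10, c(0.10, 0.15), c(0.10, 0.15, 0.22, 0.30))
  errs <- vapply(sets, function(ds)
    nrmse(ctf_retrieve(simulate_fresnel(obj, ds), alpha = 1e-8)$phi,
          obj$phi), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("pure-phase CTF: trivia, algebraic reduction, Fresnel recovery", {
  n <- 128
  flat <- hologram_stack(list(matrix(1, n, n), matrix(1, n, n)),
                         c(0.1, 0.15), PIX, WL)
  expect_equal(ctf_pure_phase(flat)$phi, matrix(0, n, n),
               tolerance = 1e-12)

  # on B = 0 data it inverts ctf_forward like the full CTF does
  phi <- grf(n, 4, 0.01, 10)
  obj <- object_maps(phi, NULL, PIX)
  ds <- c(0.10, 0.15)
  st <- hologram_stack(lapply(ds, function(d) ctf_forward(obj, WL, d)),
                       ds, PIX, WL)
  expect_lt(max(abs(ctf_pure_phase(st, alpha = 0)$phi - zero_mean(phi))),
            1e-9)

  # pure-phase weak phantom, 4 distances, full Fresnel: NRMSE <= 2 %
  n2 <- 256
  obj2 <- object_maps(grf(n2, 4, 0.01, 10), NULL, PIX)
  st4 <- simulate_fresnel(obj2, c(0.10, 0.15, 0.22, 0.30))
  expect_lt(nrmse(ctf_pure_phase(st4, alpha = 1e-8)$phi, obj2$phi), 0.02)
})

test_that("mixed approach: reduction, trivia, prior-based disc recovery", {
  n <- 128
  # zero-contrast stack with I0 = 1 -> phi = 0
  flat <- hologram_stack(list(matrix(1, n, n), matrix(1, n, n)),
                         c(0.05, 0.1), PIX, WL)
  expect_equal(mixed_approach(flat, matrix(1, n, n))$phi, matrix(0, n, n),
               tolerance = 1e-12)

  # I0 = 1, prior none: identical to pure-phase CTF
  phi <- grf(n, 4, 0.01, 10)
  obj <- object_maps(phi, NULL, PIX)
  ds <- c(0.10, 0.15)
  st <- hologram_stack(lapply(ds, function(d) ctf_forward(obj, WL, d)),
                       ds, PIX, WL)
  expect_lt(max(abs(mixed_approach(st, matrix(1, n, n), alpha = 1e-8)$phi -
                    ctf_pure_phase(st, alpha = 1e-8)$phi)), 1e-10)

  # inverts its own linearized model (psi = I0 * phi) to 1e-8
  b <- pmax(grf(n, 4, 0.01, 4) + 0.01, 0)
  i0 <- exp(-2 * b)
  psi <- i0 * phi
  mk <- function(d) {
    chi <- chirp_phase(n, n, PIX, WL, d)
    Re(holopr:::ifft2(cos(chi) * holopr:::fft2(i0) +
                      2 * sin(chi) * holopr:::fft2(psi)))
  }
  stm <- hologram_stack(lapply(ds, function(d) pmax(mk(d), 0)), ds,
                        PIX, WL)
  rm_ <- mixed_approach(stm, i0, prior = "none", alpha = 0)
  expect_lt(max(abs(zero_mean(rm_$phi - phi))), 1e-8)

  # homogeneous disc, true delta/beta prior, 2 distances: NRMSE <= 3 %
  n2 <- 256; gam <- 100; tmax <- 2e-6
  beta <- 0.02 * WL / (2 * pi * tmax)
  ph <- make_disc_phantom(c(n2, n2), c(n2 / 2, n2 / 2), 50, tmax,
                          gam * beta, beta, PIX, edge_sigma = 2)
  objh <- project_phantom(ph, WL)
  sth <- simulate_fresnel(objh, c(0.05, 0.10))
  rmix <- mixed_approach(sth, exp(-2 * objh$B), prior = "homogeneous",
                         delta_beta = gam, alpha = 1e-8)
  expect_lt(nrmse(rmix$phi, objh$phi), 0.03)

  expect_error(mixed_approach(st, NULL), "contact")
})

test_that("mixed approach multimaterial and heterogeneous priors", {
  n <- 128; ds <- c(0.05, 0.1)
  gam <- 80; tmax <- 2e-6
  beta <- 0.02 * WL / (2 * pi * tmax)
  ph <- make_disc_phantom(c(n, n), c(n / 2, n / 2), 30, tmax,
                          gam * beta, beta, PIX, edge_sigma = 2)
  obj <- project_phantom(ph, WL)
  st <- simulate_fresnel(obj, ds)
  i0 <- exp(-2 * obj$B)
  # single material described via each prior parameterization: all three
  # should behave like the homogeneous prior with the true delta/beta
  rhom <- mixed_approach(st, i0, prior = "homogeneous", delta_beta = gam)
  rmm <- mixed_approach(st, i0, prior = "multimaterial",
                        material_thresholds = -0.01,
                        material_delta_beta = c(gam, gam))
  rhet <- mixed_approach(st, i0, prior = "heterogeneous",
                         hetero_fn = function(b) gam)
  expect_equal(rmm$phi, rhom$phi, tolerance = 1e-12)
  expect_equal(rhet$phi, rhom$phi, tolerance = 1e-12)
  expect_error(mixed_approach(st, i0, prior = "multimaterial",
                              material_thresholds = c(0.1, 0.05),
                              material_delta_beta = c(1, 2, 3)))
})

test_that("filter methods are linear in the data at fixed alpha", {
  n <- 64; ds <- c(0.08, 0.12)
  set.seed(77)
  mk_stack <- function(imgs) hologram_stack(imgs, ds, PIX, WL)
  dev <- function() {
    z <- matrix(rnorm(n^2), n)
    0.01 * (z - mean(z))   # unit background exactly
  }
  i_a <- lapply(1:2, function(k) 1 + dev())
  i_b <- lapply(1:2, function(k) 1 + dev())
  i_mix <- Map(function(a, b) 0.3 * a + 0.7 * b, i_a, i_b)
  # superposition of the deviations from the unit background
  for (fn in list(function(s) wtie(s, alpha = 1e-6)$phi,
                  function(s) ctf_retrieve(s, alpha = 1e-6)$phi,
                  function(s) ctf_pure_phase(s, alpha = 1e-6)$phi)) {
    lhs <- fn(mk_stack(i_mix))
    rhs <- 0.3 * fn(mk_stack(i_a)) + 0.7 * fn(mk_stack(i_b))
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("retrieve_phase dispatches on the configuration", {
  n <- 64
  obj <- weak_object(n)
  st <- simulate_fresnel(obj, c(0.08, 0.12))
  r1 <- retrieve_phase(st, retrieval_config("ctf", alpha = 1e-8))
  expect_equal(r1$phi, ctf_retrieve(st, alpha = 1e-8)$phi)
  r2 <- retrieve_phase(st, retrieval_config("tiehom", delta_beta = 50))
  expect_equal(r2$method, "tiehom")
  expect_error(retrieve_phase(st, retrieval_config("tiehom")), "delta_beta")
  expect_error(retrieval_config("ctf", alpha = -1))
})
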