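eps_w <- 8.8541878128e-12 * 80

test_that("no larva means zero potential and zero induced charge everywhere", {
  f <- solve_potential(coarse_domain(), comb_geometry(), larva_body(), 0)
  expect_true(all(f$phi == 0))
  for (k in 1:3) expect_equal(induced_charge(f, comb_geometry(), k), 0)
  expect_equal(body_charge(f), 0)
})

test_that("the solver reproduces the closed-form parallel-plate capacitor", {
  # plates at 0 and -21 mV, separation 40 units: interior linear, field V/d
  ny <- 41L; nx <- 21L
  bc <- matrix(NA_real_, ny, nx)
  bc[1, ] <- 0
  bc[ny, ] <- -21e-3
  phi <- solve_laplace_grid(bc, h = 1)
  expected <- matrix(rep(-21e-3 * (0:(ny - 1)) / (ny - 1), nx), ny, nx)
  expect_lt(max(abs(phi - expected)) / 21e-3, 0.02)
  grad <- (phi[2, ] - phi[1, ]) / 1
  expect_equal(unname(grad), rep(-21e-3 / 40, nx), tolerance = 1e-10)
})

test_that("the solver matches the image-line-charge closed form to < 2%", {
  # small square held at -21 mV over a wide grounded plane; probe potentials
  # compare with the line-charge + image formula using the measured charge
  h <- 5; W <- 3200; H <- 1600
  nx <- W / h + 1L; ny <- H / h + 1L
  x <- (0:(nx - 1)) * h; y <- (0:(ny - 1)) * h
  bc <- matrix(NA_real_, ny, nx)
  bc[1, ] <- 0
  xc <- 1600; yc <- 60
  sq_r <- which(y >= yc - 10 & y <= yc + 10)
  sq_c <- which(x >= xc - 10 & x <= xc + 10)
  bc[sq_r, sq_c] <- -21e-3
  phi <- solve_laplace_grid(bc, h)

  mask_sq <- matrix(FALSE, ny, nx); mask_sq[sq_r, sq_c] <- TRUE
  lam <- eps_w * larvasense:::flux_out_of(phi, mask_sq)  # charge per depth
  # the full plane collects the mirror charge (image identity, Gauss)
  mask_pl <- matrix(FALSE, ny, nx); mask_pl[1, ] <- TRUE
  q_plane <- eps_w * larvasense:::flux_out_of(phi, mask_pl)
  expect_equal(q_plane, -lam, tolerance = 1e-9)

  pred <- function(px, py) {
    lam / (2 * pi * eps_w) *
      log(sqrt((px - xc)^2 + (py + yc)^2) / sqrt((px - xc)^2 + (py - yc)^2))
  }
  for (p in list(c(1600, 200), c(1600, 300), c(1450, 200), c(1750, 150))) {
    fd <- phi[which.min(abs(y - p[2])), which.min(abs(x - p[1]))]
    expect_lt(abs(fd - pred(p[1], p[2])) / abs(pred(p[1], p[2])), 0.02)
  }
})

test_that("potentials and waveforms scale linearly with surface potential", {
  f1 <- solve_potential(coarse_domain(), comb_geometry(), larva_body(), 200)
  f2 <- solve_potential(coarse_domain(), comb_geometry(),
                        larva_body(surface_potential = -42e-3), 200)
  expect_equal(f2$phi, 2 * f1$phi, tolerance = 1e-12)

  w1 <- simulate_cycle(coarse_domain(), n_steps = 20)
  wh <- simulate_cycle(coarse_domain(),
                       larva = larva_body(surface_potential = -10.5e-3),
                       n_steps = 20)
  expect_equal(wh$samples, 0.5 * w1$samples, tolerance = 1e-10)
  wz <- simulate_cycle(coarse_domain(),
                       larva = larva_body(surface_potential = 0), n_steps = 20)
  expect_true(all(wz$samples == 0))
})

test_that("induced charges satisfy Gauss's law over the closed domain", {
  f <- solve_potential(sim_domain(), comb_geometry(), larva_body(), 260)
  qe <- comb_charge(f, "all")
  qb <- body_charge(f)
  expect_lt(abs(qe + qb) / abs(qb), 0.05)
  expect_equal(comb_charge(f, "counter") + comb_charge(f, "base"), qe)
  expect_lt(qb, 0)  # negative surface potential carries negative charge
  expect_error(induced_charge(f, comb_geometry(), 99), "out of range")
})

test_that("induced charge is periodic under a one-period body shift", {
  dom <- sim_domain(width = 1000, height = 130, grid_spacing = 2.5,
                    symmetry = FALSE)
  cmb <- comb_geometry(n_teeth = 10)
  lv <- larva_body(length_min = 40, length_max = 80)
  f1 <- solve_potential(dom, cmb, lv, 380)
  f2 <- solve_potential(dom, cmb, lv, 480)  # shifted by one 100 um period
  q1 <- vapply(3:8, function(k) induced_charge(f1, cmb, k), 0)
  q2 <- vapply(4:9, function(k) induced_charge(f2, cmb, k), 0)
  expect_lt(max(abs(q2 - q1)) / max(abs(q1)), 0.01)
})

test_that("a stationary body drives no current", {
  dom <- coarse_domain()
  f <- solve_potential(dom, comb_geometry(), larva_body(), 150)
  q1 <- comb_charge(f, "counter")
  f2 <- solve_potential(dom, comb_geometry(), larva_body(), 150)
  expect_identical(comb_charge(f2, "counter"), q1)  # quasi-static: Q(extent)
  # dQ/dt = 0 for constant extent, hence V = 0 at every step
})

test_that("the cycle waveform fluctuates around zero and converges in grid", {
  w5 <- simulate_cycle(sim_domain(grid_spacing = 5), n_steps = 40)
  expect_lt(abs(mean(w5$samples)), 0.05 * w5$metadata$amplitude_V)
  w25 <- simulate_cycle(sim_domain(grid_spacing = 2.5), n_steps = 40)
  a5 <- w5$metadata$amplitude_V; a25 <- w25$metadata$amplitude_V
  expect_lt(abs(a25 - a5) / a25, 0.10)
})

test_that("alternate comb designs run and finer pitch raises power at close flight", {
  # the 40/10 and 160/40 um designs are supported via comb_geometry
  alt <- simulate_cycle(sim_domain(grid_spacing = 2.5), comb_geometry(40, 10),
                        n_steps = 20)
  expect_true(all(is.finite(alt$samples)))
  expect_gt(alt$metadata$amplitude_V, 0)
  # finer pitch increases mean generated power once the body flies closer
  # than the gap width (pitch granularity unresolved at larger clearance)
  lv <- larva_body(clearance = 5)
  rms_80 <- sqrt(mean(simulate_cycle(sim_domain(grid_spacing = 2.5),
                                     comb_geometry(80, 20), lv,
                                     n_steps = 20)$samples^2))
  rms_40 <- sqrt(mean(simulate_cycle(sim_domain(grid_spacing = 2.5),
                                     comb_geometry(40, 10), lv,
                                     n_steps = 20)$samples^2))
  expect_gt(rms_40, rms_80)
})

test_that("Ohm's law and power worked examples are exact", {
  expect_equal(ohmic_current(0.11e-3, circuit(150)), 0.11e-3 / 150)
  expect_equal(ohmic_current(0, circuit(150)), 0)
  expect_equal(ohmic_current(0.8e-3, circuit(150)), 5.33e-6, tolerance = 1e-3)
  expect_equal(electrical_power(0.11e-3, 730e-9), 8.03e-11, tolerance = 1e-3)
  expect_equal(electrical_power(0, 1), 0)
  expect_equal(electrical_power(2 * 0.11e-3, 2 * 730e-9),
               4 * electrical_power(0.11e-3, 730e-9))
  expect_error(ohmic_current(-1, circuit(150)), ">= 0")
})

test_that("triangular kinematics reproduce the stated edge speed", {
  kin <- motion_kinematics(2)
  lv <- larva_body()
  expect_equal(edge_speed(kin, lv), 2.08)
  t <- seq(0, 1, by = 1e-4)
  len <- triangular_length(t, kin, lv)
  expect_equal(range(len), c(80, 600))
  # mean absolute length change rate equals the edge speed
  expect_equal(mean(abs(diff(len))) / 1e-4 * 1e-3, 2.08, tolerance = 1e-3)
})

test_that("geometry validation rejects unresolvable or oversized setups", {
  expect_error(solve_potential(sim_domain(grid_spacing = 10), comb_geometry(),
                               larva_body(), 100), "4 cells")
  expect_error(solve_potential(coarse_domain(), comb_geometry(),
                               larva_body(height = 200), 100), "fit")
  expect_error(comb_geometry(tooth_width = -1), "positive")
  expect_error(circuit(0), "positive")
  expect_error(motion_kinematics(0), "positive")
})
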