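test_that("zero diffusion leaves positions unchanged", {
  geom <- cell_geometry(5, 0.8)
  set.seed(20)
  p <- sample_uniform_positions(10, geom)
  q <- step_brownian(p, D = 0, dt = 1e-6, geom = geom)
  expect_equal(unclass(q)[, ], p[, ])
})

test_that("free-space ensemble MSD has slope 6 D within 2 percent", {
  set.seed(21)
  D <- 10
  dt <- 1e-4
  n <- 1000
  steps <- 100
  p <- matrix(0, n, 3)
  msd <- numeric(steps)
  for (s in seq_len(steps)) {
    p <- step_brownian(p, D, dt, geom = NULL)
    msd[s] <- mean(rowSums(p^2))
  }
  tt <- seq_len(steps) * dt
  slope <- sum(msd * tt) / sum(tt^2) # through-origin regression
  expect_equal(slope, 6 * D, tolerance = 0.02)
})

test_that("confined stepping preserves the uniform stationary law", {
  geom <- cell_geometry(5, 0.8)
  set.seed(22)
  n <- 4000
  p <- sample_uniform_positions(n, geom)
  for (s in 1:150) p <- step_brownian(p, 10, 1e-5, geom)
  expect_true(all(inside_spherocylinder(p, geom)))
  frac <- mean(abs(p[, 1]) <= (geom$L - geom$d) / 2)
  expected <- ((geom$L - geom$d) * pi * geom$d^2 / 4) /
    spherocylinder_volume(geom$L, geom$d)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("redraw and reflect boundaries give indistinguishable occupancy", {
  # at the fine native step the two boundary rules agree; at much coarser
  # steps the redraw rule measurably depletes near-wall occupancy
  geom <- cell_geometry(5, 0.8)
  set.seed(23)
  n <- 3000
  p0 <- sample_uniform_positions(n, geom)
  pr <- p0
  pf <- p0
  for (s in 1:100) {
    pr <- step_brownian(pr, 10, 1e-6, geom, boundary = "redraw")
    pf <- step_brownian(pf, 10, 1e-6, geom, boundary = "reflect")
  }
  # compare radial occupancy across the cell width
  ks <- suppressWarnings(
    ks.test(sqrt(pr[, 2]^2 + pr[, 3]^2), sqrt(pf[, 2]^2 + pf[, 3]^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("an immobile emitter at the focus gives a constant unit trace", {
  cfg <- simulation_config(n_particles = 1, dt = 1e-4, duration = 0.01,
                           geometry = cell_geometry(5, 0.85),
                           motion = motion_model("brownian", D = 0), seed = 1)
  tr <- simulate_trace(cfg, initial_positions = cfg$confocal$center)
  expect_equal(tr$values, rep(1, 100))
})

test_that("default acquisition yields bounded intensity of the right length", {
  cfg <- small_brownian_config(seed = 24, duration = 1)
  tr <- simulate_trace(cfg)
  expect_length(tr$values, 1e5)
  expect_true(all(tr$values >= 0 & tr$values <= cfg$n_particles))
})

test_that("time-averaged intensity matches the PSF integral over the cell", {
  cfg <- small_brownian_config(seed = 25, duration = 8)
  tr <- simulate_trace(cfg)
  set.seed(26)
  pts <- sample_uniform_positions(2e5, cfg$geometry)
  expected <- cfg$n_particles * mean(psf_intensity(pts, cfg$confocal))
  expect_equal(mean(tr$values), expected, tolerance = 0.05)
})

test_that("traces are stationary: half-trace means agree within 3 SE", {
  cfg <- small_brownian_config(seed = 27, duration = 16)
  tr <- simulate_trace(cfg)
  # block means: 16 blocks of 1 s, far longer than the slowest relaxation
  blocks <- colMeans(matrix(tr$values, ncol = 16))
  h1 <- blocks[1:8]; h2 <- blocks[9:16]
  se <- sqrt(var(h1) / 8 + var(h2) / 8)
  expect_lt(abs(mean(h1) - mean(h2)), 3 * se)
})

test_that("identical config and seed give bit-identical traces", {
  cfg <- small_brownian_config(seed = 28, duration = 0.2)
  expect_identical(simulate_trace(cfg)$values, simulate_trace(cfg)$values)
  cfgf <- simulation_config(n_particles = 5, dt = 1e-4, duration = 0.5,
                            geometry = cell_geometry(5, 0.85),
                            motion = motion_model("fbm", alpha = 0.9,
                                                  Gamma = 14),
                            boundary = "reflect", seed = 29)
  expect_identical(simulate_trace(cfgf)$values, simulate_trace(cfgf)$values)
  cfg2 <- cfg
  cfg2$seed <- 99
  expect_false(identical(simulate_trace(cfg)$values,
                         simulate_trace(cfg2)$values))
})

test_that("fBm with alpha = 1 and Gamma = 2D reproduces Brownian statistics", {
  D <- 10
  cfgb <- small_brownian_config(seed = 30, duration = 6)
  cfgf <- simulation_config(n_particles = 50, dt = 1e-5, duration = 6,
                            geometry = cell_geometry(5, 0.85),
                            motion = motion_model("fbm", alpha = 1,
                                                  Gamma = 2 * D),
                            boundary = "reflect", seed = 30)
  ab <- compute_acf(simulate_trace(cfgb), min_lag = 2e-5, max_lag = 0.05)
  af <- compute_acf(simulate_trace(cfgf), min_lag = 2e-5, max_lag = 0.05)
  fb <- fit_acf(ab, "anomalous", fixed = list(S = 4, F_P = 0))
  ff <- fit_acf(af, "anomalous", fixed = list(S = 4, F_P = 0))
  expect_equal(ff$par$tau_D, fb$par$tau_D, tolerance = 0.15)
  expect_equal(ff$par$alpha, fb$par$alpha, tolerance = 0.1)
})

test_that("a confocal center outside the cell is rejected", {
  expect_error(simulation_config(confocal = confocal_volume(0.2, 0.8,
                                                            c(0, 0.6, 0))),
               "outside")
})

test_that("bleaching plumbing darkens emitters irreversibly", {
  cfg <- small_brownian_config(seed = 32, duration = 8)
  cfg$bleach_rate <- 3
  tr <- simulate_trace(cfg)
  first <- mean(head(tr$values, 4e4))
  last <- mean(tail(tr$values, 4e4))
  expect_lt(last, 0.8 * first)
})
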