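test_that("free diffusion has the right single-step displacement variance", {
  sys <- synthetic_system(50)  # walls far away
  p <- brownian_params(D = 1, dt = 0.01, n_molecules = 10,
                       n_steps = 10000L, save_stride = 0.01, seed = 21L)
  tr <- simulate_brownian(sys, p, start = matrix(0, 10, 3))
  d <- apply(tr$rel, c(2, 3), diff)
  v <- var(as.vector(d))
  n <- length(d)
  se <- 2 * 0.01 * sqrt(2 / n)   # SE of a variance estimate
  expect_lt(abs(v - 0.02), 3 * se)
})

test_that("identical seeds give identical trajectories", {
  sys <- synthetic_system(10, list(well_spec(c(3, 0, 0), 2, 2, "w")))
  p <- brownian_params(n_molecules = 4, n_steps = 2000L, save_stride = 1,
                       seed = 22L)
  t1 <- simulate_brownian(sys, p)
  t2 <- simulate_brownian(sys, p)
  expect_identical(t1$rel, t2$rel)
})

test_that("a deep well raises in-well residence over free diffusion", {
  mk <- function(depth) {
    sys <- synthetic_system(8, if (depth > 0)
      list(well_spec(c(0, 0, 0), 3, depth, "w")) else list())
    tr <- simulate_brownian(sys, brownian_params(
      n_molecules = 20, n_steps = 1e5, save_stride = 1, seed = 23L))
    mean(tr$dist < 3)
  }
  frac0 <- mk(0)
  frac4 <- mk(4)
  expect_gt(frac4, frac0)
  # Boltzmann enhancement should be substantial, not marginal
  expect_gt(frac4 / frac0, 3)
})

test_that("reflecting walls keep every saved position inside the box", {
  sys <- synthetic_system(4, sink_radius = 1)
  tr <- simulate_brownian(sys, brownian_params(
    n_molecules = 10, n_steps = 5e4, save_stride = 0.5, seed = 24L))
  expect_lte(max(abs(tr$rel)), 4)
})

test_that("too-large timesteps are refused", {
  sys <- synthetic_system(10, list(well_spec(c(0, 0, 0), 0.5, 50, "sharp")))
  expect_error(
    simulate_brownian(sys, brownian_params(dt = 0.01, n_molecules = 1,
                                           n_steps = 10, save_stride = 0.01)),
    "timestep")
})

test_that("brute-force MFPT matches the spherical-shell closed form", {
  sys <- synthetic_system(20)
  theory <- shell_mfpt_theory(a = 6, b = 20, r0 = 20, D = 1)
  bf <- brute_force_mfpt(sys, brownian_params(D = 1, dt = 0.01, seed = 25L),
                         source_radius = 20, sink_radius = 6,
                         n_events = 4000L, outer = "sphere")
  expect_lt(abs(bf$mean - theory), 2 * bf$se)
  expect_equal(bf$censored, 0L)
})

test_that("coincident source and sink give zero passage time", {
  sys <- synthetic_system(20)
  bf <- brute_force_mfpt(sys, brownian_params(seed = 26L), 10, 10,
                         n_events = 50L)
  expect_equal(bf$mean, 0)
})

test_that("trapping wells on the source shell slow passage to the sink", {
  # the traps must be metastable side pockets far from the sink: wells whose
  # inner edge approaches the sink act as stepping stones and can even
  # accelerate passage, so these sit against the outer wall
  free_sys <- synthetic_system(10, sink_radius = 2)
  trap_sys <- synthetic_system(
    10, list(well_spec(c(0, 8, 0), 3, 4, "t1"),
             well_spec(c(0, -8, 0), 3, 4, "t2")), sink_radius = 2)
  p <- brownian_params(D = 1, dt = 0.02, seed = 27L)
  bf_free <- brute_force_mfpt(free_sys, p, 9, 2, n_events = 4000L,
                              outer = "box")
  bf_trap <- brute_force_mfpt(trap_sys, p, 9, 2, n_events = 4000L,
                              outer = "box")
  expect_gt(bf_trap$mean - bf_free$mean,
            2 * sqrt(bf_trap$se^2 + bf_free$se^2))
})

test_that("boltzmann reference is uniform without a potential and sums to 1", {
  sys <- synthetic_system(5.5, sink_radius = 1)
  g <- grid_spec(1, 5, wrap = "clamp")
  w <- boltzmann_reference(sys, g)
  expect_equal(sum(w), 1)
  expect_equal(unname(w), rep(1 / length(w), length(w)))
  expect_equal(length(w), 11^3)
})

test_that("two equal-volume wells at depths 0 and ln 2 occupy 1:2", {
  sys <- synthetic_system(
    10.5, list(well_spec(c(-5, 0, 0), 2.5, 0, "shallow"),
               well_spec(c(5, 0, 0), 2.5, log(2), "deep")),
    sink_radius = 1)
  g <- grid_spec(0.5, 10, wrap = "clamp")
  w <- boltzmann_reference(sys, g)
  xyz <- state_to_grid(as.integer(names(w)), g)
  in_a <- sqrt(rowSums(sweep(xyz, 2, c(-5, 0, 0))^2)) <= 2.5
  in_b <- sqrt(rowSums(sweep(xyz, 2, c(5, 0, 0))^2)) <= 2.5
  ratio <- sum(w[in_b]) / sum(w[in_a])
  # independent oracle: radial quadrature of the Boltzmann factor over the
  # smooth ramp profile, exp(depth * (1 - 3t^2 + 2t^3)); the zero-depth well
  # integrates to the plain volume, so the ratio is the mean Boltzmann factor
  boltz <- function(r, depth, R) exp(depth * (1 - 3 * (r / R)^2 +
                                                2 * (r / R)^3)) * r^2
  num <- stats::integrate(boltz, 0, 2.5, depth = log(2), R = 2.5)$value
  den <- stats::integrate(function(r) r^2, 0, 2.5)$value
  expect_equal(ratio, num / den, tolerance = 0.02)
  expect_gt(ratio, 1)  # deeper well holds more mass
})

test_that("scripted fixtures hit their waypoints and validate input", {
  wp <- data.frame(time = c(0, 50, 100), id = "m",
                   x = c(25, 5, 25), y = 0, z = 0)
  tr <- scripted_fixture(wp, save_stride = 10)
  expect_equal(n_frames(tr), 11L)
  expect_equal(tr$dist[c(1, 6, 11), 1], c(25, 5, 25))
  expect_equal(tr$dist[2, 1], 21)  # linear interpolation
  expect_error(scripted_fixture(rbind(wp, wp[1, ])), "duplicate")
  expect_error(scripted_fixture(wp[1, , drop = FALSE], 10), "2 frames")
})

test_that("well-lining pseudo-residues sit on the well surface with regions", {
  sys <- synthetic_system(
    10, list(well_spec(c(6, 0, 0), 2, 3.5, "wA"),
             well_spec(c(0, -6, 0), 2.5, 3.5, "wB")), sink_radius = 3)
  env <- environment_from_system(sys, n_points = 26L)
  expect_equal(nrow(env$atoms), 52L)
  expect_setequal(names(env$regions), c("wA", "wB"))
  a <- env$atoms[env$atoms$label == "wA", ]
  r <- sqrt((a$x - 6)^2 + a$y^2 + a$z^2)
  expect_equal(r, rep(2, 26), tolerance = 1e-9)
})
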