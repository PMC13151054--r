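test_that("the default grid enumerates 40^3 states and rounds to nearest point", {
  g <- grid_spec()
  expect_equal(n_grid_states(g), 64000)
  tr <- gas_traj(c(0, 100), "m",
                 array(rep(c(0.4, -0.3, 0.2), each = 2), c(2, 1, 3)),
                 stride = 100)
  dt_ <- assign_states(tr, g)
  expect_equal(dt_$dtrajs$m[1], grid_to_state(cbind(0, 0, 0), g))
})

test_that("out-of-cube positions wrap periodically or clamp", {
  tr <- gas_traj(c(0, 100), "m",
                 array(rep(c(25, 0, 0), each = 2), c(2, 1, 3)), stride = 100)
  gp <- grid_spec(1, 20, "periodic")
  sp <- assign_states(tr, gp)$dtrajs$m[1]
  expect_equal(state_to_grid(sp, gp)[1, ], c(-15, 0, 0))
  gc <- grid_spec(1, 20, "clamp")
  sc <- assign_states(tr, gc)$dtrajs$m[1]
  expect_equal(state_to_grid(sc, gc)[1, ], c(20, 0, 0))
})

test_that("state indexing is bijective over the cube", {
  for (wrap in c("periodic", "clamp")) {
    g <- grid_spec(1, 4, wrap)
    rng <- if (wrap == "periodic") -4:3 else -4:4
    pts <- as.matrix(expand.grid(rng, rng, rng))
    ids <- grid_to_state(pts, g)
    expect_equal(sort(ids), seq_len(n_grid_states(g)))
    expect_equal(state_to_grid(ids, g), unname(pts))
  }
})

test_that("event restriction nulls frames outside traced spans", {
  d <- c(25, 18, 10, 5, 4, 9, 21, 25, 25)
  tr <- gas_traj((seq_along(d) - 1) * 10, "m",
                 array(c(d, rep(0, 18)), c(9, 1, 3)), stride = 10)
  ev <- detect_events(tr)
  dt_ <- assign_states(tr, grid_spec(1, 20, "clamp"))
  r <- restrict_to_events(dt_, ev)
  expect_true(all(!is.na(r$dtrajs$m[1:7])))  # event spans frames 1..7
  expect_true(all(is.na(r$dtrajs$m[8:9])))
  none <- restrict_to_events(dt_, ev[0, ])
  expect_true(all(is.na(none$dtrajs$m)))
})

test_that("sliding-window counts match hand enumeration and the MLE is row-normalized", {
  dt_ <- chain_dtraj(c(1L, 1L, 2L, 2L), stride = 100)
  m <- estimate_msm(dt_, 100)
  expect_equal(as.matrix(m$counts),
               matrix(c(1, 0, 1, 1), 2, 2), ignore_attr = TRUE)
  expect_equal(as.matrix(m$T),
               matrix(c(0.5, 0, 0.5, 1), 2, 2), ignore_attr = TRUE)
  expect_equal(m$n_pairs, 3L)
  # counts row (2, 8) -> T row (0.2, 0.8)
  dt2 <- chain_dtraj(rep(c(1L, 1L, 1L, 1L, 1L, 2L), 20), stride = 100)
  m2 <- estimate_msm(dt2, 100)
  expect_equal(sum(abs(Matrix::rowSums(m2$T) - 1)), 0, tolerance = 1e-12)
})

test_that("count total equals the number of valid lagged pairs", {
  set.seed(41)
  v <- sample(c(1:5, NA), 500, replace = TRUE)
  dt_ <- chain_dtraj(v, stride = 100, n_states = 5L)
  for (lag in c(100, 300)) {
    L <- lag / 100
    a <- v[1:(500 - L)]; b <- v[(1 + L):500]
    m <- estimate_msm(dt_, lag)
    expect_equal(m$n_pairs, sum(!is.na(a) & !is.na(b)))
    expect_equal(sum(m$counts), m$n_pairs)
  }
})

test_that("symmetric two-state chains have the uniform stationary distribution", {
  set.seed(42)
  v <- simulate_chain(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2), 4000)
  m <- estimate_msm(chain_dtraj(v, stride = 100), 100)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 0.05)
  expect_lte(max(Mod(gasport:::msm_eigenvalues(m, 2))), 1 + 1e-12)
})

test_that("implied timescale matches the closed form for a known eigenvalue", {
  Tm <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)  # lambda_2 = 0.9
  m <- msm_from_matrix(Tm, lag = 100)
  its <- implied_timescales_model(m, 1)
  expect_equal(its$its_ps, -100 / log(0.9), tolerance = 1e-6)
  # identity chain: divergent timescale
  mi <- msm_from_matrix(diag(2), lag = 100)
  expect_equal(implied_timescales_model(mi, 1)$its_ps, Inf)
})

test_that("implied timescales are lag-invariant for Markovian data", {
  set.seed(43)
  Tm <- matrix(c(0.95, 0.04, 0.01,
                 0.03, 0.95, 0.02,
                 0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  v <- simulate_chain(Tm, 2e5)
  dt_ <- chain_dtraj(v, stride = 100)
  its <- implied_timescales(dt_, c(100, 200, 500), n_its = 2)
  t2 <- its$its_ps[its$k == 2]
  expect_lt(max(abs(t2 - mean(t2))) / mean(t2), 0.15)
})

test_that("Bayesian posterior matches conjugate closed forms and is seeded", {
  m1 <- msm_from_matrix(matrix(c(1, 0, 0, 1), 2, 2), lag = 100)
  m1$counts <- Matrix::Matrix(matrix(c(1000, 0, 0, 1000), 2, 2),
                              sparse = TRUE)
  s <- sample_bayesian(m1, n_samples = 400L, seed = 51L)
  t11 <- vapply(s$T_samples, function(Tm) Tm[1, 1], numeric(1))
  # Beta(1000.5, 0.5) lower 2.5% quantile, computed independently
  expect_gt(quantile(t11, 0.025), 0.99)
  expect_lt(abs(mean(t11) - 1000.5 / 1001), 1e-3)
  m2 <- m1
  m2$counts <- Matrix::Matrix(matrix(c(1, 1, 1, 1), 2, 2), sparse = TRUE)
  s2 <- sample_bayesian(m2, n_samples = 4000L, seed = 52L)
  t11b <- vapply(s2$T_samples, function(Tm) Tm[1, 1], numeric(1))
  expect_equal(mean(t11b), (1 + 0.5) / (2 + 1), tolerance = 0.01)
  s2b <- sample_bayesian(m2, n_samples = 4000L, seed = 52L)
  expect_identical(s2$T_samples, s2b$T_samples)
  # every sampled matrix is row-stochastic to 1e-12
  expect_lt(max(abs(vapply(s2$T_samples, function(Tm)
    max(abs(rowSums(Tm) - 1)), numeric(1)))), 1e-12)
})

test_that("the CK test accepts data generated by an exact Markov chain", {
  set.seed(44)
  Tm <- matrix(c(0.92, 0.06, 0.02,
                 0.03, 0.94, 0.03,
                 0.02, 0.06, 0.92), 3, 3, byrow = TRUE)
  v <- simulate_chain(Tm, 2e5)
  dt_ <- chain_dtraj(v, stride = 100)
  ck <- ck_test(dt_, lag = 100, sets = list(1L, 3L), ks = 1:5,
                n_samples = 200L, seed = 45L)
  expect_true(all(ck$pass))
  expect_equal(ck$predicted[ck$k == 1], ck$estimated[ck$k == 1],
               tolerance = 1e-12)
})

test_that("milestoning relabels by the most recent core", {
  dt_ <- chain_dtraj(c(1L, 5L, 5L, 9L, 5L, NA, 1L), stride = 100,
                     n_states = 9L)
  r <- reduce_milestoning(dt_, list(1L, 9L))
  expect_equal(r$dtrajs$m1, c(1L, 1L, 1L, 2L, 2L, 2L, 1L))
  dt2 <- chain_dtraj(c(5L, 5L, 5L), stride = 100, n_states = 9L)
  r2 <- reduce_milestoning(dt2, list(1L, 9L))
  expect_true(all(is.na(r2$dtrajs$m1)))
  # frames before the first core visit stay null
  dt3 <- chain_dtraj(c(5L, 9L, 5L), stride = 100, n_states = 9L)
  expect_equal(reduce_milestoning(dt3, list(1L, 9L))$dtrajs$m1,
               c(NA, 2L, 2L))
  expect_error(reduce_milestoning(dt_, list(c(1L, 5L), 5L)), "disjoint")
})

test_that("source and sink sets follow the grid-distance rules", {
  g <- grid_spec(1, 20, "clamp")
  # the molecule visits grid points at 6 A (inside the 6.7 A MSM sink) and
  # 7 A (outside) on its way in
  d <- c(25, 18, 10, 7, 6, 4, 9, 21)
  tr <- gas_traj((seq_along(d) - 1) * 10, "m",
                 array(c(d, rep(0, 16)), c(8, 1, 3)), stride = 10)
  ev <- detect_events(tr)
  dt_ <- assign_states(tr, g)
  ss <- select_source_sink(dt_, ev, r_sink = 6.7, r_source = 22)
  sink_d <- sqrt(rowSums(state_to_grid(ss$sink, g)^2))
  expect_true(all(sink_d < 6.7))
  expect_true(grid_to_state(cbind(6, 0, 0), g) %in% ss$sink)
  expect_false(grid_to_state(cbind(7, 0, 0), g) %in% ss$sink)
  # the scripted entry has exactly one boundary state (25 -> clamped 20);
  # the exit boundary frame is at 21 -> state 20 too, deduplicated
  expect_equal(length(ss$source), 1L)
})

test_that("equilibrium MSM recovers the Boltzmann distribution", {
  fx <- equilibrium_fixture()
  tv <- tv_msm_vs_reference(fx$msm, fx$ref)
  expect_lt(tv, 0.05)
  # raw occupancy histogram agrees too
  counts <- table(unlist(fx$dtraj$dtrajs))
  h <- as.numeric(counts) / sum(counts)
  names(h) <- names(counts)
  all_states <- union(names(h), names(fx$ref))
  hv <- h[all_states]; hv[is.na(hv)] <- 0
  rv <- fx$ref[all_states]; rv[is.na(rv)] <- 0
  expect_lt(0.5 * sum(abs(hv - rv)), 0.05)
})

test_that("reduced milestoning MFPTs agree with the full-state model", {
  fx <- twowell_fixture()
  full <- msm_mfpt_shell(fx)
  red_dt <- reduce_milestoning(fx$dtraj, list(fx$sink, fx$source))
  red_msm <- estimate_msm(red_dt, lag = fx$msm$lag)
  red <- compute_mfpt(red_msm, B = 1L, A = 2L)
  expect_lt(abs(red$mfpt_ns - full$mfpt_ns) / full$mfpt_ns, 0.15)
})
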