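# Shared fixtures and independent oracles, built in code at test time.

# wrap a hand-written state sequence as a gas_dtraj
chain_dtraj <- function(..., stride = 100, n_states = NULL, grid = NULL) {
  seqs <- lapply(list(...), as.integer)
  names(seqs) <- paste0("m", seq_along(seqs))
  if (is.null(n_states)) n_states <- max(unlist(seqs), na.rm = TRUE)
  structure(list(dtrajs = seqs,
                 times = (seq_along(seqs[[1L]]) - 1L) * stride,
                 stride = stride, n_states = n_states, grid = grid),
            class = "gas_dtraj")
}

# build a gas_msm directly from a known transition matrix (uniform pi unless
# given); used to test spectral/kinetic code against closed forms
msm_from_matrix <- function(Tm, lag = 100, pi = NULL) {
  n <- nrow(Tm)
  if (is.null(pi)) {
    e <- eigen(t(Tm))
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    pi <- v / sum(v)
  }
  Ts <- methods::as(Matrix::Matrix(Tm, sparse = TRUE), "CsparseMatrix")
  structure(list(counts = Ts, T = Ts, active = seq_len(n), pi = pi,
                 lag = lag, stride = lag, scc = seq_len(n), n_pairs = 0L,
                 grid = NULL, estimator = "MLE"),
            class = "gas_msm")
}

# simulate an exact Markov chain (row-stochastic Tm), returning a state vector
simulate_chain <- function(Tm, n_steps, start = 1L) {
  n <- nrow(Tm)
  out <- integer(n_steps)
  s <- start
  cum <- t(apply(Tm, 1L, cumsum))
  u <- stats::runif(n_steps)
  for (t in seq_len(n_steps)) {
    s <- findInterval(u[t], cum[s, ]) + 1L
    out[t] <- s
  }
  out
}

# Monte-Carlo committor oracle: fraction of chains from each start state that
# reach B before A
mc_committor <- function(Tm, A, B, n_rep = 1000L) {
  n <- nrow(Tm)
  cum <- t(apply(Tm, 1L, cumsum))
  vapply(seq_len(n), function(s0) {
    if (s0 %in% A) return(0)
    if (s0 %in% B) return(1)
    hits <- 0L
    for (r in seq_len(n_rep)) {
      s <- s0
      repeat {
        s <- findInterval(stats::runif(1L), cum[s, ]) + 1L
        if (s %in% B) { hits <- hits + 1L; break }
        if (s %in% A) break
      }
    }
    hits / n_rep
  }, numeric(1L))
}

# shared two-well kinetics system: a 4 kT binding basin holding the gas at
# the catalytic zone (with real inward force at the 3 A absorbing radius, so
# the sampled chain resolves arrivals) plus a 3.5 kT cavity trap, between a
# 9 A source shell and the sink, in a 10 A reflecting box. Heavier products
# (long run, MSM, brute-force MFPT) are built once per session on demand.
twowell_system <- function() {
  synthetic_system(
    box_half_edge = 10,
    wells = list(well_spec(c(0, 0, 0), 6, 4, "site"),
                 well_spec(c(7, 0, 0), 2, 3.5, "trap")),
    sink_radius = 3)
}

.fixture_cache <- new.env(parent = emptyenv())

twowell_fixture <- function() {
  if (!is.null(.fixture_cache$twowell)) return(.fixture_cache$twowell)
  sys <- twowell_system()
  params <- brownian_params(D = 1, dt = 0.01, n_molecules = 100,
                            n_steps = 2e6, save_stride = 1, seed = 101L)
  traj <- simulate_brownian(sys, params)   # 100 x 20001 saved frames
  grid <- grid_spec(spacing = 1, half_edge = 10, wrap = "clamp")
  dtraj <- assign_states(traj, grid)
  msm <- estimate_msm(dtraj, lag = 1)
  dist <- sqrt(rowSums(state_to_grid(msm$active, grid)^2))
  sink <- msm$active[dist < sys$sink_radius]
  source_shell <- msm$active[abs(dist - 9) <= 0.5]
  bf <- brute_force_mfpt(sys, brownian_params(dt = 0.01, seed = 202L),
                         source_radius = 9, sink_radius = 3,
                         n_events = 10000L, outer = "box")
  .fixture_cache$twowell <- list(system = sys, traj = traj, grid = grid,
                                 dtraj = dtraj, msm = msm, sink = sink,
                                 source = source_shell, bf = bf)
  .fixture_cache$twowell
}

# equilibrium fixture: one 1 kT well in a box whose walls end on grid-cell
# boundaries (box_half_edge = grid half_edge + spacing/2), so every cell has
# equal volume and the Boltzmann point-weight reference is exact
equilibrium_fixture <- function() {
  if (!is.null(.fixture_cache$equil)) return(.fixture_cache$equil)
  sys <- synthetic_system(5.5, list(well_spec(c(2, 0, 0), 2, 1, "w1")),
                          sink_radius = 1)
  params <- brownian_params(D = 1, dt = 0.01, n_molecules = 100,
                            n_steps = 2e6, save_stride = 2, seed = 303L)
  traj <- simulate_brownian(sys, params)   # 100 x 10001 = 1.0e6 saved frames
  grid <- grid_spec(spacing = 1, half_edge = 5, wrap = "clamp")
  dtraj <- assign_states(traj, grid)
  msm <- estimate_msm(dtraj, lag = 2)
  ref <- boltzmann_reference(sys, grid)
  .fixture_cache$equil <- list(system = sys, traj = traj, grid = grid,
                               dtraj = dtraj, msm = msm, ref = ref)
  .fixture_cache$equil
}

tv_msm_vs_reference <- function(msm, ref) {
  p <- stats::setNames(msm$pi, msm$active)
  all_states <- union(names(ref), names(p))
  pv <- p[all_states]; pv[is.na(pv)] <- 0
  rv <- ref[all_states]; rv[is.na(rv)] <- 0
  0.5 * sum(abs(pv - rv))
}

msm_mfpt_shell <- function(fx) {
  w <- stats::setNames(rep(1, length(intersect(fx$source, fx$msm$active))),
                       intersect(fx$source, fx$msm$active))
  compute_mfpt(fx$msm, B = fx$sink, weights = w / sum(w))
}
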