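# Synthetic flooded-gas generator: non-interacting Brownian particles in a
# reflecting cube around the catalytic anchor, with smooth attractive wells
# standing in for the hydrophobic cavities that trap the gas in real proteins.

#' Define a cavity well
#'
#' Wells are smooth C1 radial ramps, `U(r) = -depth * (1 - 3t^2 + 2t^3)` with
#' `t = r/radius`, so the gradient exists everywhere and the Euler-Maruyama
#' integrator stays stable without rejection moves.
#'
#' @param center length-3 well center (Angstrom, anchor-relative).
#' @param radius well radius (Angstrom, > 0).
#' @param depth well depth in kT units (>= 0).
#' @param id unique well identifier (string).
#' @return a `gas_well`.
#' @export
well_spec <- function(center, radius, depth, id) {
  stopifnot(length(center) == 3L, radius > 0, depth >= 0)
  structure(list(center = as.numeric(center), radius = radius,
                 depth = depth, id = as.character(id)),
            class = "gas_well")
}

#' Define a synthetic system
#'
#' @param box_half_edge half-edge of the reflecting cubic box (Angstrom); the
#'   anchor sits at the origin.
#' @param wells list of [well_spec()] objects (unique ids).
#' @param sink_radius radius of the catalytic zone (Angstrom, smaller than
#'   the box half-edge).
#' @return a `gas_system`.
#' @export
synthetic_system <- function(box_half_edge, wells = list(), sink_radius = 6) {
  stopifnot(box_half_edge > 0, sink_radius < box_half_edge)
  ids <- vapply(wells, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("well ids must be unique")
  for (w in wells) {
    if (any(abs(w$center) > box_half_edge)) {
      stop("well '", w$id, "' center lies outside the box")
    }
  }
  structure(list(box_half_edge = box_half_edge, wells = wells,
                 sink_radius = sink_radius),
            class = "gas_system")
}

#' Brownian dynamics parameters
#'
#' @param D diffusion coefficient (Angstrom^2/ps).
#' @param dt integration timestep (ps).
#' @param n_molecules number of independent gas molecules.
#' @param n_steps number of integration steps.
#' @param save_stride saving interval (ps); must be an integer multiple of
#'   `dt`.
#' @param seed RNG seed.
#' @param kT thermal energy unit (1 by convention; well depths are in kT).
#' @return a `gas_bd_params`.
#' @export
brownian_params <- function(D = 1, dt = 0.01, n_molecules = 100,
                            n_steps = 10000L, save_stride = 10, seed = 1L,
                            kT = 1) {
  stopifnot(D > 0, dt > 0, n_molecules >= 1, n_steps >= 1)
  k <- save_stride / dt
  if (abs(k - round(k)) > 1e-8) {
    stop("save_stride must be an integer multiple of dt")
  }
  structure(list(D = D, dt = dt, n_molecules = as.integer(n_molecules),
                 n_steps = as.integer(n_steps), save_stride = save_stride,
                 seed = as.integer(seed), kT = kT),
            class = "gas_bd_params")
}

wells_matrix <- function(system, kT = 1) {
  if (length(system$wells) == 0L) {
    return(matrix(numeric(0), ncol = 5L))
  }
  t(vapply(system$wells, function(w) {
    c(w$center, w$radius, w$depth / kT)
  }, numeric(5L)))
}

check_stability <- function(system, params) {
  for (w in system$wells) {
    # max |dU/dr| = 1.5 * depth / radius at t = 1/2
    drift <- params$D * 1.5 * (w$depth / params$kT) / w$radius * params$dt
    if (drift > w$radius / 2) {
      stop("timestep too large for well '", w$id, "': max drift per step ",
           signif(drift, 3), " A exceeds radius/2")
    }
  }
  invisible(TRUE)
}

#' Evaluate the synthetic potential (kT units)
#'
#' @param points `n x 3` matrix of anchor-relative coordinates.
#' @param system a `gas_system`.
#' @return numeric vector of potential energies in kT.
#' @export
well_potential <- function(points, system) {
  points <- matrix(as.numeric(points), ncol = 3L)
  U <- numeric(nrow(points))
  for (w in system$wells) {
    d <- sqrt((points[, 1L] - w$center[1L])^2 +
                (points[, 2L] - w$center[2L])^2 +
                (points[, 3L] - w$center[3L])^2)
    t <- pmin(d / w$radius, 1)
    U <- U - w$depth * (1 - 3 * t^2 + 2 * t^3)
  }
  U
}

#' Simulate flooded-gas Brownian dynamics
#'
#' Overdamped Euler-Maruyama, `x <- x - D grad(U) dt + sqrt(2 D dt) xi`, with
#' reflecting walls at the box faces. Molecules do not interact. Output is
#' deterministic given `params$seed`.
#'
#' @param system a `gas_system`.
#' @param params a `gas_bd_params`.
#' @param start `"uniform"` (uniform in the box) or an `n_molecules x 3`
#'   matrix of initial positions.
#' @return a `gas_traj` (anchor at the origin).
#' @export
simulate_brownian <- function(system, params, start = "uniform") {
  stopifnot(inherits(system, "gas_system"), inherits(params, "gas_bd_params"))
  check_stability(system, params)
  set.seed(params$seed)
  nm <- params$n_molecules
  x0 <- if (is.matrix(start)) {
    stopifnot(nrow(start) == nm, ncol(start) == 3L)
    start
  } else {
    matrix(stats::runif(nm * 3L, -system$box_half_edge,
                        system$box_half_edge), ncol = 3L)
  }
  save_every <- as.integer(round(params$save_stride / params$dt))
  pos <- bd_simulate_cpp(x0, params$n_steps, params$dt, params$D,
                         system$box_half_edge,
                         wells_matrix(system, params$kT), save_every)
  n_saves <- dim(pos)[1L]
  gas_traj(times = (seq_len(n_saves) - 1L) * params$save_stride,
           ids = as.character(seq_len(nm)), rel = pos,
           stride = params$save_stride,
           provenance = list(superposed = FALSE, source = "simulate_brownian",
                             seed = params$seed))
}

#' Closed-form mean first-passage time in a spherical shell
#'
#' For free diffusion between an absorbing sphere of radius `a` and a
#' reflecting sphere of radius `b`, started at radius `r0`:
#' `tau = (b^3/(3 D)) (1/a - 1/r0) - (r0^2 - a^2)/(6 D)`.
#'
#' @param a absorbing radius (Angstrom).
#' @param b reflecting outer radius (Angstrom).
#' @param r0 starting radius (`a <= r0 <= b`).
#' @param D diffusion coefficient (Angstrom^2/ps).
#' @return MFPT in ps.
#' @export
shell_mfpt_theory <- function(a, b, r0 = b, D = 1) {
  stopifnot(a > 0, b > a, r0 >= a, r0 <= b)
  (b^3 / (3 * D)) * (1 / a - 1 / r0) - (r0^2 - a^2) / (6 * D)
}

#' Brute-force first-passage sampling
#'
#' Repeated independent Brownian runs started uniformly on the source shell
#' and absorbed at the sink sphere; the reference oracle for MSM-derived
#' MFPTs. A Brownian-bridge crossing test at the absorbing sphere removes the
#' leading timestep bias of naive endpoint detection.
#'
#' @param system a `gas_system` (its wells slow passage; its box half-edge is
#'   the outer reflecting boundary).
#' @param params a `gas_bd_params` (`n_molecules`/`n_steps` are ignored;
#'   `D`, `dt`, `seed`, `kT` are used).
#' @param source_radius starting shell radius (Angstrom).
#' @param sink_radius absorbing radius (Angstrom, < `source_radius`).
#' @param n_events number of independent first-passage samples.
#' @param outer reflecting outer boundary shape: `"sphere"` of radius
#'   `box_half_edge` or the reflecting `"box"` itself.
#' @param max_time per-event cap in ps (default generous: 2000 x the free
#'   diffusion shell MFPT); events hitting the cap are censored with a
#'   warning and excluded from the mean.
#' @param bridge_correction apply the Brownian-bridge crossing test.
#' @return list with `mean` (ps), `se`, `n`, `censored`, `times`.
#' @export
brute_force_mfpt <- function(system, params, source_radius, sink_radius,
                             n_events = 1000L, outer = c("sphere", "box"),
                             max_time = NULL, bridge_correction = TRUE) {
  outer <- match.arg(outer)
  b <- system$box_half_edge
  stopifnot(sink_radius <= source_radius, source_radius <= b)
  if (sink_radius == source_radius) {
    return(list(mean = 0, se = 0, n = n_events, censored = 0L,
                times = rep(0, n_events)))
  }
  check_stability(system, params)
  if (is.null(max_time)) {
    max_time <- 2000 * shell_mfpt_theory(sink_radius, b, source_radius,
                                         params$D)
  }
  set.seed(params$seed)
  res <- bd_first_passage_cpp(as.integer(n_events), source_radius,
                              sink_radius, params$D, params$dt,
                              if (outer == "sphere") 0L else 1L, b,
                              wells_matrix(system, params$kT),
                              max_time / params$dt, bridge_correction)
  times <- res$times[!is.na(res$times)]
  if (res$censored > 0L) {
    warning(res$censored, " of ", n_events,
            " first-passage runs hit the step cap and were censored")
  }
  list(mean = mean(times), se = stats::sd(times) / sqrt(length(times)),
       n = length(times), censored = res$censored, times = times)
}

#' Boltzmann equilibrium reference on a grid
#'
#' Per-state weights proportional to `exp(-U/kT)` at the grid-point centers,
#' normalized to 1 over in-box states. The analytic oracle for MSM stationary
#' distributions on equilibrium runs.
#'
#' @param system a `gas_system`.
#' @param grid a [grid_spec()] covering the box.
#' @param kT thermal energy unit.
#' @return named numeric vector of weights; names are grid state ids.
#' @export
boltzmann_reference <- function(system, grid, kT = 1) {
  pts <- grid_points(grid)
  inside <- abs(pts$x) <= system$box_half_edge &
    abs(pts$y) <= system$box_half_edge &
    abs(pts$z) <= system$box_half_edge
  pts <- pts[inside, , drop = FALSE]
  U <- well_potential(as.matrix(pts[, c("x", "y", "z")]), system) / kT
  w <- exp(-(U - min(U)))
  w <- w / sum(w)
  stats::setNames(w, pts$state)
}

#' Build a trajectory that passes exactly through waypoints
#'
#' Linear interpolation between waypoints at `save_stride`; positions are held
#' constant outside a molecule's waypoint range. The hand-checkable fixture
#' generator for event-tracing oracles.
#'
#' @param waypoints data.frame with columns `time` (ps), `id`, `x`, `y`, `z`
#'   (anchor-relative Angstrom), time-ordered within each molecule.
#' @param save_stride output frame spacing (ps).
#' @return a `gas_traj`.
#' @export
scripted_fixture <- function(waypoints, save_stride = 10) {
  need <- c("time", "id", "x", "y", "z")
  stopifnot(all(need %in% names(waypoints)))
  waypoints$id <- as.character(waypoints$id)
  if (anyDuplicated(waypoints[, c("time", "id")])) {
    stop("duplicate (time, id) waypoint")
  }
  t0 <- min(waypoints$time)
  t1 <- max(waypoints$time)
  times <- seq(t0, t1, by = save_stride)
  if (length(times) < 2L) stop("waypoints must span at least 2 frames")
  ids <- unique(waypoints$id)
  rel <- array(NA_real_, dim = c(length(times), length(ids), 3L))
  for (m in seq_along(ids)) {
    wp <- waypoints[waypoints$id == ids[m], , drop = FALSE]
    wp <- wp[order(wp$time), , drop = FALSE]
    for (k in 1:3) {
      v <- wp[[c("x", "y", "z")[k]]]
      rel[, m, k] <- if (nrow(wp) == 1L) v else
        stats::approx(wp$time, v, xout = times, rule = 2)$y
    }
  }
  gas_traj(times, ids, rel, stride = save_stride,
           provenance = list(superposed = FALSE, source = "scripted_fixture"))
}

#' Derive the pseudo-residue environment of a synthetic system
#'
#' Places single-atom pseudo-residues on lattice points of each well surface,
#' labeled by well id, so residue-contact classification has unambiguous
#' ground truth: a molecule inside a well of radius `<= contact cutoff` is
#' always within the cutoff of some lining atom. One region per well is
#' defined, containing its lining residues.
#'
#' @param system a `gas_system`.
#' @param n_points number of surface points per well (placed by a Fibonacci
#'   sphere lattice).
#' @return a `gas_env`.
#' @export
environment_from_system <- function(system, n_points = 26L) {
  if (length(system$wells) == 0L) {
    return(environment_model(data.frame(residue_id = character(),
                                        label = character(), x = numeric(),
                                        y = numeric(), z = numeric())))
  }
  dirs <- fibonacci_sphere(n_points)
  atoms <- do.call(rbind, lapply(system$wells, function(w) {
    p <- dirs * w$radius
    data.frame(residue_id = paste0(w$id, ".", seq_len(n_points)),
               label = w$id,
               x = p[, 1L] + w$center[1L],
               y = p[, 2L] + w$center[2L],
               z = p[, 3L] + w$center[3L],
               stringsAsFactors = FALSE)
  }))
  regions <- lapply(system$wells, function(w) {
    paste0(w$id, ".", seq_len(n_points))
  })
  names(regions) <- vapply(system$wells, `[[`, "", "id")
  environment_model(atoms, regions)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
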