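# Grid discretization of anchor-relative gas positions and Markov state model
# estimation: sliding-window transition counts, row-normalized maximum
# likelihood, implied timescales, Chapman-Kolmogorov validation, Bayesian
# posterior sampling, and milestoning core-set reduction.

#' Cubic grid state space
#'
#' A cube of side `2 * half_edge` centered on the anchor, with one state per
#' grid point at `spacing` resolution. In `"periodic"` wrap mode out-of-cube
#' positions are mapped by minimum image with period `2 * half_edge`, which
#' identifies the `+half_edge` plane with `-half_edge` and gives exactly
#' `(2 half_edge / spacing)^3` states (the default 1 A / 40 A cube enumerates
#' 64,000). `"clamp"` mode instead pins outside positions to the nearest
#' face and keeps the `+half_edge` plane as distinct states.
#'
#' @param spacing grid spacing (Angstrom; default 1).
#' @param half_edge half-edge of the cube (Angstrom; default 20).
#' @param wrap `"periodic"` or `"clamp"`.
#' @return a `grid_spec`.
#' @export
grid_spec <- function(spacing = 1, half_edge = 20,
                      wrap = c("periodic", "clamp")) {
  wrap <- match.arg(wrap)
  if (spacing <= 0) stop("grid spacing must be positive")
  h <- half_edge / spacing
  if (abs(h - round(h)) > 1e-9) {
    stop("half_edge must be an integer multiple of spacing")
  }
  h <- as.integer(round(h))
  side <- if (wrap == "periodic") 2L * h else 2L * h + 1L
  structure(list(spacing = spacing, half_edge = half_edge, wrap = wrap,
                 h = h, side = side),
            class = "grid_spec")
}

#' Number of states in a grid
#' @param grid a `grid_spec`.
#' @export
n_grid_states <- function(grid) as.numeric(grid$side)^3

#' Map integer grid indices to linear state ids
#'
#' @param idx `n x 3` integer matrix of grid indices (units of `spacing`),
#'   already wrapped/clamped into range.
#' @param grid a `grid_spec`.
#' @return integer state ids in `1..n_grid_states(grid)`; bijective over
#'   in-range indices.
#' @export
grid_to_state <- function(idx, grid) {
  idx <- matrix(as.integer(idx), ncol = 3L)
  off <- idx + grid$h
  as.integer(off[, 1L] * grid$side^2 + off[, 2L] * grid$side + off[, 3L] + 1L)
}

#' Map state ids back to grid-point coordinates (Angstrom)
#'
#' @param states integer state ids.
#' @param grid a `grid_spec`.
#' @return `n x 3` matrix of grid-point coordinates.
#' @export
state_to_grid <- function(states, grid) {
  v <- as.integer(states) - 1L
  iz <- v %% grid$side
  v <- v %/% grid$side
  iy <- v %% grid$side
  ix <- v %/% grid$side
  cbind(ix - grid$h, iy - grid$h, iz - grid$h) * grid$spacing
}

grid_points <- function(grid) {
  rng <- if (grid$wrap == "periodic") seq(-grid$h, grid$h - 1L) else
    seq(-grid$h, grid$h)
  pts <- expand.grid(z = rng, y = rng, x = rng)[, 3:1] * grid$spacing
  data.frame(state = grid_to_state(as.matrix(round(pts / grid$spacing)), grid),
             x = pts$x, y = pts$y, z = pts$z)
}

wrap_indices <- function(i, grid) {
  if (grid$wrap == "periodic") {
    ((i + grid$h) %% (2L * grid$h)) - grid$h
  } else {
    pmin(pmax(i, -grid$h), grid$h)
  }
}

#' Discretize a trajectory onto the grid
#'
#' Positions are rounded to the nearest grid point and mapped per the grid's
#' wrap mode. If `stride` exceeds the trajectory stride the trajectory is
#' decimated first (frames at multiples of `stride`).
#'
#' @param traj a `gas_traj` in anchor-relative coordinates.
#' @param grid a `grid_spec`.
#' @param stride target stride (ps); default the trajectory stride.
#' @return a `gas_dtraj`: integer state sequences per molecule (`NA` marks
#'   null frames), plus `times`, `stride`, `n_states`, `grid`.
#' @export
assign_states <- function(traj, grid, stride = NULL) {
  stopifnot(inherits(traj, "gas_traj"), inherits(grid, "grid_spec"))
  keep <- seq_len(n_frames(traj))
  if (!is.null(stride) && stride != traj$stride) {
    k <- stride / traj$stride
    if (abs(k - round(k)) > 1e-8 || k < 1) {
      stop("stride must be an integer multiple of the trajectory stride")
    }
    keep <- seq(1L, n_frames(traj), by = as.integer(round(k)))
  } else {
    stride <- traj$stride
  }
  dtrajs <- lapply(seq_along(traj$ids), function(m) {
    xyz <- matrix(traj$rel[keep, m, ], ncol = 3L)
    i <- wrap_indices(round(xyz / grid$spacing), grid)
    grid_to_state(i, grid)
  })
  names(dtrajs) <- traj$ids
  structure(list(dtrajs = dtrajs, times = traj$times[keep], stride = stride,
                 n_states = n_grid_states(grid), grid = grid),
            class = "gas_dtraj")
}

#' Keep only frames inside traced event spans
#'
#' Frames of each molecule outside the union of its events' traced spans are
#' set to the null state (`NA`); censored span ends fall back to the
#' available boundary.
#'
#' @param dtraj a `gas_dtraj`.
#' @param events a `gas_events` table sharing molecule ids and time base.
#' @return a `gas_dtraj` with nulls outside events.
#' @export
restrict_to_events <- function(dtraj, events) {
  stopifnot(inherits(dtraj, "gas_dtraj"))
  out <- dtraj
  for (m in names(dtraj$dtrajs)) {
    ev <- events[events$molecule_id == m, , drop = FALSE]
    keep <- rep(FALSE, length(dtraj$times))
    if (nrow(ev)) {
      lo <- pmin(ev$t_outer, ev$t_inner, na.rm = TRUE)
      hi <- pmax(ev$t_outer, ev$t_inner, na.rm = TRUE)
      for (k in seq_len(nrow(ev))) {
        keep <- keep | (dtraj$times >= lo[k] & dtraj$times <= hi[k])
      }
    }
    v <- dtraj$dtrajs[[m]]
    v[!keep] <- NA_integer_
    out$dtrajs[[m]] <- v
  }
  out
}

lagged_pairs <- function(dtraj, lag) {
  L <- lag / dtraj$stride
  if (abs(L - round(L)) > 1e-8 || L < 1) {
    stop("lag must be a positive integer multiple of the stride")
  }
  L <- as.integer(round(L))
  ii <- integer(0); jj <- integer(0)
  for (v in dtraj$dtrajs) {
    n <- length(v)
    if (n <= L) next
    a <- v[seq_len(n - L)]
    b <- v[seq_len(n - L) + L]
    ok <- !is.na(a) & !is.na(b)
    ii <- c(ii, a[ok]); jj <- c(jj, b[ok])
  }
  list(i = ii, j = jj, L = L)
}

#' Estimate a maximum-likelihood Markov state model
#'
#' Sliding-window transition counts at lag `lag` (a pair is counted when both
#' endpoints are non-null). States never visited or left without outgoing
#' transitions are excluded (iterating until every remaining row has
#' positive count). The MLE is the row-normalized count matrix; the
#' stationary distribution is the leading left eigenvector on the largest
#' strongly connected component, zero elsewhere, renormalized.
#'
#' @param dtraj a `gas_dtraj`.
#' @param lag lag time (ps), an integer multiple of the stride.
#' @return a `gas_msm`: sparse `counts` and `T` over the `active` state ids,
#'   `pi`, `lag`, `stride`, `scc` (active-set indices of the connected
#'   component), `n_pairs`, `grid`, `estimator`.
#' @export
estimate_msm <- function(dtraj, lag) {
  stopifnot(inherits(dtraj, "gas_dtraj"))
  pr <- lagged_pairs(dtraj, lag)
  if (length(pr$i) == 0L) stop("no lagged transitions observed; cannot estimate")
  states <- sort(unique(c(pr$i, pr$j)))
  i0 <- match(pr$i, states)
  j0 <- match(pr$j, states)
  # iterate the active-set restriction on the pair lists (cheap) before
  # building the matrix: drop states with no outgoing transition, repeat
  keep <- rep(TRUE, length(states))
  repeat {
    ok <- keep[i0] & keep[j0]
    outdeg <- tabulate(i0[ok], nbins = length(states))
    visited <- logical(length(states))
    visited[unique(c(i0[ok], j0[ok]))] <- TRUE
    keep2 <- keep & visited & outdeg > 0
    if (!any(keep2)) stop("count matrix empty after active-set restriction")
    if (identical(keep2, keep)) break
    keep <- keep2
  }
  ok <- keep[i0] & keep[j0]
  active <- states[keep]
  remap <- cumsum(keep)
  C <- Matrix::sparseMatrix(i = remap[i0[ok]], j = remap[j0[ok]], x = 1,
                            dims = c(length(active), length(active)))
  Tm <- C / Matrix::rowSums(C)
  Tm <- methods::as(Tm, "CsparseMatrix")
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  big <- which.max(tabulate(comp$membership))
  scc <- which(comp$membership == big)
  pi_full <- numeric(length(active))
  pi_full[scc] <- stationary_scc(Tm, scc)
  pi_full <- pi_full / sum(pi_full)
  structure(list(counts = C, T = Tm, active = active, pi = pi_full,
                 lag = lag, stride = dtraj$stride, scc = scc,
                 n_pairs = sum(ok), n_pairs_raw = length(pr$i),
                 grid = dtraj$grid, estimator = "MLE"),
            class = "gas_msm")
}

stationary_scc <- function(Tm, scc) {
  Ts <- Tm[scc, scc, drop = FALSE]
  rs <- Matrix::rowSums(Ts)
  Ts <- Ts / rs  # renormalize away outflow that leaves the component
  n <- length(scc)
  if (n == 1L) return(1)
  if (n <= 2000L) {
    # small systems: exact solve of pi (T - I) = 0 with sum(pi) = 1
    M <- Matrix::t(Ts) - Matrix::Diagonal(n)
    M[n, ] <- 1
    b <- c(rep(0, n - 1L), 1)
    p <- tryCatch(as.numeric(Matrix::solve(M, b)), error = function(e) NULL)
    if (!is.null(p) && all(is.finite(p)) && min(p) > -1e-8) {
      p[p < 0] <- 0
      return(p / sum(p))
    }
  }
  # large (or ill-conditioned) systems: power iteration; sparse LU fill-in on
  # grid-shaped chains is far more expensive than repeated matvecs
  p <- rep(1 / n, n)
  for (it in seq_len(200000L)) {
    p2 <- as.numeric(p %*% Ts)
    p2 <- p2 / sum(p2)
    delta <- sum(abs(p2 - p))
    p <- p2
    if (delta < 1e-13) break
  }
  p[p < 0] <- 0
  p / sum(p)
}

#' @export
print.gas_msm <- function(x, ...) {
  cat(sprintf(
    "gas_msm (%s): %d active states (%d in the connected set), lag %g ps, %d counted pairs\n",
    x$estimator, length(x$active), length(x$scc), x$lag, x$n_pairs))
  invisible(x)
}

msm_eigenvalues <- function(model, n_ev = 5L) {
  Ts <- model$T[model$scc, model$scc, drop = FALSE]
  Ts <- Ts / Matrix::rowSums(Ts)
  n <- nrow(Ts)
  n_ev <- min(n_ev, n)
  if (n <= 600L) {
    ev <- eigen(as.matrix(Ts), only.values = TRUE)$values
    return(ev[order(-Mod(ev))][seq_len(n_ev)])
  }
  # large components: a few leading eigenvalues via ARPACK (sparse matvecs)
  ar <- igraph::arpack(function(x, extra) as.numeric(Ts %*% x),
                       options = list(n = n, nev = n_ev,
                                      ncv = min(n, max(4L * n_ev + 5L, 25L)),
                                      which = "LM", maxiter = 5000L),
                       sym = FALSE, complex = TRUE)
  ev <- ar$values
  ev[order(-Mod(ev))][seq_len(min(n_ev, length(ev)))]
}

#' Implied timescales of a single model
#'
#' `t_k = -lag / log |lambda_k|` for the leading nontrivial eigenvalues;
#' eigenvalues at modulus 1 (within 1e-12) report as `Inf` (divergent).
#'
#' @param model a `gas_msm`.
#' @param n_its number of timescales.
#' @return data.frame (`k`, `eigenvalue_mod`, `its_ps`, `complex`).
#' @export
implied_timescales_model <- function(model, n_its = 5L) {
  ev <- msm_eigenvalues(model, n_its + 1L)
  ev <- ev[-1L]  # drop the stationary eigenvalue
  m <- Mod(ev)
  its <- ifelse(m >= 1 - 1e-12, Inf, -model$lag / log(m))
  data.frame(k = seq_along(ev) + 1L, eigenvalue_mod = m, its_ps = its,
             complex = abs(Im(ev)) > 1e-8)
}

#' Implied-timescale scan over lag times
#'
#' @param dtraj a `gas_dtraj`.
#' @param lags lag times (ps).
#' @param n_its number of timescales per lag.
#' @return data.frame (`lag`, `k`, `its_ps`, `eigenvalue_mod`, `complex`).
#' @export
implied_timescales <- function(dtraj, lags, n_its = 5L) {
  stopifnot(length(lags) >= 1L)
  out <- lapply(lags, function(l) {
    m <- estimate_msm(dtraj, l)
    its <- implied_timescales_model(m, n_its)
    its$lag <- l
    its
  })
  do.call(rbind, out)[, c("lag", "k", "its_ps", "eigenvalue_mod", "complex")]
}

#' Sample the Bayesian posterior over transition matrices
#'
#' Conjugate per-row Dirichlet sampling with a uniform prior pseudo-count of
#' `1/N` per element (`N` the number of active states), given the observed
#' counts.
#'
#' @param model a `gas_msm` (its count matrix is used).
#' @param n_samples number of posterior draws.
#' @param seed RNG seed.
#' @return object of class `gas_msm_samples`: list of dense transition
#'   matrices plus `active`, `lag`.
#' @export
sample_bayesian <- function(model, n_samples = 100L, seed = 1L) {
  stopifnot(inherits(model, "gas_msm"))
  n <- length(model$active)
  if (n > 2000L) {
    stop("Bayesian sampling is intended for reduced models (", n,
         " states); reduce with reduce_milestoning() first")
  }
  set.seed(seed)
  Cd <- as.matrix(model$counts) + 1 / n
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    G <- matrix(stats::rgamma(n * n, shape = Cd), n, n)
    samples[[s]] <- G / rowSums(G)
  }
  structure(list(T_samples = samples, active = model$active,
                 lag = model$lag, prior_weight = 1 / n),
            class = "gas_msm_samples")
}

#' Credible interval of a transition-matrix functional
#'
#' @param samples a `gas_msm_samples`.
#' @param f function of a dense transition matrix returning a scalar.
#' @param conf credible level (default 0.95).
#' @return list `mean`, `lo`, `hi`, `values`.
#' @export
bayesian_ci <- function(samples, f, conf = 0.95) {
  v <- vapply(samples$T_samples, f, numeric(1L))
  a <- (1 - conf) / 2
  q <- stats::quantile(v, c(a, 1 - a), names = FALSE)
  list(mean = mean(v), lo = q[1L], hi = q[2L], values = v)
}

#' Chapman-Kolmogorov test
#'
#' Compares the model prediction `w' T(lag)^k 1_set` (probability of being in
#' a metastable set after `k` lags, started from the stationary distribution
#' restricted to the set) against the same quantity under a model estimated
#' directly at lag `k * lag`, with Bayesian sampling credible intervals on
#' the latter.
#'
#' @param dtraj a `gas_dtraj`.
#' @param lag base lag (ps).
#' @param sets list of state-id vectors (metastable sets).
#' @param ks multiples of the base lag to test (default `1:5`).
#' @param n_samples Bayesian draws per lag.
#' @param seed RNG seed.
#' @param conf credible level.
#' @return data.frame of class `gas_ck` (`set`, `k`, `predicted`,
#'   `estimated`, `lo`, `hi`, `pass`).
#' @export
ck_test <- function(dtraj, lag, sets, ks = 1:5, n_samples = 100L, seed = 1L,
                    conf = 0.95) {
  base <- estimate_msm(dtraj, lag)
  rows <- list()
  for (k in ks) {
    est_model <- estimate_msm(dtraj, k * lag)
    smp <- sample_bayesian(est_model, n_samples, seed = seed + k)
    for (s in seq_along(sets)) {
      set_states <- sets[[s]]
      p_pred <- set_stay_probability(base, set_states, k)
      f <- function(Tm) set_stay_probability_matrix(
        Tm, est_model$active, est_model$pi, set_states, 1L)
      p_est <- f(as.matrix(est_model$T))
      ci <- bayesian_ci(smp, f, conf)
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, k = k, predicted = p_pred, estimated = p_est,
        lo = ci$lo, hi = ci$hi,
        pass = p_pred >= ci$lo & p_pred <= ci$hi)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gas_ck", "data.frame")
  out
}

set_stay_probability <- function(model, set_states, k) {
  set_stay_probability_matrix(model$T, model$active, model$pi, set_states, k)
}

set_stay_probability_matrix <- function(Tm, active, pi, set_states, k) {
  idx <- match(intersect(set_states, active), active)
  if (length(idx) == 0L) return(NA_real_)
  w <- numeric(length(active))
  w[idx] <- pi[idx]
  if (sum(w) <= 0) w[idx] <- 1
  w <- w / sum(w)
  for (step in seq_len(k)) w <- as.numeric(w %*% Tm)
  sum(w[idx])
}

#' Milestoning reduction onto core sets
#'
#' Relabels every frame with the most recently visited core; intermediate and
#' null frames inherit the last core, and frames before any core visit stay
#' null. The standard coarse-graining that makes Bayesian sampling and CK
#' testing affordable on grid models.
#'
#' @param dtraj a `gas_dtraj`.
#' @param core_sets list of disjoint state-id vectors.
#' @return a `gas_dtraj` over core indices (`n_states = length(core_sets)`).
#' @export
reduce_milestoning <- function(dtraj, core_sets) {
  stopifnot(inherits(dtraj, "gas_dtraj"), length(core_sets) >= 1L)
  all_states <- unlist(core_sets)
  if (anyDuplicated(all_states)) stop("core sets must be disjoint")
  lookup <- function(v) {
    m <- rep(NA_integer_, length(v))
    for (k in seq_along(core_sets)) {
      m[v %in% core_sets[[k]]] <- k
    }
    m
  }
  out <- dtraj
  out$dtrajs <- lapply(dtraj$dtrajs, function(v) {
    lab <- lookup(v)
    hit <- which(!is.na(lab))
    if (length(hit) == 0L) return(rep(NA_integer_, length(v)))
    pos <- findInterval(seq_along(lab), hit)
    res <- rep(NA_integer_, length(lab))
    res[pos > 0L] <- lab[hit[pmax(pos, 1L)]][pos > 0L]
    res
  })
  out$n_states <- length(core_sets)
  out$grid <- NULL
  out$core_sets <- core_sets
  out
}

#' Select TPT source and sink state sets
#'
#' The sink is every visited state whose grid point lies within `r_sink` of
#' the anchor; the source is the set of states occupied at event boundary
#' frames (the outer-shell frame each traced event starts or ends on).
#'
#' @param dtraj a grid-based `gas_dtraj`.
#' @param events a `gas_events` table.
#' @param r_sink sink radius (Angstrom; default 6.7).
#' @param r_source nominal source radius (Angstrom; default 22) — recorded,
#'   the source states themselves come from the event boundary frames.
#' @return list with `source`, `sink` (state-id vectors), `r_sink`,
#'   `r_source`.
#' @export
select_source_sink <- function(dtraj, events, r_sink = 6.7, r_source = 22) {
  stopifnot(inherits(dtraj, "gas_dtraj"), !is.null(dtraj$grid))
  visited <- sort(unique(unlist(lapply(dtraj$dtrajs, function(v)
    v[!is.na(v)]))))
  d <- sqrt(rowSums(state_to_grid(visited, dtraj$grid)^2))
  sink <- visited[d < r_sink]
  src <- integer(0)
  for (r in seq_len(nrow(events))) {
    tb <- events$t_outer[r]
    if (is.na(tb)) next
    f <- which.min(abs(dtraj$times - tb))
    m <- match(events$molecule_id[r], names(dtraj$dtrajs))
    s <- dtraj$dtrajs[[m]][f]
    if (!is.na(s)) src <- c(src, s)
  }
  src <- sort(setdiff(unique(src), sink))
  if (length(src) == 0L) stop("empty source set: no usable event boundary frames")
  if (length(sink) == 0L) stop("empty sink set: no visited states within r_sink")
  list(source = src, sink = sink, r_sink = r_sink, r_source = r_source)
}

#' Write a sparse matrix in coordinate text format
#'
#' @param model a `gas_msm`.
#' @param path_prefix files `<prefix>_counts.txt`, `<prefix>_T.txt`,
#'   `<prefix>_states.txt` are written (state table: id, grid x/y/z,
#'   distance to anchor, stationary probability).
#' @export
write_msm <- function(model, path_prefix) {
  dump_coo <- function(M, path, what) {
    co <- methods::as(M, "TsparseMatrix")
    tab <- data.frame(state_i = model$active[co@i + 1L],
                      state_j = model$active[co@j + 1L], value = co@x)
    writeLines(sprintf("# gasport %s; lag=%g ps", what, model$lag), path)
    suppressWarnings(utils::write.table(tab, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  dump_coo(model$counts, paste0(path_prefix, "_counts.txt"), "counts")
  dump_coo(model$T, paste0(path_prefix, "_T.txt"), "transition matrix")
  st <- paste0(path_prefix, "_states.txt")
  if (!is.null(model$grid)) {
    xyz <- state_to_grid(model$active, model$grid)
    tab <- data.frame(state = model$active, x = xyz[, 1L], y = xyz[, 2L],
                      z = xyz[, 3L], dist = sqrt(rowSums(xyz^2)),
                      pi = model$pi)
  } else {
    tab <- data.frame(state = model$active, pi = model$pi)
  }
  writeLines(sprintf("# gasport state table; lag=%g ps", model$lag), st)
  suppressWarnings(utils::write.table(tab, st, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path_prefix)
}
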