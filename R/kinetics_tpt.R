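# Transition path theory on an estimated MSM: committors, reactive flux,
# rates, and mean first-passage times between source and sink state sets.

map_states <- function(model, states, what) {
  idx <- match(states, model$active)
  if (anyNA(idx)) {
    miss <- states[is.na(idx)]
    warning(length(miss), " ", what, " state(s) not in the active set; dropped")
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0L) stop(what, " set is empty within the active set")
  sort(unique(idx))
}

reachable_to <- function(Tm, targets) {
  # states from which any of `targets` is reachable: multi-source backward
  # BFS by boolean sparse matvec (one pass per graph-diameter level)
  A <- Tm > 0
  r <- rep(FALSE, nrow(Tm))
  r[targets] <- TRUE
  repeat {
    r2 <- r | as.logical(A %*% r > 0)
    if (identical(r2, r)) break
    r <- r2
  }
  r
}

# solve (I - M) x = b by direct sparse LU for small systems or damped fixed
# point iteration x <- M x + b for large ones (M strictly substochastic on
# the solved block, so the iteration is a contraction)
solve_substochastic <- function(M, b, tol = 1e-10, max_iter = 500000L) {
  n <- nrow(M)
  if (n <= 2000L) {
    return(as.numeric(Matrix::solve(Matrix::Diagonal(n) - M, b)))
  }
  x <- b
  for (it in seq_len(max_iter)) {
    x2 <- as.numeric(M %*% x) + b
    delta <- max(abs(x2 - x))
    scale <- max(abs(x2), 1)
    x <- x2
    if (delta < tol * scale) break
  }
  x
}

#' Forward and backward committors
#'
#' The forward committor solves the discrete committor linear system
#' `q+ = 0` on A, `q+ = 1` on B, `(I - T) q+ = 0` elsewhere; the backward
#' committor is the forward committor of the time-reversed chain
#' `T~_ij = pi_j T_ji / pi_i` with the roles of A and B swapped. Intermediate
#' states from which neither A nor B is reachable make the system singular;
#' they are reported and dropped (committor `NA`).
#'
#' @param model a `gas_msm`.
#' @param A source state ids (disjoint from `B`).
#' @param B sink state ids.
#' @return list with `q_plus`, `q_minus` (named by state id), `A`, `B`
#'   (active-set indices).
#' @export
compute_committors <- function(model, A, B) {
  iA <- map_states(model, A, "source")
  iB <- map_states(model, B, "sink")
  if (length(intersect(iA, iB))) stop("source and sink sets must be disjoint")
  n <- length(model$active)
  Tm <- model$T
  q_plus <- committor_system(Tm, iA, iB)
  # reversed chain needs pi > 0; states outside the connected set get NA
  pi <- model$pi
  pos <- pi > 0
  q_minus <- rep(NA_real_, n)
  if (any(pos)) {
    # T~_ij = pi_j T_ji / pi_i; rows with pi_i = 0 are zeroed and end up
    # dropped as unreachable by the committor solver
    Trev <- Matrix::Diagonal(x = ifelse(pos, 1 / pi, 0)) %*%
      Matrix::t(Tm) %*% Matrix::Diagonal(x = pi)
    rs <- Matrix::rowSums(Trev)
    Trev <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% Trev
    q_minus <- committor_system(methods::as(Trev, "CsparseMatrix"), iB, iA)
  }
  names(q_plus) <- names(q_minus) <- model$active
  list(q_plus = q_plus, q_minus = q_minus, A = iA, B = iB)
}

committor_system <- function(Tm, iA, iB) {
  n <- nrow(Tm)
  q <- rep(NA_real_, n)
  q[iA] <- 0
  q[iB] <- 1
  iI <- setdiff(seq_len(n), c(iA, iB))
  if (length(iI) == 0L) return(q)
  ok <- reachable_to(Tm, c(iA, iB))
  dropped <- iI[!ok[iI]]
  if (length(dropped)) {
    warning(length(dropped),
            " intermediate state(s) cannot reach source or sink; dropped")
    iI <- iI[ok[iI]]
    if (length(iI) == 0L) return(q)
  }
  rhs <- Matrix::rowSums(Tm[iI, iB, drop = FALSE])
  q[iI] <- solve_substochastic(Tm[iI, iI, drop = FALSE], rhs)
  q
}

#' Mean first-passage time to a sink set
#'
#' Solves `m_i = lag + sum_j T_ij m_j` with `m = 0` on B; the headline MFPT
#' is the stationary-weighted average of `m` over the source set (or
#' explicit weights). States that cannot reach B have infinite passage time;
#' if any source state is among them the MFPT is reported as `Inf`.
#'
#' @param model a `gas_msm`.
#' @param B sink state ids.
#' @param A source state ids (used with stationary weights), or `NULL` when
#'   `weights` is given.
#' @param weights optional named vector of source weights (names are state
#'   ids); overrides the stationary weighting.
#' @return list with `mfpt_ns`, `per_state_ns` (named), `weights_used`.
#' @export
compute_mfpt <- function(model, B, A = NULL, weights = NULL) {
  iB <- map_states(model, B, "sink")
  n <- length(model$active)
  m <- rep(NA_real_, n)
  m[iB] <- 0
  iC <- setdiff(seq_len(n), iB)
  if (length(iC)) {
    can <- reachable_to(model$T, iB)
    m[iC[!can[iC]]] <- Inf
    iS <- iC[can[iC]]
    if (length(iS)) {
      # unreachable states absorb probability mass in the solve; remove them
      m[iS] <- solve_substochastic(model$T[iS, iS, drop = FALSE],
                                   rep(model$lag, length(iS)))
    }
  }
  names(m) <- model$active
  if (is.null(weights)) {
    if (is.null(A)) stop("give either A or weights")
    iA <- map_states(model, A, "source")
    w <- model$pi[iA]
    if (sum(w) <= 0) w <- rep(1, length(iA))
    w <- w / sum(w)
    wa <- stats::setNames(w, model$active[iA])
  } else {
    idx <- match(as.integer(names(weights)), model$active)
    if (anyNA(idx)) stop("weight names must be active state ids")
    wa <- stats::setNames(as.numeric(weights) / sum(weights),
                          names(weights))
    iA <- idx
  }
  mf <- sum(wa * m[names(wa)]) / 1000  # ps -> ns
  list(mfpt_ns = mf, per_state_ns = m / 1000, weights_used = wa,
       lag = model$lag)
}

#' Reactive flux and TPT rate
#'
#' Computes the reactive flux `f_ij = pi_i q-_i T_ij q+_j` (i != j), the
#' total flux out of the source `F = sum_{i in A, j} f_ij`, and the rate
#' `k = F / (lag * sum_i pi_i q-_i)`. The reciprocal `1/k` is returned as a
#' companion diagnostic next to the linear-system MFPT; the two are close
#' but not identical by construction.
#'
#' @param model a `gas_msm`.
#' @param A source state ids.
#' @param B sink state ids.
#' @return object of class `gas_tpt` with `committors`, `flux` (sparse),
#'   `net_flux`, `total_flux`, `rate_per_ps`, `mfpt_tpt_ns`, `mfpt_ns`
#'   (linear system), `top_states`.
#' @export
compute_tpt_rate <- function(model, A, B) {
  com <- compute_committors(model, A, B)
  qp <- com$q_plus; qm <- com$q_minus
  qp[is.na(qp)] <- 0; qm[is.na(qm)] <- 0
  pi <- model$pi
  Fm <- model$T * (pi * qm)
  Fm <- Matrix::t(Matrix::t(Fm) * qp)
  Matrix::diag(Fm) <- 0
  total_flux <- sum(Fm[com$A, , drop = FALSE])
  denom <- model$lag * sum(pi * qm)
  rate <- if (denom > 0) total_flux / denom else 0
  if (total_flux <= 0) {
    warning("zero reactive flux: sink unreachable from source")
  }
  net <- Fm - Matrix::t(Fm)
  net@x[net@x < 0] <- 0
  mfpt_ls <- compute_mfpt(model, B, A)
  inflow <- Matrix::colSums(Fm)
  ord <- order(-inflow)
  top <- data.frame(state = model$active[ord[seq_len(min(20L, length(ord)))]],
                    flux_in = inflow[ord[seq_len(min(20L, length(ord)))]])
  if (!is.null(model$grid)) {
    xyz <- state_to_grid(top$state, model$grid)
    top$x <- xyz[, 1L]; top$y <- xyz[, 2L]; top$z <- xyz[, 3L]
  }
  structure(list(committors = com, flux = Fm, net_flux = net,
                 total_flux = total_flux, rate_per_ps = rate,
                 mfpt_tpt_ns = if (rate > 0) 1 / rate / 1000 else Inf,
                 mfpt_ns = mfpt_ls$mfpt_ns, mfpt_linear = mfpt_ls,
                 lag = model$lag, A = A, B = B, top_states = top,
                 estimator = model$estimator),
            class = "gas_tpt")
}

#' @export
print.gas_tpt <- function(x, ...) {
  cat(sprintf(
    "gas_tpt: |A|=%d, |B|=%d, lag %g ps\n  MFPT (linear system) = %.4g ns\n  1/k (reactive flux)  = %.4g ns\n",
    length(x$A), length(x$B), x$lag, x$mfpt_ns, x$mfpt_tpt_ns))
  invisible(x)
}

#' Write a kinetics report
#'
#' @param tpt a `gas_tpt`.
#' @param path output text file.
#' @export
write_kinetics <- function(tpt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gasport kinetics report; lag=%g ps; estimator=%s",
            tpt$lag, tpt$estimator),
    sprintf("source_states\t%d", length(tpt$A)),
    sprintf("sink_states\t%d", length(tpt$B)),
    sprintf("mfpt_linear_ns\t%.8g", tpt$mfpt_ns),
    sprintf("mfpt_tpt_ns\t%.8g", tpt$mfpt_tpt_ns),
    sprintf("rate_per_ps\t%.8g", tpt$rate_per_ps),
    "# top flux-carrying states"), con)
  suppressWarnings(utils::write.table(tpt$top_states, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}
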