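# Access/egress event detection: find dwells of each gas molecule inside the
# inner catalytic-zone cutoff and trace them backward/forward to the outer
# shell. Two sub-inner dwells with no outer-shell crossing between them are
# one event: excursions that never reach the outer shell do not terminate a
# traced event, which prevents double-counting rattling at the cutoff.

#' Event-tracing thresholds
#'
#' @param r_inner inner (catalytic zone) cutoff in Angstrom; default 6.
#' @param r_outer outer tracing shell in Angstrom; default 20.
#' @return a `gas_thresholds`.
#' @export
event_thresholds <- function(r_inner = 6, r_outer = 20) {
  if (r_inner >= r_outer) {
    stop("r_inner (", r_inner, ") must be smaller than r_outer (", r_outer, ")")
  }
  structure(list(r_inner = r_inner, r_outer = r_outer),
            class = "gas_thresholds")
}

#' Detect access and egress events
#'
#' For each maximal dwell below `r_inner` (merging dwells not separated by an
#' `r_outer` crossing) two records are produced: an entry, traced backward to
#' the last frame with distance > `r_outer` before the dwell, and an exit,
#' traced forward to the first such frame after it. Dwells with no prior (or
#' posterior) outer crossing yield a censored entry (exit): counted, but with
#' undefined trace time, and excluded from duration averages downstream.
#'
#' @param traj a `gas_traj`.
#' @param thresholds an [event_thresholds()].
#' @return a data.frame of class `gas_events`, one row per event, with
#'   columns `event_id`, `molecule_id`, `dwell_id`, `direction`
#'   (`"entry"`/`"exit"`), `t_outer`, `t_inner` (ps), `duration_ns`,
#'   `min_distance` (Angstrom, over the dwell), `frame_outer`, `frame_inner`,
#'   `censored`, `pathway` (`NA` until classified).
#' @export
detect_events <- function(traj, thresholds = event_thresholds()) {
  stopifnot(inherits(traj, "gas_traj"))
  out <- list()
  dwell_counter <- 0L
  for (m in seq_along(traj$ids)) {
    d <- traj$dist[, m]
    sep <- which(d > thresholds$r_outer)
    inner <- d < thresholds$r_inner
    if (!any(inner)) next
    # segments: maximal runs of frames strictly between consecutive separators
    bounds <- c(0L, sep, length(d) + 1L)
    for (s in seq_len(length(bounds) - 1L)) {
      lo <- bounds[s] + 1L
      hi <- bounds[s + 1L] - 1L
      if (lo > hi) next
      idx <- lo:hi
      in_idx <- idx[inner[idx]]
      if (length(in_idx) == 0L) next
      dwell_counter <- dwell_counter + 1L
      first_in <- in_idx[1L]
      last_in <- in_idx[length(in_idx)]
      min_d <- min(d[first_in:last_in])
      entry_cens <- bounds[s] == 0L
      exit_cens <- bounds[s + 1L] == length(d) + 1L
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = traj$ids[m],
        dwell_id = dwell_counter,
        direction = c("entry", "exit"),
        t_outer = c(if (entry_cens) NA_real_ else traj$times[bounds[s]],
                    if (exit_cens) NA_real_ else traj$times[bounds[s + 1L]]),
        t_inner = c(traj$times[first_in], traj$times[last_in]),
        frame_outer = c(if (entry_cens) NA_integer_ else bounds[s],
                        if (exit_cens) NA_integer_ else bounds[s + 1L]),
        frame_inner = c(first_in, last_in),
        min_distance = min_d,
        censored = c(entry_cens, exit_cens),
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else data.frame(
    molecule_id = character(), dwell_id = integer(), direction = character(),
    t_outer = numeric(), t_inner = numeric(), frame_outer = integer(),
    frame_inner = integer(), min_distance = numeric(), censored = logical())
  ev$duration_ns <- abs(ev$t_inner - ev$t_outer) / 1000
  ev$pathway <- rep(NA_character_, nrow(ev))
  ev$event_id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev <- ev[, c("event_id", "molecule_id", "dwell_id", "direction", "t_outer",
               "t_inner", "duration_ns", "min_distance", "frame_outer",
               "frame_inner", "censored", "pathway")]
  attr(ev, "thresholds") <- thresholds
  attr(ev, "stride") <- traj$stride
  class(ev) <- c("gas_events", "data.frame")
  ev
}

#' Event-rate arithmetic
#'
#' The bookkeeping used in per-system summaries: events per microsecond of
#' simulation, the mean interval between successive events anywhere in the
#' system, and the mean interval per individual molecule.
#'
#' @param n_events number of access events (entry/exit pairs).
#' @param total_time_us total simulated time in microseconds.
#' @param n_molecules number of gas molecules in the system.
#' @return list with `rate_per_us`, `interval_ns`, `per_molecule_interval_us`.
#' @export
event_rate_summary <- function(n_events, total_time_us, n_molecules) {
  if (n_events == 0) {
    return(list(rate_per_us = 0, interval_ns = NA_real_,
                per_molecule_interval_us = NA_real_, zero_events = TRUE))
  }
  list(rate_per_us = n_events / total_time_us,
       interval_ns = 1000 * total_time_us / n_events,
       per_molecule_interval_us = n_molecules * total_time_us / n_events,
       zero_events = FALSE)
}

#' Summarize detected events
#'
#' Per-pathway entry/exit counts and mean trace times (censored records are
#' counted but excluded from the means), plus aggregate rates via
#' [event_rate_summary()]. An event here is one dwell (an entry/exit pair).
#'
#' @param events a `gas_events` table (optionally pathway-labeled).
#' @param total_time_us total simulated time (microseconds).
#' @param n_molecules number of gas molecules.
#' @return list of class `gas_event_summary` with `per_pathway`
#'   (data.frame), `n_events`, `n_censored_records`, and the rate fields.
#' @export
summarize_events <- function(events, total_time_us, n_molecules) {
  n_ev <- length(unique(events$dwell_id))
  rates <- event_rate_summary(n_ev, total_time_us, n_molecules)
  pw <- if (nrow(events)) {
    ifelse(is.na(events$pathway), "unassigned", events$pathway)
  } else {
    character(0)
  }
  per <- do.call(rbind, lapply(split(seq_len(nrow(events)), pw), function(i) {
    e <- events[i, , drop = FALSE]
    ent <- e[e$direction == "entry", , drop = FALSE]
    ext <- e[e$direction == "exit", , drop = FALSE]
    data.frame(
      pathway = pw[i[1L]],
      n_entry = nrow(ent), n_exit = nrow(ext),
      mean_entry_ns = mean(ent$duration_ns[!ent$censored]),
      mean_exit_ns = mean(ext$duration_ns[!ext$censored]),
      n_censored = sum(e$censored))
  }))
  rownames(per) <- NULL
  structure(c(list(per_pathway = per, n_events = n_ev,
                   n_censored_records = sum(events$censored),
                   total_time_us = total_time_us,
                   n_molecules = n_molecules), rates),
            class = "gas_event_summary")
}

#' @export
print.gas_event_summary <- function(x, ...) {
  cat(sprintf(
    "%d events in %g us (%d molecules): %.3g events/us, one every %.3g ns (%.3g us per molecule)\n",
    x$n_events, x$total_time_us, x$n_molecules, x$rate_per_us,
    x$interval_ns, x$per_molecule_interval_us))
  if (nrow(x$per_pathway)) print(x$per_pathway, row.names = FALSE)
  invisible(x)
}

#' Write the event table as delimited text
#'
#' @param events a `gas_events` table.
#' @param path output TSV path.
#' @export
write_events <- function(events, path) {
  th <- attr(events, "thresholds")
  hdr <- sprintf("# gasport events; r_inner=%g A, r_outer=%g A, stride=%g ps",
                 th$r_inner, th$r_outer, attr(events, "stride"))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    events, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}
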