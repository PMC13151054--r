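# Residue-contact profiles along traced events, the trapped-molecule filter,
# contact-mass pathway assignment, and overlap / same-path statistics.

#' Pathway definitions
#'
#' @param labels character vector of pathway labels (unique).
#' @param signatures list (same length) of residue-id vectors; non-empty.
#' @param priority integer rank used to break contact-mass ties (lower rank
#'   wins); defaults to the order given.
#' @return a `gas_pathways` data structure.
#' @export
pathway_definitions <- function(labels, signatures,
                                priority = seq_along(labels)) {
  stopifnot(length(labels) == length(signatures),
            !anyDuplicated(labels),
            all(lengths(signatures) > 0))
  structure(list(labels = as.character(labels),
                 signatures = lapply(signatures, as.character),
                 priority = as.integer(priority)),
            class = "gas_pathways")
}

event_frame_span <- function(ev, nf) {
  # traced span in frame indices; censored ends fall back to the trajectory
  # boundary so contacts during a truncated trace are still observable
  lo <- min(ev$frame_outer, ev$frame_inner, na.rm = TRUE)
  hi <- max(ev$frame_outer, ev$frame_inner, na.rm = TRUE)
  c(max(lo, 1L), min(hi, nf))
}

#' Residue-contact frequencies along events
#'
#' A frame counts as a contact with a residue when any atom of that residue
#' lies within `cutoff` of the gas particle site (for diatomic inputs with
#' two sites per molecule, either site). Frequencies are contacts per
#' nanosecond of the traced event span; `fraction` is the share of the span's
#' frames in contact.
#'
#' @param events a `gas_events` table.
#' @param traj the `gas_traj` the events were detected in.
#' @param environment a `gas_env`.
#' @param cutoff contact distance cutoff (Angstrom; default 3.5).
#' @param report_floor frequency floor (contacts/ns) applied only in
#'   aggregated reports; the raw profile always keeps everything.
#' @return object of class `gas_contacts`: `pairs` data.frame (`event_id`,
#'   `residue_id`, `label`, `n_contact_frames`, `n_frames`, `duration_ns`,
#'   `freq`, `fraction`) plus metadata.
#' @export
contact_frequencies <- function(events, traj, environment, cutoff = 3.5,
                                report_floor = 12) {
  stopifnot(inherits(traj, "gas_traj"), inherits(environment, "gas_env"))
  at <- environment$atoms
  res_ids <- unique(at$residue_id)
  atom_xyz <- as.matrix(at[, c("x", "y", "z")])
  by_res <- split(seq_len(nrow(at)), at$residue_id)
  lab <- at$label[!duplicated(at$residue_id)]
  names(lab) <- at$residue_id[!duplicated(at$residue_id)]
  nf <- n_frames(traj)
  cutoff2 <- cutoff^2
  rows <- vector("list", nrow(events))
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    span <- event_frame_span(ev, nf)
    frames <- span[1L]:span[2L]
    m <- match(ev$molecule_id, traj$ids)
    if (is.na(m)) stop("event molecule '", ev$molecule_id,
                       "' absent from trajectory")
    gp <- matrix(traj$rel[frames, m, ], ncol = 3L)
    # squared distances frames x atoms
    d2 <- outer(rowSums(gp^2), rowSums(atom_xyz^2), "+") -
      2 * gp %*% t(atom_xyz)
    hit_any <- FALSE
    n_fr <- length(frames)
    dur_ns <- n_fr * traj$stride / 1000
    res_rows <- lapply(res_ids, function(rid) {
      cols <- by_res[[rid]]
      sub <- d2[, cols, drop = FALSE]
      n_contact <- sum(apply(sub, 1L, min) <= cutoff2)
      if (n_contact == 0L) return(NULL)
      data.frame(event_id = ev$event_id, residue_id = rid,
                 label = unname(lab[rid]), n_contact_frames = n_contact,
                 n_frames = n_fr, duration_ns = dur_ns,
                 freq = n_contact / dur_ns, fraction = n_contact / n_fr,
                 stringsAsFactors = FALSE)
    })
    rows[[r]] <- do.call(rbind, res_rows)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    pairs <- data.frame(event_id = integer(), residue_id = character(),
                        label = character(), n_contact_frames = integer(),
                        n_frames = integer(), duration_ns = numeric(),
                        freq = numeric(), fraction = numeric())
  }
  rownames(pairs) <- NULL
  durations <- vapply(seq_len(nrow(events)), function(r) {
    span <- event_frame_span(events[r, ], nf)
    (span[2L] - span[1L] + 1L) * traj$stride / 1000
  }, numeric(1L))
  names(durations) <- events$event_id
  structure(list(pairs = pairs, event_durations = durations,
                 cutoff = cutoff, report_floor = report_floor,
                 trapped_filtered = FALSE),
            class = "gas_contacts")
}

#' Trapped-molecule filter (the ** variant)
#'
#' Removes every (residue, event) pair in which that single residue is in
#' contact for more than `threshold` of the event's time; only the offending
#' pair is dropped, the event and its other residue contacts are retained.
#'
#' @param profile a `gas_contacts`.
#' @param threshold contact-time fraction above which a pair is considered
#'   trapped (default 0.75).
#' @return a filtered `gas_contacts` with `trapped_filtered = TRUE`.
#' @export
trapped_filter <- function(profile, threshold = 0.75) {
  stopifnot(inherits(profile, "gas_contacts"))
  keep <- profile$pairs$fraction <= threshold
  out <- profile
  out$pairs <- profile$pairs[keep, , drop = FALSE]
  rownames(out$pairs) <- NULL
  out$trapped_filtered <- TRUE
  out$trapped_threshold <- threshold
  out
}

#' Aggregate contact frequencies per pathway and direction
#'
#' Pools events by (pathway, direction): the aggregated frequency of a
#' residue is its total contact count divided by the total traced time of
#' that group, in contacts/ns. Only the `top_n` residues per group are
#' listed and entries below the report floor are omitted (the raw per-event
#' profile is unaffected).
#'
#' @param profile a `gas_contacts`.
#' @param events the pathway-labeled `gas_events` the profile came from.
#' @param top_n residues listed per pathway x direction (default 10).
#' @param report_floor minimum aggregated frequency (contacts/ns) to report;
#'   defaults to the profile's floor.
#' @return data.frame (`pathway`, `direction`, `residue_id`, `label`,
#'   `freq`).
#' @export
aggregate_contacts <- function(profile, events, top_n = 10L,
                               report_floor = profile$report_floor) {
  p <- merge(profile$pairs,
             events[, c("event_id", "direction", "pathway")],
             by = "event_id")
  p$pathway[is.na(p$pathway)] <- "unassigned"
  groups <- split(p, list(p$pathway, p$direction), drop = TRUE)
  # the denominator is the total traced time of ALL events in the group,
  # taken from the profile's per-event durations where available — the
  # trapped filter removes pairs, never events, so In** and In frequencies
  # share denominators and the filter can only remove mass
  ev_pw <- ifelse(is.na(events$pathway), "unassigned", events$pathway)
  group_total <- function(pw, dir) {
    ids <- as.character(events$event_id[ev_pw == pw &
                                          events$direction == dir])
    if (!is.null(profile$event_durations)) {
      ids <- intersect(ids, names(profile$event_durations))
      sum(profile$event_durations[ids])
    } else {
      keep <- profile$pairs$event_id %in% as.integer(ids)
      sub <- profile$pairs[keep, , drop = FALSE]
      sum(sub$duration_ns[!duplicated(sub$event_id)])
    }
  }
  out <- lapply(groups, function(g) {
    tot_ns <- group_total(g$pathway[1L], g$direction[1L])
    agg <- stats::aggregate(n_contact_frames ~ residue_id + label, g, sum)
    agg$freq <- agg$n_contact_frames / tot_ns
    agg <- agg[order(-agg$freq), , drop = FALSE]
    agg <- agg[agg$freq >= report_floor, , drop = FALSE]
    agg <- utils::head(agg, top_n)
    if (nrow(agg) == 0L) return(NULL)
    data.frame(pathway = g$pathway[1L], direction = g$direction[1L],
               residue_id = agg$residue_id, label = agg$label,
               freq = agg$freq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), direction = character(),
                      residue_id = character(), label = character(),
                      freq = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Assign pathway labels to events by signature contact mass
#'
#' Each event gets the label of the pathway definition whose signature
#' residues carry the largest summed contact frequency along the traced
#' span; ties go to the lower priority rank and are flagged. Events touching
#' no signature residue are labeled `"unassigned"`.
#'
#' @param events a `gas_events` table.
#' @param profile a `gas_contacts` for those events.
#' @param definitions a [pathway_definitions()].
#' @return `events` with `pathway` filled in and a logical `pathway_tie`
#'   column.
#' @export
classify_pathway <- function(events, profile, definitions) {
  stopifnot(inherits(definitions, "gas_pathways"))
  if (length(definitions$labels) == 0L) stop("empty pathway definitions")
  mass <- matrix(0, nrow = nrow(events), ncol = length(definitions$labels),
                 dimnames = list(NULL, definitions$labels))
  p <- profile$pairs
  for (k in seq_along(definitions$labels)) {
    sel <- p$residue_id %in% definitions$signatures[[k]]
    if (any(sel)) {
      s <- tapply(p$freq[sel], p$event_id[sel], sum)
      idx <- match(as.integer(names(s)), events$event_id)
      mass[idx, k] <- as.numeric(s)
    }
  }
  events$pathway <- NA_character_
  events$pathway_tie <- FALSE
  for (r in seq_len(nrow(events))) {
    mx <- max(mass[r, ])
    if (mx <= 0) {
      events$pathway[r] <- "unassigned"
      next
    }
    top <- which(abs(mass[r, ] - mx) < 1e-12 * max(mx, 1))
    if (length(top) > 1L) {
      events$pathway_tie[r] <- TRUE
      top <- top[which.min(definitions$priority[top])]
    }
    events$pathway[r] <- definitions$labels[top]
  }
  events
}

#' Overlap and same-path statistics
#'
#' Counts pairs of events whose traced spans intersect in time, split by the
#' pathway pair (the diagonal holds intra-pathway overlaps), and, per
#' pathway, the percentage of dwells whose exit leaves through the same
#' pathway as the entry came in.
#'
#' @param events a pathway-labeled `gas_events` table.
#' @return list with `overlap` (symmetric pathway x pathway count matrix)
#'   and `same_path` (data.frame `pathway`, `n_dwells`, `pct_same_exit`).
#' @export
overlap_and_samepath <- function(events) {
  pw <- ifelse(is.na(events$pathway), "unassigned", events$pathway)
  labs <- sort(unique(pw))
  lo <- pmin(events$t_outer, events$t_inner, na.rm = TRUE)
  hi <- pmax(events$t_outer, events$t_inner, na.rm = TRUE)
  n <- nrow(events)
  overlap <- matrix(0L, length(labs), length(labs),
                    dimnames = list(labs, labs))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (lo[i] <= hi[j] && lo[j] <= hi[i]) {
          a <- pw[i]; b <- pw[j]
          overlap[a, b] <- overlap[a, b] + 1L
          if (a != b) overlap[b, a] <- overlap[b, a] + 1L
        }
      }
    }
  }
  sp <- lapply(split(seq_len(n), events$dwell_id), function(i) {
    e <- events[i, , drop = FALSE]
    ent <- e$pathway[e$direction == "entry"]
    ext <- e$pathway[e$direction == "exit"]
    if (length(ent) != 1L || length(ext) != 1L) return(NULL)
    data.frame(entry = ent, same = identical(ent, ext))
  })
  sp <- do.call(rbind, sp)
  same_path <- if (is.null(sp)) {
    data.frame(pathway = character(), n_dwells = integer(),
               pct_same_exit = numeric())
  } else {
    agg <- stats::aggregate(same ~ entry, sp, function(v) {
      c(n = length(v), pct = 100 * mean(v))
    })
    data.frame(pathway = agg$entry, n_dwells = agg$same[, "n"],
               pct_same_exit = agg$same[, "pct"])
  }
  list(overlap = overlap, same_path = same_path)
}
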