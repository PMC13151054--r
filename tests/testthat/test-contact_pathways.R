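# A hand-built corridor fixture: a molecule travels from the outer shell to
# the sink past one well's lining residues, so counts are enumerable.

corridor_fixture <- function() {
  sys <- synthetic_system(
    30, list(well_spec(c(12, 0, 0), 3, 3, "wA"),
             well_spec(c(0, 12, 0), 3, 3, "wB")),
    sink_radius = 6)
  env <- environment_from_system(sys, n_points = 26L)
  # molecule m1 enters along +x (through wA), m2 along +y (through wB)
  wp <- rbind(
    data.frame(time = c(0, 200, 400), id = "m1",
               x = c(25, 4, 25), y = 0, z = 0),
    data.frame(time = c(0, 200, 400), id = "m2", x = 0,
               y = c(25, 4, 25), z = 0))
  tr <- scripted_fixture(wp, save_stride = 10)
  ev <- detect_events(tr)
  list(system = sys, env = env, traj = tr, events = ev)
}

test_that("contacts obey the distance cutoff exactly", {
  env <- environment_model(data.frame(residue_id = "r1", label = "R",
                                      x = 10, y = 0, z = 0))
  mk <- function(x_at_closest) {
    wp <- data.frame(time = c(0, 50, 100), id = "m",
                     x = c(25, x_at_closest, 25), y = 0, z = 0)
    tr <- scripted_fixture(wp, save_stride = 50)
    ev <- detect_events(tr, event_thresholds(r_inner = 15, r_outer = 20))
    contact_frequencies(ev, tr, env, cutoff = 3.5)
  }
  expect_gt(nrow(mk(13.0)$pairs), 0)   # 3.0 A from the residue: contact
  expect_equal(nrow(mk(13.6)$pairs), 0)  # 3.6 A: no contact
})

test_that("contact frequency is contacts per ns of the traced span", {
  # 1000-frame span at 10 ps = 10 ns; residue in contact over 120 frames
  d <- rep(30, 1000)
  d[200:319] <- 3  # 120 frames near the residue at the origin-side
  tr <- gas_traj((seq_along(d) - 1) * 10, "m",
                 array(c(d, rep(0, 2000)), c(1000, 1, 3)))
  env <- environment_model(data.frame(residue_id = "r1", label = "R",
                                      x = 3, y = 0, z = 0))
  ev <- data.frame(event_id = 1L, molecule_id = "m", dwell_id = 1L,
                   direction = "entry", t_outer = 0, t_inner = 9990,
                   duration_ns = 9.99, min_distance = 3, frame_outer = 1L,
                   frame_inner = 1000L, censored = FALSE,
                   pathway = NA_character_)
  prof <- contact_frequencies(ev, tr, env, cutoff = 3.5)
  expect_equal(prof$pairs$n_contact_frames, 120L)
  expect_equal(prof$pairs$freq, 120 / 10)  # 12 contacts/ns, at the floor
  expect_equal(prof$pairs$fraction, 0.12)
})

test_that("trapped filter removes exactly the >75% pairs and only removes", {
  pairs <- data.frame(
    event_id = c(1L, 1L, 2L, 3L, 3L),
    residue_id = c("a", "b", "a", "a", "b"),
    label = "x", n_contact_frames = c(80L, 20L, 70L, 80L, 80L),
    n_frames = 100L, duration_ns = 1,
    freq = c(80, 20, 70, 80, 80), fraction = c(0.8, 0.2, 0.7, 0.8, 0.8))
  prof <- structure(list(pairs = pairs,
                         event_durations = c(`1` = 1, `2` = 1, `3` = 1),
                         cutoff = 3.5, report_floor = 12,
                         trapped_filtered = FALSE), class = "gas_contacts")
  f <- trapped_filter(prof, 0.75)
  # event 1: only (a) removed; event 2 kept; event 3: both removed but the
  # event itself survives in the table of other events
  expect_equal(nrow(f$pairs), 2L)
  expect_setequal(f$pairs$event_id, c(1L, 2L))
  expect_false("a" %in% f$pairs$residue_id[f$pairs$event_id == 1L])
  expect_true("b" %in% f$pairs$residue_id[f$pairs$event_id == 1L])
  # filter only removes mass: aggregated frequencies never increase
  ev <- data.frame(event_id = 1:3, direction = "entry",
                   pathway = "P", molecule_id = "m", dwell_id = 1:3,
                   duration_ns = 1)
  agg0 <- aggregate_contacts(prof, ev, report_floor = 0)
  agg1 <- aggregate_contacts(f, ev, report_floor = 0)
  m <- merge(agg0, agg1, by = c("pathway", "direction", "residue_id"),
             all.x = TRUE)
  m$freq.y[is.na(m$freq.y)] <- 0
  expect_true(all(m$freq.y <= m$freq.x + 1e-12))
  expect_true(all(agg1$residue_id %in% agg0$residue_id))
})

test_that("classification matches synthetic corridor ground truth", {
  fx <- corridor_fixture()
  prof <- contact_frequencies(fx$events, fx$traj, fx$env)
  defs <- pathway_definitions(names(fx$env$regions), fx$env$regions)
  ev <- classify_pathway(fx$events, prof, defs)
  expect_equal(unname(ev$pathway[ev$molecule_id == "m1"]), c("wA", "wA"))
  expect_equal(unname(ev$pathway[ev$molecule_id == "m2"]), c("wB", "wB"))
  # permutation invariance of residue order
  env2 <- fx$env
  perm <- sample(nrow(env2$atoms))
  env2$atoms <- env2$atoms[perm, ]
  prof2 <- contact_frequencies(fx$events, fx$traj, env2)
  ev2 <- classify_pathway(fx$events, prof2, defs)
  expect_equal(ev2$pathway, ev$pathway)
})

test_that("ties break by priority rank and no-contact events are unassigned", {
  ev <- data.frame(event_id = 1:2, molecule_id = "m", dwell_id = 1:2,
                   direction = "entry", t_outer = 0, t_inner = 10,
                   duration_ns = 0.01, min_distance = 1, frame_outer = 1L,
                   frame_inner = 2L, censored = FALSE,
                   pathway = NA_character_)
  pairs <- data.frame(event_id = c(1L, 1L), residue_id = c("a", "b"),
                      label = c("A", "B"), n_contact_frames = 5L,
                      n_frames = 10L, duration_ns = 0.01,
                      freq = 500, fraction = 0.5)
  prof <- structure(list(pairs = pairs, cutoff = 3.5, report_floor = 12,
                         trapped_filtered = FALSE), class = "gas_contacts")
  defs <- pathway_definitions(c("P1", "P2"), list("a", "b"),
                              priority = c(2L, 1L))
  out <- classify_pathway(ev, prof, defs)
  expect_equal(out$pathway[1], "P2")  # lower priority rank wins the tie
  expect_true(out$pathway_tie[1])
  expect_equal(out$pathway[2], "unassigned")
  expect_error(classify_pathway(ev, prof,
                                structure(list(labels = character(),
                                               signatures = list(),
                                               priority = integer()),
                                          class = "gas_pathways")),
               "empty")
})

test_that("overlap counts intersecting spans and same-path percentages", {
  ev <- data.frame(
    event_id = 1:6,
    molecule_id = c("a", "a", "b", "b", "c", "c"),
    dwell_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    direction = rep(c("entry", "exit"), 3),
    t_outer = c(0, 300, 100, 400, 1000, 1300),
    t_inner = c(200, 200, 250, 250, 1100, 1100),
    duration_ns = 0.1, min_distance = 1, frame_outer = 1L, frame_inner = 2L,
    censored = FALSE,
    pathway = c("P", "P", "P", "Q", "Q", "Q"))
  res <- overlap_and_samepath(ev)
  # dwell1 spans 0-300, dwell2 spans 100-400 -> entries/exits overlap
  expect_gt(res$overlap["P", "P"], 0)
  expect_equal(sum(res$overlap), sum(res$overlap))  # symmetric by build
  expect_true(isSymmetric(res$overlap))
  # disjoint dwell 3 (1000-1300) overlaps nothing
  expect_equal(res$overlap["Q", "Q"], 1L)  # only its own entry/exit pair
  sp <- res$same_path
  expect_equal(sp$pct_same_exit[sp$pathway == "P"], 50)  # dwell2 exits via Q
  expect_equal(sp$pct_same_exit[sp$pathway == "Q"], 100)
})

test_that("every-entry-exits-same-path gives 100 percent", {
  ev <- data.frame(
    event_id = 1:4, molecule_id = c("a", "a", "b", "b"),
    dwell_id = c(1L, 1L, 2L, 2L), direction = rep(c("entry", "exit"), 2),
    t_outer = c(0, 100, 500, 600), t_inner = c(50, 50, 550, 550),
    duration_ns = 0.05, min_distance = 1, frame_outer = 1L,
    frame_inner = 2L, censored = FALSE, pathway = "Pr")
  sp <- overlap_and_samepath(ev)$same_path
  expect_equal(sp$pct_same_exit, 100)
  expect_equal(sp$n_dwells, 2L)
})
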