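# End-to-end orchestration: simulate or ingest a trajectory, trace events,
# classify pathways, discretize, estimate and validate the MSM, compute TPT
# kinetics and the MSD exponent, and write every table next to the resolved
# configuration that produced it.

#' Build a run configuration
#'
#' Defaults follow the analysis conventions this package implements: 6 A
#' inner and 20 A outer event cutoffs at a 10 ps analysis stride, a 1 A /
#' 40 A-cube grid at a 100 ps MSM stride, 6.7 A sink and 22 A source radii,
#' 3.5 A contacts with a 75% trapped filter, and a 0.1-5 ns lag scan.
#'
#' @param input list: either `trajectory` (+ `format`, optional
#'   `environment` PDB and `anchor`) or `NULL` when `synthetic` is given.
#' @param synthetic list describing a synthetic system: `box_half_edge`,
#'   `sink_radius`, `wells` (list of lists with `center`, `radius`, `depth`,
#'   `id`), `n_molecules`, `n_steps`, `D`, `dt`.
#' @param thresholds,strides,grid,lags,msm_lag,pathways,seed see Details in
#'   the package vignette; every value lands in the resolved config written
#'   beside the outputs.
#' @return a validated `gas_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       thresholds = list(), strides = list(), grid = list(),
                       lags = c(100, 200, 500, 1000, 2000, 5000),
                       msm_lag = NULL, pathways = NULL, seed = 1L) {
  th <- utils::modifyList(list(r_inner = 6, r_outer = 20, r_sink = 6.7,
                               r_source = 22, contact = 3.5, trapped = 0.75),
                          thresholds)
  st <- utils::modifyList(list(analysis = 10, msm = 100), strides)
  gr <- utils::modifyList(list(spacing = 1, half_edge = 20,
                               wrap = "periodic"), grid)
  if (th$r_inner >= th$r_outer) {
    stop("config error: r_inner (", th$r_inner,
         ") must be smaller than r_outer (", th$r_outer, ")")
  }
  if (is.null(input) && is.null(synthetic)) {
    stop("config error: give an input trajectory or a synthetic block")
  }
  cfg <- structure(list(input = input, synthetic = synthetic,
                        thresholds = th, strides = st, grid = gr,
                        lags = lags,
                        msm_lag = if (is.null(msm_lag)) lags[1L] else msm_lag,
                        pathways = pathways, seed = as.integer(seed)),
                   class = "gas_config")
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [run_config()].
#' @return a `gas_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

config_system <- function(syn) {
  wells <- lapply(syn$wells, function(w) {
    well_spec(unlist(w$center), w$radius, w$depth, w$id)
  })
  synthetic_system(box_half_edge = syn$box_half_edge, wells = wells,
                   sink_radius = if (is.null(syn$sink_radius)) 6 else
                     syn$sink_radius)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate/ingest, event detection, contact profiling and pathway
#' classification, overlap statistics, grid discretization and MSM
#' estimation, implied-timescale scan, TPT kinetics, MSD exponent, and state
#' cloud export. Each stage failure is rethrown naming the stage; outputs
#' written before the failure are kept.
#'
#' @param config a `gas_config`.
#' @param out_dir output directory (created); `NULL` to skip writing.
#' @return list of stage results, invisibly when writing.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "gas_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- c(sprintf("gasport %s; seed %d; started %s",
                         as.character(utils::packageVersion("gasport")),
                         config$seed, format(Sys.time())))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %-10s %.2f s", name,
                                       as.numeric(Sys.time() - t0,
                                                  units = "secs")))
    r
  }
  res <- list(config = config)
  set.seed(config$seed)

  res$traj <- stage("input", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      system <- config_system(syn)
      params <- brownian_params(
        D = if (is.null(syn$D)) 1 else syn$D,
        dt = if (is.null(syn$dt)) 0.01 else syn$dt,
        n_molecules = syn$n_molecules, n_steps = syn$n_steps,
        save_stride = config$strides$analysis, seed = config$seed)
      res$system <- system
      res$environment <- environment_from_system(system)
      simulate_brownian(system, params)
    } else {
      fr <- load_trajectory(config$input$trajectory,
                            format = if (is.null(config$input$format))
                              "columnar" else config$input$format)
      if (!is.null(config$input$environment)) {
        res$environment <- read_environment_pdb(
          config$input$environment,
          anchor = if (is.null(config$input$anchor)) c(0, 0, 0) else
            config$input$anchor)
      }
      superpose_and_center(fr)
    }
  })
  # stage() evaluates in this frame, so res$system/environment set above stick
  th <- config$thresholds

  res$events <- stage("events", {
    detect_events(res$traj, event_thresholds(th$r_inner, th$r_outer))
  })

  have_env <- !is.null(res$environment) &&
    nrow(res$environment$atoms) > 0
  if (have_env && nrow(res$events) > 0) {
    res$contacts <- stage("contacts", {
      contact_frequencies(res$events, res$traj, res$environment,
                          cutoff = th$contact)
    })
    res$contacts_trapped <- trapped_filter(res$contacts, th$trapped)
    defs <- config$pathways
    if (is.null(defs) && length(res$environment$regions) > 0) {
      defs <- pathway_definitions(names(res$environment$regions),
                                  res$environment$regions)
    }
    if (!is.null(defs)) {
      if (!inherits(defs, "gas_pathways")) {
        defs <- pathway_definitions(defs$labels, defs$signatures)
      }
      res$events <- stage("classify", {
        classify_pathway(res$events, res$contacts, defs)
      })
      res$overlap <- overlap_and_samepath(res$events)
    }
  }

  total_us <- (res$traj$times[n_frames(res$traj)] - res$traj$times[1L]) / 1e6
  res$summary <- summarize_events(res$events, total_us,
                                  length(res$traj$ids))

  grid <- grid_spec(config$grid$spacing, config$grid$half_edge,
                    config$grid$wrap)
  res$dtraj <- stage("discretize", {
    assign_states(res$traj, grid, stride = config$strides$msm)
  })
  res$dtraj_events <- if (nrow(res$events) > 0) {
    restrict_to_events(res$dtraj, res$events)
  } else {
    res$dtraj
  }

  res$msm <- stage("msm", estimate_msm(res$dtraj, config$msm_lag))
  res$its <- stage("its", {
    ok_lags <- config$lags[config$lags <= diff(range(res$dtraj$times)) / 2]
    implied_timescales(res$dtraj, ok_lags)
  })

  if (nrow(res$events) > 0 && any(!is.na(res$events$t_outer))) {
    res$kinetics <- stage("kinetics", {
      ss <- select_source_sink(res$dtraj, res$events,
                               r_sink = th$r_sink, r_source = th$r_source)
      ev_msm <- estimate_msm(res$dtraj_events, config$msm_lag)
      compute_tpt_rate(ev_msm, intersect(ss$source, ev_msm$active),
                       intersect(ss$sink, ev_msm$active))
    })
  }

  res$msd <- stage("msd", msd_alpha(res$traj))

  if (!is.null(out_dir)) {
    stage("write", {
      write_events(res$events, file.path(out_dir, "events.tsv"))
      if (!is.null(res$contacts)) {
        utils::write.table(res$contacts$pairs,
                           file.path(out_dir, "contacts_raw.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        agg <- aggregate_contacts(res$contacts, res$events)
        utils::write.table(agg, file.path(out_dir, "contacts_agg.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        agg2 <- aggregate_contacts(res$contacts_trapped, res$events)
        utils::write.table(agg2,
                           file.path(out_dir, "contacts_agg_trapped.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(res$overlap)) {
        utils::write.table(res$overlap$overlap,
                           file.path(out_dir, "overlap.tsv"),
                           sep = "\t", quote = FALSE)
        utils::write.table(res$overlap$same_path,
                           file.path(out_dir, "same_path.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write_msm(res$msm, file.path(out_dir, "msm"))
      utils::write.table(res$its, file.path(out_dir, "its.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(res$kinetics)) {
        write_kinetics(res$kinetics, file.path(out_dir, "kinetics.txt"))
      }
      utils::write.table(res$msd$msd, file.path(out_dir, "msd.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      export_state_cloud(res$msm, grid,
                         radius_max = config$grid$half_edge,
                         file = file.path(out_dir, "state_cloud.pdb"))
      cfg_path <- file.path(out_dir, "config_resolved.yaml")
      yaml::write_yaml(unclass_config(config), cfg_path)
      hash <- unname(tools::md5sum(cfg_path))
      log_lines <<- c(log_lines, sprintf("config md5 %s", hash))
      writeLines(c(log_lines, sprintf("finished %s", format(Sys.time()))),
                 file.path(out_dir, "run.log"))
      invisible(NULL)
    })
    return(invisible(res))
  }
  res
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$pathways <- if (inherits(x$pathways, "gas_pathways"))
    unclass(x$pathways) else x$pathways
  x
}
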