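#' Simulation configuration
#'
#' Bundles everything a run needs: the model parameters, the initial-shape
#' specification, the forced-orientation preset (`mode`), the stop criterion
#' and the seed.  `mode = "hollow"` forces longitudinal division throughout
#' L1-L3 of both identities (bifacial growth); `mode = "ridge"` additionally
#' forces adaxial L2/L3 to divide periclinally (adaxial protrusion).
#'
#' @param mode `"hollow"` or `"ridge"`.
#' @param seed integer seed; recorded in every output.
#' @param params a [model_params()] list.
#' @param n_cells,shape,n_adaxial,depth_frac,width_frac passed to
#'   [build_initial_mesh()].
#' @param max_cells stop once the cell count reaches this value.
#' @param max_steps hard cap on time steps (guards runaway configurations).
#' @param burn_in morphogen/mechanics steps before divisions are enabled,
#'   letting the fields approach steady state from their zero initial values.
#' @param snapshot_every write a snapshot every this many divisions (only
#'   when `out_dir` is set).
#' @param out_dir optional run directory for snapshots (CSV + SVG),
#'   `events.csv` and `summary.json`.
#' @param fast_forward advance clocks analytically while the tissue is
#'   mechanically and chemically quiescent (see the methods vignette);
#'   disable to force explicit stepping of every `dt`.
#' @return A list of class `leaf_run_config`.
#' @export
run_config <- function(mode = c("hollow", "ridge"), seed = 1,
                       params = model_params(), n_cells = 100,
                       shape = c("depression", "round"), n_adaxial = 6,
                       depth_frac = 0.15, width_frac = 0.35,
                       max_cells = 400, max_steps = 5e7, burn_in = 2000,
                       snapshot_every = 100, out_dir = NULL,
                       fast_forward = TRUE) {
  structure(list(mode = match.arg(mode), seed = as.integer(seed),
                 params = params, n_cells = n_cells,
                 shape = match.arg(shape), n_adaxial = n_adaxial,
                 depth_frac = depth_frac, width_frac = width_frac,
                 max_cells = max_cells, max_steps = max_steps,
                 burn_in = burn_in, snapshot_every = snapshot_every,
                 out_dir = out_dir, fast_forward = fast_forward),
            class = "leaf_run_config")
}

#' Run a full simulation
#'
#' The main loop interleaves, per time step `dt` and in this fixed order:
#' morphogen Euler step, clock Euler step, division check and execution,
#' RK4 mechanics step.  Given the same configuration and seed the run is
#' exactly reproducible.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return An object of class `leaf_run`: list with the final `tissue`, the
#'   division-event log `events` (one row per division, with division-plane
#'   angles relative to the local tissue surface), the `config`, and a
#'   one-row `summary` tibble (see [glance.leaf_run()]).
#' @export
run_simulation <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "leaf_run_config"))
  set.seed(config$seed)
  p <- config$params
  tissue <- build_initial_mesh(n_cells = config$n_cells, shape = config$shape,
                               n_adaxial = config$n_adaxial,
                               depth_frac = config$depth_frac,
                               width_frac = config$width_frac, params = p)
  tissue <- classify_layers(tissue)
  events <- list()
  n_div <- 0L
  snap_due <- config$snapshot_every
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    snapshot_run(tissue, config, "initial")
  }

  # burn-in: fields approach steady state before divisions are enabled
  if (config$burn_in > 0) {
    res <- engine_chunk(tissue, p, config$burn_in, check_divisions = FALSE)
    tissue <- engine_sync(tissue, res, p)
  }

  repeat {
    if (length(tissue$cells) >= config$max_cells) break
    if (tissue$step >= config$max_steps) {
      warning("max_steps reached before max_cells")
      break
    }
    res <- engine_chunk(tissue, p, max_steps = 500000L,
                        check_divisions = TRUE,
                        quiesce = config$fast_forward)
    tissue <- engine_sync(tissue, res, p)
    queue <- integer(0)
    if (res$status == 3L) {
      # quiescent: clock rates are constant; jump to the next threshold
      # crossing on the dt grid
      st <- tissue$states
      non_epi <- st$layer != "L1" & res$rate > 0
      k_i <- floor((st$threshold[non_epi] - st$clock[non_epi]) /
                   (p$dt * res$rate[non_epi])) + 1
      k <- max(1, min(k_i))
      if (tissue$step + k > config$max_steps) k <- config$max_steps - tissue$step
      st$clock[st$layer != "L1"] <- st$clock[st$layer != "L1"] +
        k * p$dt * res$rate[st$layer != "L1"]
      tissue$states <- st
      tissue$time <- tissue$time + k * p$dt
      tissue$step <- tissue$step + as.integer(k)
      queue <- check_divisions(tissue, p)
    } else if (res$status == 1L) {
      queue <- check_divisions(tissue, p)
    }
    if (length(queue)) {
      div <- process_divisions(tissue, queue, p, config$mode)
      tissue <- div$tissue
      if (nrow(div$events)) {
        div$events$time <- tissue$time
        div$events$step <- tissue$step
        events[[length(events) + 1L]] <- div$events
        n_div <- n_div + nrow(div$events)
      }
      # complete the division step's dt with its mechanics update
      mres <- cpp_mech_steps(tissue$vertices, engine_topo(tissue, params = p), p, 1L)
      tissue$vertices <- mres$V
      if (!quiet) message(sprintf("t=%.1f cells=%d divisions=%d",
                                  tissue$time, length(tissue$cells), n_div))
      if (!is.null(config$out_dir) && n_div >= snap_due) {
        snapshot_run(tissue, config, sprintf("div%05d", n_div))
        snap_due <- snap_due + config$snapshot_every
      }
    }
  }

  events <- if (length(events)) dplyr::bind_rows(events) else empty_events()
  events$event <- seq_len(nrow(events))
  run <- structure(list(tissue = tissue, events = events, config = config),
                   class = "leaf_run")
  run$summary <- glance(run)
  if (!is.null(config$out_dir)) {
    snapshot_run(tissue, config, "final")
    readr::write_csv(events, file.path(config$out_dir, "events.csv"),
                     progress = FALSE)
    jsonlite::write_json(c(list(seed = config$seed, mode = config$mode),
                           as.list(run$summary)),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

empty_events <- function() {
  tibble::tibble(parent = integer(), daughter1 = integer(),
                 daughter2 = integer(), x1 = numeric(), y1 = numeric(),
                 x2 = numeric(), y2 = numeric(), mode = character(),
                 layer = character(), side = character(),
                 angle = numeric(), time = numeric(), step = integer())
}

# run the compiled fused loop on the current tissue
engine_chunk <- function(tissue, params, max_steps, check_divisions = TRUE,
                         clocks_on = TRUE, quiesce = TRUE) {
  topo <- tissue_topology(tissue)
  st <- tissue$states
  cpp_run_chunk(tissue$vertices, engine_topo(tissue, topo, params), params,
                st$u, st$v, st$w, st$clock, st$threshold,
                as.integer(max_steps), check_divisions, clocks_on, quiesce,
                tol_v = 1e-8, tol_z = 1e-11)
}

engine_sync <- function(tissue, res, params) {
  tissue$vertices <- res$V
  tissue$states$u <- res$u
  tissue$states$v <- res$v
  tissue$states$w <- res$w
  tissue$states$clock <- res$clock
  tissue$time <- tissue$time + res$steps * params$dt
  tissue$step <- tissue$step + res$steps
  tissue
}

# execute a division queue (ascending cell id), cascading the epidermal
# six-edge rule until no trigger remains; deferred divisions get their clock
# pinned at the threshold so they re-trigger next step
process_divisions <- function(tissue, queue, params, mode) {
  evs <- list()
  queue <- sort(queue)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > 100L) stop("epidermal division cascade failed to terminate")
    for (id in queue) {
      if (isTRUE(getOption("pitchersim.debug"))) {
        message("dividing cell ", id, " (", length(tissue$cells), " cells)")
      }
      topo <- tissue_topology(tissue)
      res <- divide_cell(tissue, id, params, mode, topo)
      if (is.null(res)) {
        message("division of cell ", id, " deferred one step")
        i <- match(id, tissue$states$cell)
        tissue$states$clock[i] <- tissue$states$threshold[i]
      } else {
        tissue <- classify_layers(res$tissue)
        ev <- res$event
        ev$angle <- division_angle(tissue, c(ev$x1, ev$y1), c(ev$x2, ev$y2))
        evs[[length(evs) + 1L]] <- ev
      }
    }
    topo <- tissue_topology(tissue)
    epi <- topo$l1 & lengths(topo$neighbors) >= 5L
    queue <- sort(tissue$states$cell[epi])
    if (!length(queue)) break
  }
  list(tissue = tissue,
       events = if (length(evs)) dplyr::bind_rows(evs) else
         empty_events()[0, c("parent", "daughter1", "daughter2", "x1", "y1",
                             "x2", "y2", "mode", "layer", "side", "angle")])
}

snapshot_run <- function(tissue, config, tag) {
  dir <- file.path(config$out_dir, paste0("snapshot_", tag))
  write_tissue(tissue, dir)
  write_svg_tissue(tissue, file.path(dir, "tissue.svg"))
  invisible(dir)
}

#' @export
print.leaf_run <- function(x, ...) {
  cat("<leaf_run> mode=", x$config$mode, " seed=", x$config$seed,
      " cells=", length(x$tissue$cells), " divisions=", nrow(x$events),
      " t=", format(round(x$tissue$time, 1)), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Parameter sweeps
#'
#' Runs one simulation per configuration and tabulates the morphometric
#' outcome.  Individual failures are recorded (column `error`) and the sweep
#' continues.
#'
#' @param configs a list of [run_config()] objects.
#' @param quiet suppress per-run progress.
#' @return A tibble with one row per run: mode, seed, key parameters
#'   (`D_u`, `A_u`, `P`, shape), final cell counts per layer, protrusion
#'   height, aspect ratio and classification.
#' @export
sweep_simulations <- function(configs, quiet = TRUE) {
  purrr::map_dfr(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    base <- tibble::tibble(run = i, mode = cfg$mode, seed = cfg$seed,
                           D_u = cfg$params$D_u, A_u = cfg$params$A_u,
                           P = cfg$params$P, shape = cfg$shape)
    out <- tryCatch({
      r <- run_simulation(cfg, quiet = quiet)
      dplyr::bind_cols(base, r$summary, tibble::tibble(error = NA_character_))
    }, error = function(e) {
      dplyr::bind_cols(base, tibble::tibble(error = conditionMessage(e)))
    })
    out
  })
}
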