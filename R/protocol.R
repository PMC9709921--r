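# The thermal-titration protocol: temperature ramp construction, the
# window-by-window driver with its early-termination rule, and fold
# monitoring.

#' Build a temperature ramp
#'
#' The ramp is the arithmetic sequence `t_start, t_start + increment, ...`
#' capped at `t_end` (no partial step beyond the end temperature). The
#' default protocol heats from 300 K to 450 K in 10 K steps of 10 ns,
#' giving 16 windows.
#'
#' @param t_start,t_end Start and end temperature, K.
#' @param increment Temperature increase per step, K (> 0).
#' @param window_length Length of each simulation window, ns (> 0).
#' @return Object of class `temperature_ramp` with the window `temperatures`.
#' @export
build_ramp <- function(t_start = 300, t_end = 450, increment = 10,
                       window_length = 10) {
  if (!is.finite(increment) || increment <= 0)
    config_error("temperature increment must be > 0")
  if (!is.finite(window_length) || window_length <= 0)
    config_error("window length must be > 0")
  if (t_end < t_start)
    config_error("t_end must be >= t_start")
  structure(
    list(t_start = t_start, t_end = t_end, increment = increment,
         window_length = window_length,
         temperatures = seq(t_start, t_end, by = increment)),
    class = "temperature_ramp"
  )
}

#' @export
print.temperature_ramp <- function(x, ...) {
  cat(sprintf("<temperature_ramp> %g..%g K, %g K steps, %g ns windows (%d windows)\n",
              x$t_start, x$t_end, x$increment, x$window_length,
              length(x$temperatures)))
  invisible(x)
}

#' MD engine contract
#'
#' An engine is a list with functions
#' `equilibrate(system, seed)` returning a [trajectory()] whose final frame
#' defines the reference pose, and
#' `run_window(system, start_coords, temperature, length_ns, seed)` returning
#' the window [trajectory()]. Deterministic engines must return identical
#' trajectories for identical arguments. Real-MD adapters (thermostats,
#' equilibration physics) live behind this contract and are not part of the
#' analysis code.
#'
#' @param equilibrate,run_window The two contract functions.
#' @param name Backend identifier stored in run provenance.
#' @return Object of class `ttmd_engine`.
#' @export
ttmd_engine <- function(equilibrate, run_window, name = "engine") {
  stopifnot(is.function(equilibrate), is.function(run_window))
  structure(list(equilibrate = equilibrate, run_window = run_window,
                 name = name),
            class = "ttmd_engine")
}

#' Protocol configuration
#'
#' @param epsilon Termination tolerance: a window whose mean IFP_CS is
#'   `>= -epsilon` counts as "null" (original binding mode no longer
#'   sampled) and stops the run. Default 1e-4, a float-safe zero.
#' @param stride Fingerprint scoring stride over saved frames (default 1).
#' @param thresholds Interaction-detection criteria,
#'   see [interaction_thresholds()].
#' @param store_trajectories Keep window trajectories in the run result
#'   (needed for RMSD/energy plots; switch off for long batch runs).
#' @return Named list of protocol settings.
#' @export
ttmd_config <- function(epsilon = 1e-4, stride = 1L,
                        thresholds = interaction_thresholds(),
                        store_trajectories = TRUE) {
  if (epsilon < 0) config_error("epsilon must be >= 0")
  list(epsilon = epsilon, stride = as.integer(stride),
       thresholds = thresholds, store_trajectories = store_trajectories)
}

#' Run a thermal-titration MD protocol
#'
#' Drives the engine through the ramp window by window. Each window starts
#' from the final coordinates of the previous one, is scored frame-by-frame
#' against the reference fingerprint (derived from the engine's
#' equilibration), and the run stops early at the first window whose mean
#' IFP_CS is `>= -epsilon` - i.e. the native binding mode was not sampled at
#' all during that window.
#'
#' @param system A [molecular_system()].
#' @param engine A [ttmd_engine()].
#' @param ramp A [build_ramp()].
#' @param config A [ttmd_config()].
#' @param seed Master seed for this replicate; window sub-seeds are derived
#'   deterministically from it.
#' @return Object of class `ttmd_run`: list with `steps` (one record per
#'   executed window: `temperature`, `similarity`, `mean_ifp_cs`,
#'   `backbone_rmsd_max`, `backbone_rmsd`, optionally `trajectory`),
#'   `terminated_early`, `last_temperature`, `seed`, `ramp`, `reference`,
#'   `engine_name`.
#' @export
run_ttmd <- function(system, engine, ramp, config = ttmd_config(), seed = 1L) {
  if (!inherits(engine, "ttmd_engine"))
    config_error("engine does not implement the engine contract")
  features <- perceive_features(system, config$thresholds)
  ctx <- fingerprint_context(system, features, config$thresholds)

  equil <- engine$equilibrate(system, derive_seed(seed, 0L))
  reference <- reference_fingerprint(equil, system, ctx)
  ref_coords <- equil$coords[[length(equil)]]
  bb_idx <- select_atoms(system, "backbone")

  steps <- list()
  terminated <- FALSE
  start_coords <- ref_coords
  failed <- FALSE

  for (w in seq_along(ramp$temperatures)) {
    temp <- ramp$temperatures[w]
    traj <- tryCatch(
      engine$run_window(system, start_coords, temp, ramp$window_length,
                        derive_seed(seed, w)),
      error = function(e) e
    )
    if (inherits(traj, "error")) {
      warning(sprintf("engine failed in window %d (%g K): %s; partial results kept",
                      w, temp, conditionMessage(traj)))
      failed <- TRUE
      break
    }
    series <- score_trajectory(traj, system, ctx, reference,
                               stride = config$stride, window_id = w)
    mean_cs <- window_average(series)
    bb <- rmsd_series(traj, system, fit_selection = bb_idx,
                      measure_selection = bb_idx, reference = ref_coords,
                      stride = config$stride)
    step <- list(
      window = w, temperature = temp, similarity = series,
      mean_ifp_cs = mean_cs, backbone_rmsd = bb,
      backbone_rmsd_max = max(bb$rmsd),
      provenance = list(engine = engine$name, window = w,
                        seed = derive_seed(seed, w))
    )
    if (isTRUE(config$store_trajectories)) step$trajectory <- traj
    steps[[w]] <- step
    start_coords <- traj$coords[[length(traj)]]

    if (mean_cs >= -config$epsilon) {
      terminated <- TRUE
      break
    }
  }

  if (!length(steps))
    usage_error("no window completed; engine failed before the first step")

  structure(
    list(
      steps = steps,
      terminated_early = terminated,
      failed = failed,
      last_temperature = steps[[length(steps)]]$temperature,
      seed = seed,
      ramp = ramp,
      reference = reference,
      engine_name = engine$name
    ),
    class = "ttmd_run"
  )
}

#' @export
print.ttmd_run <- function(x, ...) {
  cat(sprintf("<ttmd_run> %d step(s), %g..%g K%s\n",
              length(x$steps), x$steps[[1]]$temperature, x$last_temperature,
              if (x$terminated_early) " (terminated early: binding mode lost)" else ""))
  means <- vapply(x$steps, function(s) s$mean_ifp_cs, 0)
  cat("  mean IFP_CS:", paste(sprintf("%.3f", means), collapse = " "), "\n")
  invisible(x)
}

#' Flag windows where the protein fold degraded
#'
#' Advisory check of fold conservation during the ramp: flags every executed
#' window whose maximum backbone RMSD (against the equilibrated reference)
#' exceeds the threshold. Flags never stop a run; they qualify whether late
#' high-temperature windows still probe an intact binding site.
#'
#' @param run A `ttmd_run`.
#' @param backbone_threshold Angstrom; windows whose max backbone RMSD
#'   exceeds this are flagged.
#' @return Logical vector, one flag per executed step.
#' @export
monitor_fold <- function(run, backbone_threshold) {
  vapply(run$steps, function(s) s$backbone_rmsd_max > backbone_threshold, TRUE)
}
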