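# Post-run analyses: titration profile, MS coefficient, per-residue
# nonbonded interaction-energy decomposition, and the three diagnostic plots.

COULOMB_K <- 332.06  # kcal A / (mol e^2)

#' Titration profile of a run
#'
#' The per-step average IFP_CS as a function of step temperature, prepended
#' with the initial state: by construction the equilibrated pose scores -1
#' at the starting temperature.
#'
#' @param run A `ttmd_run` with at least one executed step.
#' @return Object of class `titration_profile`: data.frame with columns
#'   `temperature` and `mean_ifp_cs`; attribute `t_start`.
#' @export
titration_profile <- function(run) {
  if (!inherits(run, "ttmd_run") || !length(run$steps))
    usage_error("titration profile needs a run with at least one step")
  temps <- vapply(run$steps, function(s) s$temperature, 0)
  means <- vapply(run$steps, function(s) s$mean_ifp_cs, 0)
  new_titration_profile(c(run$ramp$t_start, temps), c(-1, means),
                        t_start = run$ramp$t_start)
}

#' Construct a titration profile from temperatures and mean scores
#'
#' Low-level constructor used by [titration_profile()] and anywhere a
#' profile is assembled from already-computed step averages. The first point
#' is the initial state (IFP_CS = -1 at the starting temperature).
#'
#' @param temperature Strictly increasing temperatures, K.
#' @param mean_ifp_cs Mean IFP_CS per point, each in `[-1, 0]`.
#' @param t_start Starting temperature (default: first element).
#' @return A `titration_profile`.
#' @export
new_titration_profile <- function(temperature, mean_ifp_cs,
                                  t_start = temperature[1]) {
  if (length(temperature) != length(mean_ifp_cs))
    usage_error("temperature and mean_ifp_cs lengths differ")
  # the initial state sits at t_start, where the first window also runs:
  # only that first gap may be zero
  d <- diff(temperature)
  if (any(d < 0) || (length(d) > 1 && any(d[-1] <= 0)))
    usage_error("profile temperatures must be increasing")
  if (any(mean_ifp_cs < -1 - 1e-9 | mean_ifp_cs > 1e-9))
    usage_error("mean IFP_CS values must lie in [-1, 0]")
  structure(
    data.frame(temperature = temperature, mean_ifp_cs = mean_ifp_cs),
    t_start = t_start,
    class = c("titration_profile", "data.frame")
  )
}

#' MS coefficient: the binding-stability slope
#'
#' The slope of the straight line joining the first and last points of the
#' titration profile:
#' \deqn{MS = \frac{\overline{IFP}_{CS}^{end} - (-1)}{T^{end} - T^{start}}}
#' where the numerator compares the final-step average IFP_CS with the
#' initial-state value of -1, and \eqn{T^{end}} is the last temperature
#' explored (the final executed window for early-terminated runs). MS is 0
#' for a complex whose binding mode is fully retained across the whole ramp
#' (strong binding) and grows as the mode is lost earlier or more completely
#' (weak binding).
#'
#' @param profile A `titration_profile` (or a `ttmd_run`).
#' @return Object of class `ms_coefficient`: list with `value` (K^-1),
#'   `t_start`, `t_end`, `final_mean_ifp`.
#' @export
ms_coefficient <- function(profile) {
  if (inherits(profile, "ttmd_run")) profile <- titration_profile(profile)
  n <- nrow(profile)
  t_start <- profile$temperature[1]
  t_end <- profile$temperature[n]
  if (t_end <= t_start)
    usage_error("MS slope undefined: final temperature equals starting temperature")
  final_mean <- profile$mean_ifp_cs[n]
  structure(
    list(value = (final_mean - (-1)) / (t_end - t_start),
         t_start = t_start, t_end = t_end, final_mean_ifp = final_mean),
    class = "ms_coefficient"
  )
}

#' @export
print.ms_coefficient <- function(x, ...) {
  cat(sprintf("MS = %.6f K^-1  (IFP_CS %.4f at %g K, from -1 at %g K)\n",
              x$value, x$final_mean_ifp, x$t_end, x$t_start))
  invisible(x)
}

# --- per-residue nonbonded energy decomposition ----------------------------

check_parameters <- function(system) {
  a <- system$atoms
  for (col in c("charge", "sigma", "epsilon"))
    if (is.null(a[[col]])) a[[col]] <- NA_real_
  need <- a$role %in% c("protein", "ligand", "ion")
  bad <- need & (is.na(a$charge) | is.na(a$sigma) | is.na(a$epsilon))
  if (any(bad))
    parameter_error(paste0(
      "missing charge/LJ parameters for atom(s): ",
      paste(utils::head(paste0(a$name[bad], "/", a$key[bad]), 10), collapse = ", "),
      if (sum(bad) > 10) sprintf(" (and %d more)", sum(bad) - 10) else ""
    ))
}

#' Per-residue protein-ligand interaction energy of one frame
#'
#' Pairwise nonbonded energies between the ligand and each protein-side
#' residue: Lennard-Jones
#' \eqn{4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6]} with Lorentz-Berthelot
#' combination rules, and plain Coulomb \eqn{k\,q_iq_j/r}
#' (k = 332.06 kcal A / mol / e^2). Pairs beyond `cutoff` contribute
#' nothing; 9 A matches the common Lennard-Jones simulation cutoff.
#'
#' @param frame n x 3 coordinate matrix.
#' @param system A [molecular_system()] carrying per-atom `charge`, `sigma`
#'   (A) and `epsilon` (kcal/mol).
#' @param cutoff Pair cutoff, Angstrom. Default 9.
#' @return data.frame with one row per residue within range: `residue`,
#'   `elj`, `eelec`, `etotal` (kcal/mol).
#' @export
per_residue_energy <- function(frame, system, cutoff = 9.0) {
  check_parameters(system)
  a <- system$atoms
  xyz <- if (is.matrix(frame)) frame else as.matrix(frame)
  lig <- system$ligand_idx
  res_keys <- fingerprint_residues(system)

  lx <- xyz[lig, , drop = FALSE]
  out <- lapply(res_keys, function(k) {
    ri <- which(a$key == k & a$role != "ligand")
    D <- pair_dists(xyz[ri, , drop = FALSE], lx)
    within <- D <= cutoff & D > 0
    if (!any(within)) return(NULL)
    sig <- outer(a$sigma[ri], a$sigma[lig], "+") / 2
    eps <- sqrt(outer(a$epsilon[ri], a$epsilon[lig]))
    qq <- outer(a$charge[ri], a$charge[lig])
    sr6 <- (sig[within] / D[within])^6
    data.frame(
      residue = k,
      elj = sum(4 * eps[within] * (sr6^2 - sr6)),
      eelec = sum(COULOMB_K * qq[within] / D[within])
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(residue = character(), elj = numeric(), eelec = numeric())
  out$etotal <- out$elj + out$eelec
  rownames(out) <- NULL
  out
}

#' Time-resolved per-residue energy decomposition of a run
#'
#' @param run A `ttmd_run` with stored trajectories.
#' @param system The system the run was performed on.
#' @param cutoff Pair cutoff, Angstrom.
#' @param stride Evaluate every `stride`-th frame.
#' @return Long data.frame: `time`, `temperature`, `window`, `residue`,
#'   `elj`, `eelec`, `etotal`.
#' @export
energy_series <- function(run, system, cutoff = 9.0, stride = 1L) {
  rows <- list()
  for (s in run$steps) {
    if (is.null(s$trajectory))
      usage_error("run was executed without stored trajectories; rerun with store_trajectories = TRUE")
    traj <- s$trajectory
    for (i in seq(1, length(traj), by = stride)) {
      e <- per_residue_energy(traj$coords[[i]], system, cutoff)
      if (!nrow(e)) next
      e$time <- traj$time[i]; e$temperature <- s$temperature; e$window <- s$window
      rows[[length(rows) + 1]] <- e
    }
  }
  out <- do.call(rbind, rows)
  out %||% data.frame(residue = character(), elj = numeric(), eelec = numeric(),
                      etotal = numeric(), time = numeric(),
                      temperature = numeric(), window = integer())
}

#' Most contacted residues of a run
#'
#' Residues ranked by the number of scored frames in which they carry any
#' fingerprint bit; ties break by residue (file) order.
#'
#' @param run A `ttmd_run`.
#' @param n Number of residues to return (default 25).
#' @return Character vector of residue keys, most contacted first.
#' @export
top_contacted_residues <- function(run, n = 25) {
  counts <- Reduce(`+`, lapply(run$steps, function(s)
    attr(s$similarity, "contact_counts")))
  counts <- counts[counts > 0]
  if (!length(counts)) return(character())
  ord <- order(-counts, seq_along(counts))
  names(counts)[ord][seq_len(min(n, length(counts)))]
}

# --- plots -----------------------------------------------------------------

#' Render the three standard TTMD diagnostic plots
#'
#' Writes (1) the titration profile with the interpolating first-to-last
#' line and its slope (the MS coefficient) in the legend, (2) a
#' time-resolved heat map of the per-residue interaction energy for the
#' most contacted residues, and (3) ligand / backbone RMSD together with
#' IFP_CS against simulation time.
#'
#' @param run A `ttmd_run` with stored trajectories.
#' @param system The system the run was performed on.
#' @param out_dir Output directory (created if missing).
#' @param n_residues Number of residues in the heat map (default 25).
#' @param energy_stride,rmsd_stride Frame strides for the heavier panels.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Named character vector of the three file paths.
#' @export
render_plots <- function(run, system, out_dir, n_residues = 25,
                         energy_stride = 1L, rmsd_stride = 1L,
                         width = 7, height = 5, dpi = 150) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- titration_profile(run)
  ms <- ms_coefficient(profile)
  paths <- c(
    titration = file.path(out_dir, "titration_profile.png"),
    energy = file.path(out_dir, "energy_heatmap.png"),
    rmsd = file.path(out_dir, "rmsd_ifpcs.png")
  )

  slope_label <- sprintf("MS = %.4f K^-1", ms$value)
  endpoints <- profile[c(1, nrow(profile)), ]
  p1 <- ggplot2::ggplot(profile, ggplot2::aes(x = temperature, y = mean_ifp_cs)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = endpoints,
                       ggplot2::aes(colour = slope_label), linetype = 2) +
    ggplot2::scale_colour_manual(values = stats::setNames("firebrick", slope_label),
                                 name = NULL) +
    ggplot2::labs(x = "Temperature (K)", y = "Mean IFP_CS",
                  title = "Titration profile") +
    ggplot2::ylim(-1, 0) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
  ggplot2::ggsave(paths["titration"], p1, width = width, height = height,
                  dpi = dpi)

  top <- top_contacted_residues(run, n_residues)
  en <- energy_series(run, system, stride = energy_stride)
  # absolute time across chained windows
  en <- en[en$residue %in% top, , drop = FALSE]
  if (nrow(en)) {
    wl <- run$ramp$window_length
    en$abs_time <- (en$window - 1) * wl + en$time
    en$residue <- factor(en$residue, levels = rev(top))
    p2 <- ggplot2::ggplot(en, ggplot2::aes(x = abs_time, y = residue,
                                           fill = etotal)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                    high = "firebrick", midpoint = 0,
                                    name = "E (kcal/mol)") +
      ggplot2::labs(x = "Time (ns)", y = NULL,
                    title = "Per-residue interaction energy") +
      ggplot2::theme_bw()
  } else {
    p2 <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no residues in range") +
      ggplot2::theme_void()
  }
  ggplot2::ggsave(paths["energy"], p2, width = width, height = height, dpi = dpi)

  wl <- run$ramp$window_length
  series <- do.call(rbind, lapply(run$steps, function(s) {
    if (is.null(s$trajectory))
      usage_error("run was executed without stored trajectories")
    lig <- rmsd_series(s$trajectory, system, "backbone", "ligand",
                       stride = rmsd_stride)
    bb <- rmsd_series(s$trajectory, system, "backbone", "backbone",
                      stride = rmsd_stride)
    cs <- s$similarity
    abs_t <- (s$window - 1) * wl + lig$time
    rbind(
      data.frame(time = abs_t, value = lig$rmsd, what = "Ligand RMSD (A)"),
      data.frame(time = abs_t, value = bb$rmsd, what = "Backbone RMSD (A)"),
      data.frame(time = (s$window - 1) * wl + cs$time, value = cs$ifp_cs,
                 what = "IFP_CS")
    )
  }))
  p3 <- ggplot2::ggplot(series, ggplot2::aes(x = time, y = value,
                                             colour = what)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (ns)", y = NULL,
                  title = "RMSD and IFP_CS evolution") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  ggplot2::ggsave(paths["rmsd"], p3, width = width, height = height, dpi = dpi)

  attr(paths, "slope_label") <- slope_label
  paths
}
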