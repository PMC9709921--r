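# Synthetic systems and scripted trajectories: a toy binding pocket whose
# reference pose exercises most fingerprint channels, plus a deterministic
# engine that emulates fingerprint dynamics (not forces) so the whole
# pipeline is testable without molecular dynamics.

LJ_BY_ELEMENT <- c(C = 3.40, N = 3.25, O = 2.96, S = 3.56, H = 2.50, ZN = 1.96)
EPS_BY_ELEMENT <- c(C = 0.086, N = 0.170, O = 0.210, S = 0.250, H = 0.015,
                    ZN = 0.0125)

toy_atom <- function(name, element, resno, resid, xyz, role, charge,
                     chain = "A") {
  data.frame(name = name, element = element, chain = chain, resno = resno,
             icode = "", resid = resid, x = xyz[1], y = xyz[2], z = xyz[3],
             role = role, charge = charge, stringsAsFactors = FALSE)
}

# Backbone placed around `ca`, heavy-atom side chain along `u` (unit vector)
# with the terminal atom landing where the pocket design wants the contact.
toy_backbone <- function(resno, resid, ca, charge_ca = 0.1) {
  rbind(
    toy_atom("N", "N", resno, resid, ca + c(-0.8, 1.2, 0), "protein", -0.40),
    toy_atom("CA", "C", resno, resid, ca, "protein", charge_ca),
    toy_atom("C", "C", resno, resid, ca + c(1.0, 1.0, 0), "protein", 0.50),
    toy_atom("O", "O", resno, resid, ca + c(1.6, 2.1, 0), "protein", -0.50)
  )
}

#' Build the deterministic toy protein-ligand complex
#'
#' A nine-residue binding pocket plus a catalytic zinc around a small
#' engineered ligand (benzene core carrying a carboxylate, an ammonium and a
#' hydroxyl). In the reference pose the complex forms hydrophobic, aromatic
#' face-to-face, hydrogen-bond (both directions), salt-bridge (both
#' directions) and metal-coordination contacts, so the reference fingerprint
#' sets bits in 7 of the 8 channels. Per-atom charges and Lennard-Jones
#' parameters are included for the energy decomposition.
#'
#' The contact geometry is fixed; `seed` only perturbs the positions of the
#' non-contacting filler residues slightly, so equal seeds give identical
#' systems and the engineered contacts never depend on the seed.
#'
#' @param seed Integer seed.
#' @return A [molecular_system()] with `charge`, `sigma`, `epsilon` filled.
#' @export
make_toy_complex <- function(seed = 1L) {
  ring <- function(centre, radius = 1.39, z = 0) {
    t(vapply(0:5, function(k) {
      a <- k * pi / 3
      centre + c(radius * cos(a), radius * sin(a), z)
    }, numeric(3)))
  }

  # --- ligand: benzene + carboxylate + ammonium + hydroxyl + methyl -------
  lr <- ring(c(0, 0, 0))
  lig <- rbind(
    toy_atom("C1", "C", 1, "LIG", lr[1, ], "ligand", -0.05, "L"),
    toy_atom("C2", "C", 1, "LIG", lr[2, ], "ligand", 0.10, "L"),
    toy_atom("C3", "C", 1, "LIG", lr[3, ], "ligand", -0.05, "L"),
    toy_atom("C4", "C", 1, "LIG", lr[4, ], "ligand", -0.05, "L"),
    toy_atom("C5", "C", 1, "LIG", lr[5, ], "ligand", -0.05, "L"),
    toy_atom("C6", "C", 1, "LIG", lr[6, ], "ligand", -0.05, "L"),
    toy_atom("C7", "C", 1, "LIG", c(2.89, 0, 0), "ligand", 0.70, "L"),
    toy_atom("O1", "O", 1, "LIG", c(3.54, 1.05, 0), "ligand", -0.80, "L"),
    toy_atom("O2", "O", 1, "LIG", c(3.54, -1.05, 0), "ligand", -0.80, "L"),
    toy_atom("C8", "C", 1, "LIG", c(-2.89, 0, 0), "ligand", 0.20, "L"),
    toy_atom("N1", "N", 1, "LIG", c(-3.56, 1.08, 0), "ligand", 1.00, "L"),
    toy_atom("O3", "O", 1, "LIG", c(1.375, 2.382, 0), "ligand", -0.40, "L"),
    toy_atom("C9", "C", 1, "LIG", c(-1.445, -2.503, 0), "ligand", -0.10, "L")
  )

  # --- contact residues ---------------------------------------------------
  # LEU 1: hydrophobic floor under the ligand ring (CD1 3.2 A below).
  leu <- rbind(
    toy_backbone(1, "LEU", c(0, 0, -7.7)),
    toy_atom("CB", "C", 1, "LEU", c(0, 0, -6.2), "protein", -0.06),
    toy_atom("CG", "C", 1, "LEU", c(0, 0, -4.7), "protein", -0.06),
    toy_atom("CD1", "C", 1, "LEU", c(0, 0, -3.2), "protein", -0.09),
    toy_atom("CD2", "C", 1, "LEU", c(1.45, 0, -5.1), "protein", -0.09)
  )

  # PHE 2: face-to-face stack 3.6 A above the ligand ring.
  pr <- ring(c(0, 0, 3.6))
  phe_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  pr <- pr[c(1, 2, 6, 3, 5, 4), ]  # CG, CD1, CD2, CE1, CE2, CZ
  phe <- toy_backbone(2, "PHE", c(3.7, 0, 5.2))
  for (i in seq_along(phe_names))
    phe <- rbind(phe, toy_atom(phe_names[i], "C", 2, "PHE", pr[i, ],
                               "protein", -0.06))
  phe <- rbind(phe, toy_atom("CB", "C", 2, "PHE", c(2.6, 0, 4.2),
                             "protein", -0.06))

  # SER 3: hydroxyl H-bond partner of the ligand hydroxyl (2.8 A).
  og <- c(1.375, 5.182, 0)
  ser <- rbind(
    toy_backbone(3, "SER", og + c(0.4, 2.8, 0.6)),
    toy_atom("CB", "C", 3, "SER", og + c(0.2, 1.4, 0.3), "protein", 0.05),
    toy_atom("OG", "O", 3, "SER", og, "protein", -0.60)
  )

  # LYS 4: ammonium salt bridge to the ligand carboxylate (NZ-O1 2.8 A).
  uk <- unit(c(1, 0.8, 0.4))
  nz <- c(3.54, 1.05, 0) + 2.8 * uk
  lys <- rbind(
    toy_backbone(4, "LYS", nz + 6.0 * uk),
    toy_atom("CB", "C", 4, "LYS", nz + 4.5 * uk, "protein", -0.05),
    toy_atom("CG", "C", 4, "LYS", nz + 3.0 * uk, "protein", -0.05),
    toy_atom("CE", "C", 4, "LYS", nz + 1.5 * uk, "protein", 0.20),
    toy_atom("NZ", "N", 4, "LYS", nz, "protein", 1.00)
  )

  # ASP 5: carboxylate salt bridge to the ligand ammonium (OD1-N1 2.8 A).
  ua <- unit(c(-1, 0.8, 0.4))
  od1 <- c(-3.56, 1.08, 0) + 2.8 * ua
  cg <- od1 + c(-1.1, 0.55, 0.2)
  asp <- rbind(
    toy_backbone(5, "ASP", cg + c(-2.7, -1.6, 0.3)),
    toy_atom("CB", "C", 5, "ASP", cg + c(-1.35, -0.8, 0.15), "protein", -0.10),
    toy_atom("CG", "C", 5, "ASP", cg, "protein", 0.70),
    toy_atom("OD1", "O", 5, "ASP", od1, "protein", -0.80),
    toy_atom("OD2", "O", 5, "ASP", cg + c(-0.6, 1.1, 0), "protein", -0.80)
  )

  # ZN 6: catalytic zinc coordinating the second carboxylate oxygen (2.15 A).
  zn <- toy_atom("ZN", "ZN", 6, "ZN", c(3.54, -1.45, -2.1), "ion", 2.00)

  # --- filler residues (seed-jittered, out of interaction range) ----------
  fill <- with_seed(seed, {
    jit <- function() stats::rnorm(3, sd = 0.05)
    gly <- toy_backbone(7, "GLY", c(0, -9.5, 5) + jit(), charge_ca = 0.0)
    ala_ca <- c(-8, -6.5, 3) + jit()
    ala <- rbind(toy_backbone(8, "ALA", ala_ca),
                 toy_atom("CB", "C", 8, "ALA", ala_ca + c(0, -1.0, 1.1),
                          "protein", -0.09))
    tyr_c <- c(9.5, -7.5, -4) + jit()
    tr <- ring(tyr_c)
    tyr <- toy_backbone(9, "TYR", tyr_c + c(3.2, 1.5, 1.8))
    tnames <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    tperm <- c(1, 2, 6, 3, 5, 4)
    for (i in seq_along(tnames))
      tyr <- rbind(tyr, toy_atom(tnames[i], "C", 9, "TYR", tr[tperm[i], ],
                                 "protein", -0.06))
    tyr <- rbind(tyr, toy_atom("OH", "O", 9, "TYR",
                               tr[tperm[6], ] + c(-1.36, 0, 0), "protein", -0.55))
    glu_cd <- c(-9.5, -7, -5) + jit()
    glu <- rbind(
      toy_backbone(10, "GLU", glu_cd + c(-2.9, -1.8, 0.4)),
      toy_atom("CB", "C", 10, "GLU", glu_cd + c(-1.9, -1.2, 0.3), "protein", -0.10),
      toy_atom("CG", "C", 10, "GLU", glu_cd + c(-0.95, -0.6, 0.15), "protein", -0.10),
      toy_atom("CD", "C", 10, "GLU", glu_cd, "protein", 0.70),
      toy_atom("OE1", "O", 10, "GLU", glu_cd + c(0.6, 1.1, 0), "protein", -0.80),
      toy_atom("OE2", "O", 10, "GLU", glu_cd + c(1.1, -0.6, 0), "protein", -0.80)
    )
    rbind(gly, ala, tyr, glu)
  })

  atoms <- rbind(leu, phe, ser, lys, asp, zn, fill, lig)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$sigma <- LJ_BY_ELEMENT[atoms$element]
  atoms$epsilon <- EPS_BY_ELEMENT[atoms$element]
  molecular_system(atoms)
}

#' Define a synthetic trajectory scenario
#'
#' Scenarios script the fingerprint dynamics the real protocol must
#' discriminate: `stable` keeps the bound pose under thermal jitter that
#' grows linearly with temperature; `unbinder` is identical until a scripted
#' window, at which the ligand is translated out of the pocket along an exit
#' vector and every contact is lost; `partial_unfold` keeps the ligand bound
#' but displaces the backbone beyond the fold threshold in late windows.
#'
#' @param kind `"stable"`, `"unbinder"` or `"partial_unfold"`.
#' @param unbind_window Window (1-based) at which the unbinder exits.
#' @param sigma0 Thermal jitter at 300 K, Angstrom per coordinate; the
#'   schedule is `sigma0 * T / 300` (monotone in temperature).
#' @param exit_vector Direction of ligand exit (normalised internally).
#' @param displacement Exit translation, Angstrom (default 20, beyond every
#'   interaction cutoff).
#' @param frames_per_window Saved frames per window (default 100).
#' @param unfold_windows Windows whose backbone is displaced
#'   (`partial_unfold`); default: the last two of the ramp.
#' @param unfold_shift Backbone displacement, Angstrom.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(kind = c("stable", "unbinder", "partial_unfold"),
                               unbind_window = 3L, sigma0 = 0.3,
                               exit_vector = c(1, 0, 0), displacement = 20,
                               frames_per_window = 100L,
                               unfold_windows = NULL, unfold_shift = 6) {
  kind <- match.arg(kind)
  if (sigma0 < 0) config_error("sigma0 must be >= 0")
  if (unbind_window < 1) config_error("unbind_window must be >= 1")
  structure(
    list(kind = kind, unbind_window = as.integer(unbind_window),
         sigma0 = sigma0, exit_vector = unit(exit_vector),
         displacement = displacement,
         frames_per_window = as.integer(frames_per_window),
         unfold_windows = unfold_windows, unfold_shift = unfold_shift),
    class = "synthetic_scenario"
  )
}

#' Synthetic MD engine
#'
#' Implements the engine contract ([ttmd_engine()]) with scripted frames:
#' all frames are drawn as independent Gaussian displacements about the
#' system's reference pose (thermal fluctuation about the bound minimum -
#' the generator mimics fingerprint dynamics, not forces), with the
#' scenario's scripted events applied on top. Identical
#' (system, temperature, length, seed) always yields identical frames.
#'
#' @param system The [molecular_system()] whose reference coordinates define
#'   the bound pose.
#' @param scenario A [synthetic_scenario()].
#' @param ramp The [build_ramp()] the engine will be driven with (used to map
#'   a window temperature to its index for scripted events).
#' @return A [ttmd_engine()].
#' @export
synthetic_engine <- function(system, scenario, ramp) {
  ref <- system_coords(system)
  lig_idx <- system$ligand_idx
  bb_idx <- which(system$atoms$role == "protein" &
                  system$atoms$name %in% c("N", "CA", "C", "O"))
  # displace only the upper half of the chain: a whole-backbone shift would
  # be a rigid motion that superposition removes, i.e. not an unfold
  bb_resno <- system$atoms$resno[bb_idx]
  unfold_idx <- bb_idx[bb_resno > stats::median(unique(bb_resno))]
  n_at <- nrow(ref)
  if (!is.null(scenario$unbind_window) && scenario$kind == "unbinder" &&
      scenario$unbind_window > length(ramp$temperatures))
    config_error("unbind_window lies beyond the ramp")
  unfold_windows <- scenario$unfold_windows %||%
    utils::tail(seq_along(ramp$temperatures), 2)

  window_index <- function(temperature) {
    w <- match(temperature, ramp$temperatures)
    if (is.na(w))
      w <- as.integer(round((temperature - ramp$t_start) / ramp$increment)) + 1L
    w
  }

  make_frames <- function(n, sigma, seed, offset_lig = NULL, offset_bb = NULL) {
    with_seed(seed, lapply(seq_len(n), function(i) {
      fr <- ref + matrix(stats::rnorm(3 * n_at, sd = sigma), ncol = 3)
      if (!is.null(offset_lig))
        fr[lig_idx, ] <- sweep(fr[lig_idx, , drop = FALSE], 2, offset_lig, "+")
      if (!is.null(offset_bb))
        fr[unfold_idx, ] <- sweep(fr[unfold_idx, , drop = FALSE], 2, offset_bb, "+")
      fr
    }))
  }

  ttmd_engine(
    name = paste0("synthetic:", scenario$kind),
    equilibrate = function(system, seed) {
      n <- 5L
      coords <- make_frames(n, scenario$sigma0 * 0.5, seed)
      coords[[n]] <- ref  # fully relaxed final equilibration frame
      trajectory(coords, time = 0.1 * seq_len(n) - 0.1,
                 temperature = ramp$t_start,
                 provenance = list(engine = "synthetic", stage = "equilibration"))
    },
    run_window = function(system, start_coords, temperature, length_ns, seed) {
      w <- window_index(temperature)
      sigma <- scenario$sigma0 * temperature / 300
      offset_lig <- NULL
      offset_bb <- NULL
      if (scenario$kind == "unbinder" && w >= scenario$unbind_window)
        offset_lig <- scenario$displacement * scenario$exit_vector
      if (scenario$kind == "partial_unfold" && w %in% unfold_windows)
        offset_bb <- c(0, 0, scenario$unfold_shift)
      n <- scenario$frames_per_window
      dt <- length_ns / n
      trajectory(make_frames(n, sigma, seed, offset_lig, offset_bb),
                 time = dt * seq_len(n), temperature = temperature,
                 provenance = list(engine = "synthetic", window = w,
                                   kind = scenario$kind, seed = seed))
    }
  )
}

#' Write toy-complex fixture files
#'
#' Emits the complex as a PDB file and its per-atom charges / Lennard-Jones
#' parameters as a tab-separated parameter file (`serial`, `name`, `charge`,
#' `sigma`, `epsilon`), plus optionally a short multi-model PDB trajectory.
#'
#' @param system A system with parameters (e.g. [make_toy_complex()]).
#' @param dir Output directory.
#' @param trajectory Optional [trajectory()] to write alongside.
#' @return Named character vector of the written paths.
#' @export
write_fixtures <- function(system, dir, trajectory = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(structure = file.path(dir, "complex.pdb"),
             parameters = file.path(dir, "parameters.tsv"))
  write_structure(system, paths["structure"])
  utils::write.table(
    system$atoms[, c("serial", "name", "charge", "sigma", "epsilon")],
    paths["parameters"], sep = "\t", row.names = FALSE, quote = FALSE
  )
  if (!is.null(trajectory)) {
    paths["trajectory"] <- file.path(dir, "trajectory.pdb")
    write_trajectory(trajectory, system, paths["trajectory"])
  }
  paths
}

#' Attach per-atom parameters from a parameter file
#'
#' @param system A [molecular_system()].
#' @param path Tab-separated file with columns `serial`, `charge`, `sigma`,
#'   `epsilon` (as written by [write_fixtures()]).
#' @return The system with `charge`, `sigma`, `epsilon` columns filled.
#' @export
attach_parameters <- function(system, path) {
  if (!file.exists(path)) parameter_error(paste0("no such parameter file: ", path))
  par <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("serial", "charge", "sigma", "epsilon")
  if (!all(need %in% names(par)))
    parameter_error("parameter file lacks serial/charge/sigma/epsilon columns")
  m <- match(system$atoms$serial, par$serial)
  if (anyNA(m)) {
    missing <- system$atoms$serial[is.na(m)]
    parameter_error(paste0("no parameters for atom serial(s): ",
                           paste(utils::head(missing, 10), collapse = ", ")))
  }
  system$atoms$charge <- par$charge[m]
  system$atoms$sigma <- par$sigma[m]
  system$atoms$epsilon <- par$epsilon[m]
  system
}
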