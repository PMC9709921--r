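# Geometric substrate: molecular systems, trajectory frames, selections,
# least-squares superposition and RMSD series.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)
WATER_NAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "SPC")
METAL_NAMES <- c("ZN", "MG", "MN", "CA", "FE", "NA", "K")
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Construct a molecular system from an atom table
#'
#' A molecular system is the static topology every other stage consumes: an
#' ordered atom table partitioned into protein, ligand, water and ion roles,
#' plus a derived residue index whose order fixes the fingerprint channel
#' layout for the whole analysis.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `chain`,
#'   `resno`, `icode`, `resid`, `x`, `y`, `z`, `role`, and optionally
#'   `charge`, `sigma`, `epsilon` (per-atom Lennard-Jones parameters,
#'   Angstrom / kcal/mol).
#' @return An object of class `molecular_system` with elements `atoms`
#'   (the validated table), `residues` (one row per residue, file order) and
#'   `ligand_idx` (row indices of ligand atoms).
#' @export
molecular_system <- function(atoms) {
  required <- c("serial", "name", "element", "chain", "resno", "icode",
                "resid", "x", "y", "z", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    format_error(paste0("atom table lacks columns: ",
                        paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(atoms$serial))
    format_error("duplicate atom serial numbers")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    format_error("non-finite atom coordinates")
  ok_roles <- c("protein", "ligand", "water", "ion")
  if (!all(atoms$role %in% ok_roles))
    format_error(paste0("unknown atom role(s): ",
                        paste(unique(setdiff(atoms$role, ok_roles)), collapse = ", ")))
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"sigma" %in% names(atoms)) atoms$sigma <- NA_real_
  if (!"epsilon" %in% names(atoms)) atoms$epsilon <- NA_real_
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)

  residues <- atoms[!duplicated(atoms$key),
                    c("key", "chain", "resno", "icode", "resid", "role")]
  rownames(residues) <- NULL

  if (!any(residues$role == "protein"))
    format_error("system has no protein residues")
  if (!any(atoms$role == "ligand"))
    format_error("system has no ligand atoms")

  structure(
    list(atoms = atoms, residues = residues,
         ligand_idx = which(atoms$role == "ligand")),
    class = "molecular_system"
  )
}

residue_key <- function(chain, resno, icode) {
  icode[is.na(icode) | icode == " "] <- ""
  paste(chain, resno, icode, sep = ":")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system>\n")
  cat("  atoms:   ", nrow(x$atoms), "\n")
  cat("  residues:", nrow(x$residues),
      sprintf("(%d protein, %d water, %d ion)\n",
              sum(x$residues$role == "protein"),
              sum(x$residues$role == "water"),
              sum(x$residues$role == "ion")))
  cat("  ligand:  ", length(x$ligand_idx), "atoms,",
      paste(unique(x$atoms$resid[x$ligand_idx]), collapse = ","), "\n")
  invisible(x)
}

#' Coordinates of a system as an n x 3 matrix
#' @param system A `molecular_system`.
#' @return Numeric matrix of reference coordinates, Angstrom.
#' @export
system_coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' Fingerprint residue order of a system
#'
#' Protein residues and metal ions, in structure-file order. This order
#' defines the fingerprint element layout; waters are environment only and
#' carry no fingerprint row.
#' @param system A `molecular_system`.
#' @return Character vector of residue keys (`chain:resno:icode`).
#' @export
fingerprint_residues <- function(system) {
  res <- system$residues
  res$key[res$role %in% c("protein", "ion")]
}

guess_element <- function(name) {
  # Strip digits/primes, take the leading alphabetic token; two-letter
  # elements only when the PDB name starts with a recognised symbol.
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "ZN", "MG", "MN", "FE", "NA", "SE"),
         two, substr(nm, 1, 1))
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), assigns protein / ligand / water /
#' ion roles, keeps the highest-occupancy alternate location, and drops water
#' molecules farther than `water_cutoff` from any ligand atom (waters near
#' the ligand are part of the modelled binding site; bulk water is not).
#'
#' @param path PDB file.
#' @param ligand_selector Residue name of the ligand (e.g. `"LIG"`), or a
#'   list with elements `resid` and/or `chain` for composite selection.
#' @param water_cutoff Angstrom; waters with no atom within this distance of
#'   the ligand are discarded. Default 4.5.
#' @return A [molecular_system()].
#' @export
read_structure <- function(path, ligand_selector, water_cutoff = 4.5) {
  if (!file.exists(path)) format_error(paste0("no such file: ", path))
  # bio3d warns on duplicate serials; we raise a structured error below
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom

  if (anyDuplicated(at$eleno))
    format_error("duplicate atom serial numbers in PDB file")

  # Alternate locations: keep the highest-occupancy copy of each atom.
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    atom_id <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), atom_id), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), ]
  }

  element <- at$elesy
  element[is.na(element) | element == ""] <- guess_element(at$elety[is.na(element) | element == ""])
  element <- toupper(trimws(element))

  chain <- at$chain
  chain[is.na(chain)] <- "A"
  icode <- at$insert
  icode[is.na(icode)] <- ""

  if (is.character(ligand_selector)) ligand_selector <- list(resid = ligand_selector)
  is_lig <- rep(TRUE, nrow(at))
  if (!is.null(ligand_selector$resid))
    is_lig <- is_lig & at$resid %in% ligand_selector$resid
  if (!is.null(ligand_selector$chain))
    is_lig <- is_lig & chain %in% ligand_selector$chain
  if (!any(is_lig))
    selector_error("ligand selector matched no residue in the structure")

  role <- ifelse(is_lig, "ligand",
          ifelse(at$resid %in% WATER_NAMES, "water",
          ifelse(at$resid %in% STANDARD_AA, "protein",
          ifelse(toupper(trimws(at$resid)) %in% METAL_NAMES & element %in% METAL_NAMES,
                 "ion", "other"))))
  if (any(role == "other")) {
    warning("dropping unrecognised residue(s): ",
            paste(unique(at$resid[role == "other"]), collapse = ", "))
    keep <- role != "other"
    at <- at[keep, ]; role <- role[keep]; element <- element[keep]
    chain <- chain[keep]; icode <- icode[keep]
  }

  charge <- suppressWarnings(as.numeric(at$charge))

  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = element,
    chain = chain, resno = at$resno, icode = icode, resid = trimws(at$resid),
    x = at$x, y = at$y, z = at$z, role = role, charge = charge,
    stringsAsFactors = FALSE
  )

  # Retained-water rule: keep only waters near the ligand.
  if (any(atoms$role == "water")) {
    lig_xyz <- as.matrix(atoms[atoms$role == "ligand", c("x", "y", "z")])
    atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
    water_keys <- unique(atoms$key[atoms$role == "water"])
    drop_keys <- Filter(function(k) {
      w_xyz <- as.matrix(atoms[atoms$key == k, c("x", "y", "z")])
      min(pair_dists(w_xyz, lig_xyz)) > water_cutoff
    }, water_keys)
    atoms <- atoms[!(atoms$key %in% drop_keys), ]
    atoms$key <- NULL
  }
  rownames(atoms) <- NULL
  molecular_system(atoms)
}

#' Write a molecular system to a PDB file
#'
#' @param system A `molecular_system`.
#' @param path Output file.
#' @param coords Optional n x 3 matrix replacing the system's reference
#'   coordinates (e.g. one trajectory frame).
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, coords = NULL) {
  a <- system$atoms
  xyz <- if (is.null(coords)) system_coords(system) else coords
  stopifnot(nrow(xyz) == nrow(a))
  het <- a$role %in% c("ligand", "water", "ion")
  args <- list(
    file = path,
    type = ifelse(het, "HETATM", "ATOM"),
    xyz = as.vector(t(xyz)),
    resno = a$resno, resid = a$resid, eleno = a$serial, elety = a$name,
    chain = a$chain, o = rep(1, nrow(a)), b = rep(0, nrow(a)),
    elesy = a$element
  )
  if (any(a$icode != ""))
    args$insert <- ifelse(a$icode == "", " ", a$icode)
  do.call(bio3d::write.pdb, args)
  invisible(path)
}

# All pairwise distances between two coordinate sets (n x 3, m x 3) -> n x m.
pair_dists <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0))
}

#' Construct a trajectory
#'
#' A trajectory is an ordered sequence of coordinate frames for one system,
#' tagged with simulation time and thermostat set-temperature.
#'
#' @param coords List of n_atoms x 3 coordinate matrices, Angstrom.
#' @param time Numeric vector of frame times, ns; strictly increasing.
#' @param temperature Set temperature per frame, K (recycled if scalar).
#' @param provenance Free-form list identifying the producing backend/window.
#' @return Object of class `ttmd_trajectory`.
#' @export
trajectory <- function(coords, time, temperature = NA_real_, provenance = list()) {
  if (!length(coords)) usage_error("trajectory needs at least one frame")
  if (length(time) != length(coords))
    usage_error("one time per frame required")
  if (any(diff(time) <= 0))
    format_error("frame times must be strictly increasing")
  n <- nrow(coords[[1]])
  if (!all(vapply(coords, nrow, 0L) == n))
    format_error("all frames must have the same atom count")
  structure(
    list(coords = coords, time = as.numeric(time),
         temperature = rep_len(as.numeric(temperature), length(coords)),
         provenance = provenance),
    class = "ttmd_trajectory"
  )
}

#' @export
length.ttmd_trajectory <- function(x) length(x$coords)

#' @export
print.ttmd_trajectory <- function(x, ...) {
  cat("<ttmd_trajectory>", length(x), "frames,",
      nrow(x$coords[[1]]), "atoms;",
      sprintf("t = %.3f..%.3f ns\n", x$time[1], x$time[length(x)]))
  invisible(x)
}

#' Read trajectory frames for a system
#'
#' Multi-model PDB is the plain-text interchange format used for fixtures;
#' DCD is accepted for frames produced by a real MD backend.
#'
#' @param system The parent `molecular_system` (atom count check).
#' @param path Trajectory file.
#' @param format `"pdb"` (multi-model) or `"dcd"`; guessed from the extension
#'   by default.
#' @param dt Time between frames, ns (times are not stored in either format).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(system, path, format = c("auto", "pdb", "dcd"), dt = 0.1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  n <- nrow(system$atoms)
  xyz <- if (format == "dcd") {
    bio3d::read.dcd(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n)
    format_error(sprintf("trajectory has %d atoms, system has %d", ncol(xyz) / 3, n))
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  trajectory(coords, time = dt * (seq_along(coords) - 1),
             provenance = list(source = path, format = format))
}

#' Write a trajectory as a multi-model PDB
#' @param traj A `ttmd_trajectory`.
#' @param system Parent system (names/residues for the records).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, system, path) {
  xyz <- do.call(rbind, lapply(traj$coords, function(m) as.vector(t(m))))
  a <- system$atoms
  het <- a$role %in% c("ligand", "water", "ion")
  n <- nrow(a)
  bio3d::write.pdb(
    file = path, type = ifelse(het, "HETATM", "ATOM"), xyz = xyz,
    resno = a$resno, resid = a$resid, eleno = a$serial, elety = a$name,
    chain = a$chain, o = rep(1, n), b = rep(0, n), elesy = a$element
  )
  invisible(path)
}

#' Resolve an atom selection
#'
#' @param system A `molecular_system`.
#' @param selection Integer atom indices, or one of the keywords
#'   `"protein"`, `"backbone"` (protein N/CA/C/O), `"ligand"`
#'   (ligand heavy atoms), `"ligand_all"`, `"calpha"`.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(system, selection) {
  a <- system$atoms
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (!length(idx) || any(idx < 1 | idx > nrow(a)))
      selector_error("numeric selection out of range")
    return(idx)
  }
  idx <- switch(selection,
    protein    = which(a$role == "protein"),
    backbone   = which(a$role == "protein" & a$name %in% c("N", "CA", "C", "O")),
    calpha     = which(a$role == "protein" & a$name == "CA"),
    ligand     = which(a$role == "ligand" & a$element != "H"),
    ligand_all = which(a$role == "ligand"),
    selector_error(paste0("unknown selection keyword: ", selection))
  )
  if (!length(idx)) selector_error(paste0("empty selection: ", selection))
  idx
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation that best map `mobile` onto
#' `reference` over the given atom selection, in the least-squares sense.
#'
#' @param mobile,reference n x 3 coordinate matrices (same atom order).
#' @param selection Atom indices used for the fit (default all).
#' @return List with `rotation` (3 x 3, applied on the right), `translation`
#'   (length-3), `rmsd` (post-fit, over the selection, Angstrom), and
#'   `transform(x)` applying the fit to any coordinate matrix.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3)
    geometry_error("superposition needs at least 3 selection atoms")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    geometry_error("degenerate (collinear or coincident) selection")
  A <- crossprod(Pc, Qc)
  s <- svd(A)
  d <- sign(det(tcrossprod(s$u, s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- qc - as.vector(pc %*% R)
  fitted <- Pc %*% R
  rmsd_val <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(
    rotation = R, translation = translation, rmsd = rmsd_val,
    transform = function(x) sweep(x %*% R, 2, translation, "+")
  )
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b n x 3 matrices in the same atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series over a trajectory
#'
#' Each frame is first superposed on the reference over `fit_selection`
#' (typically the protein backbone) and the RMSD is then measured over
#' `measure_selection` (e.g. ligand heavy atoms). The reference is the first
#' frame of the trajectory unless an explicit coordinate set is supplied.
#'
#' @param traj A `ttmd_trajectory`.
#' @param system The parent system.
#' @param fit_selection,measure_selection Selections as in [select_atoms()].
#' @param reference Optional n x 3 reference coordinates (default frame 1).
#' @param stride Keep every `stride`-th frame (default 1 = every frame).
#' @return data.frame with columns `frame`, `time`, `temperature`, `rmsd`.
#' @export
rmsd_series <- function(traj, system, fit_selection = "backbone",
                        measure_selection = "ligand", reference = NULL,
                        stride = 1L) {
  fit_idx <- select_atoms(system, fit_selection)
  mea_idx <- select_atoms(system, measure_selection)
  ref <- reference %||% traj$coords[[1]]
  frames <- seq(1, length(traj), by = stride)
  vals <- vapply(frames, function(i) {
    fit <- superpose(traj$coords[[i]], ref, fit_idx)
    rmsd(fit$transform(traj$coords[[i]])[mea_idx, , drop = FALSE],
         ref[mea_idx, , drop = FALSE])
  }, 0)
  data.frame(frame = frames, time = traj$time[frames],
             temperature = traj$temperature[frames], rmsd = vals)
}
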