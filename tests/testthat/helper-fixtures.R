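# Shared fixture builders: everything is generated in code at test time.

pdb_line <- function(rec, serial, name, resid, chain, resno, x, y, z,
                     element, occ = 1.00) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, resid, chain, resno, x, y, z, occ, 0, element)
}

# Three-residue peptide + benzene (6 C, 6 H = 12 ligand atoms) + two waters:
# one 3 A from the ligand, one `far_water` A away.
write_toy_pdb <- function(path, far_water = 6) {
  ser <- 0L
  lines <- character()
  add <- function(rec, name, resid, chain, resno, x, y, z, element) {
    ser <<- ser + 1L
    lines <<- c(lines, pdb_line(rec, ser, name, resid, chain, resno,
                                x, y, z, element))
  }
  # minimal peptide backbone, 8 A from the ligand
  for (i in 1:3) {
    base <- c(8, (i - 1) * 4, 0)
    res <- c("ALA", "GLY", "SER")[i]
    add("ATOM", "N", res, "A", i, base[1] - 0.8, base[2] + 1.2, base[3], "N")
    add("ATOM", "CA", res, "A", i, base[1], base[2], base[3], "C")
    add("ATOM", "C", res, "A", i, base[1] + 1.0, base[2] + 1.0, base[3], "C")
    add("ATOM", "O", res, "A", i, base[1] + 1.6, base[2] + 2.1, base[3], "O")
  }
  # benzene ligand at the origin
  for (k in 0:5) {
    a <- k * pi / 3
    add("HETATM", paste0("C", k + 1), "BNZ", "L", 1,
        1.39 * cos(a), 1.39 * sin(a), 0, "C")
  }
  for (k in 0:5) {
    a <- k * pi / 3
    add("HETATM", paste0("H", k + 1), "BNZ", "L", 1,
        2.47 * cos(a), 2.47 * sin(a), 0, "H")
  }
  add("HETATM", "O", "HOH", "W", 1, 1.39 + 3.0, 0, 0, "O")  # 3 A from C1
  add("HETATM", "O", "HOH", "W", 2, 1.39 + far_water, 0, 0, "O")
  writeLines(c(lines, "END"), path)
  path
}

# Assemble a molecular_system straight from atom rows (no file round trip).
test_atom <- function(name, element, resno, resid, x, y, z, role,
                      chain = "A", charge = NA_real_) {
  data.frame(name = name, element = element, chain = chain, resno = resno,
             icode = "", resid = resid, x = x, y = y, z = z, role = role,
             charge = charge, stringsAsFactors = FALSE)
}

build_system <- function(...) {
  atoms <- rbind(...)
  atoms$serial <- seq_len(nrow(atoms))
  molecular_system(atoms)
}

# Building blocks for constructed interaction geometries.
far_gly <- function(base = c(-20, 0, 0), resno = 99) {
  rbind(
    test_atom("N", "N", resno, "GLY", base[1] - 0.8, base[2] + 1.2, base[3], "protein"),
    test_atom("CA", "C", resno, "GLY", base[1], base[2], base[3], "protein"),
    test_atom("C", "C", resno, "GLY", base[1] + 1.0, base[2] + 1.0, base[3], "protein"),
    test_atom("O", "O", resno, "GLY", base[1] + 1.6, base[2] + 2.1, base[3], "protein")
  )
}

benzene <- function(centre = c(0, 0, 0), normal_axis = "z", resid = "BNZ",
                    role = "ligand", resno = 1, chain = "L", prefix = "C",
                    rot = 0) {
  rows <- list()
  for (k in 0:5) {
    a <- k * pi / 3 + rot
    p <- switch(normal_axis,
      z = centre + c(1.39 * cos(a), 1.39 * sin(a), 0),
      y = centre + c(1.39 * cos(a), 0, 1.39 * sin(a)),
      x = centre + c(0, 1.39 * cos(a), 1.39 * sin(a))
    )
    rows[[k + 1]] <- test_atom(paste0(prefix, k + 1), "C", resno, resid,
                               p[1], p[2], p[3], role, chain = chain)
  }
  do.call(rbind, rows)
}

phe_ring <- function(centre, resno = 1, normal_axis = "z", rot = 0) {
  r <- benzene(centre, normal_axis, resid = "PHE", role = "protein",
               resno = resno, chain = "A", rot = rot)
  r$name <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  r
}

fp_channels <- function(sys, ...) {
  fp <- compute_fingerprint(system_coords(sys), sys, perceive_features(sys),
                            interaction_thresholds(...))
  m <- as.matrix(fp)
  colnames(m)[colSums(m) > 0]
}

random_rotation <- function() {
  a <- stats::runif(3, 0, 2 * pi)
  rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3])), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% R, 2, t, "+")

# A tiny single-contact system: one serine whose OG sits `d` Angstrom from a
# ligand hydroxyl; convenient for monotone-translation checks.
make_polar_pair <- function(d = 3.0) {
  build_system(
    test_atom("N", "N", 1, "SER", -0.8, 1.2, -6, "protein"),
    test_atom("CA", "C", 1, "SER", 0, 0, -6, "protein"),
    test_atom("C", "C", 1, "SER", 1.0, 1.0, -6, "protein"),
    test_atom("O", "O", 1, "SER", 1.6, 2.1, -6, "protein"),
    test_atom("CB", "C", 1, "SER", 0, 0, -4.5, "protein"),
    test_atom("OG", "O", 1, "SER", 0, 0, -3.1, "protein"),
    test_atom("C1", "C", 1, "LIG", 0, 0, d - 3.1 + 1.4, "ligand", chain = "L"),
    test_atom("O1", "O", 1, "LIG", 0, 0, d - 3.1, "ligand", chain = "L")
  )
}
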