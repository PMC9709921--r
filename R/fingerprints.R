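# Pharmacophoric feature perception and the r x 8 binary protein-ligand
# interaction fingerprint (one 8-channel row per protein residue / metal ion).

#' Fingerprint channel order
#'
#' HY hydrophobic contact; F2F aromatic face-to-face; E2F aromatic
#' edge-to-face; HB_PD hydrogen bond, protein donor; HB_PA hydrogen bond,
#' protein acceptor; SB_PP salt bridge, protein positive; SB_PN salt bridge,
#' protein negative; MET ligand-metal ionic bond.
#' @export
IFP_CHANNELS <- c("HY", "F2F", "E2F", "HB_PD", "HB_PA", "SB_PP", "SB_PN", "MET")

#' Geometric criteria for interaction detection
#'
#' Defaults mirror widely used open-source interaction-fingerprint toolkits;
#' every value is overridable (distances in Angstrom, angles in degrees).
#'
#' @param ... Named overrides of the defaults: `hy` (4.0), `f2f_dist` (4.5),
#'   `f2f_angle` (30), `e2f_dist` (5.5), `e2f_angle_min` (60),
#'   `e2f_angle_max` (90), `hb_dist` (3.5), `hb_angle` (130), `sb` (4.0),
#'   `met` (2.8), `ring_planarity` (0.1).
#' @return Named list of thresholds.
#' @export
interaction_thresholds <- function(...) {
  th <- list(
    hy = 4.0,
    f2f_dist = 4.5, f2f_angle = 30,
    e2f_dist = 5.5, e2f_angle_min = 60, e2f_angle_max = 90,
    hb_dist = 3.5, hb_angle = 130,
    sb = 4.0,
    met = 2.8,
    ring_planarity = 0.1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown))
    config_error(paste0("unknown interaction threshold(s): ",
                        paste(unknown, collapse = ", ")))
  th[names(dots)] <- dots
  th
}

# --- bond perception -------------------------------------------------------

# Covalent bonds from distance: X-H <= 1.2 A, heavy-heavy <= 1.9 A, only
# within one residue or between consecutive protein residues of a chain
# (peptide bond). Ions form no covalent bonds.
perceive_bonds <- function(system) {
  a <- system$atoms
  n <- nrow(a)
  xyz <- system_coords(system)
  nbrs <- vector("list", n)
  bondable <- which(a$role != "ion")
  if (length(bondable) < 2) return(nbrs)
  D <- pair_dists(xyz[bondable, , drop = FALSE], xyz[bondable, , drop = FALSE])
  is_h <- a$element[bondable] == "H"
  cut <- ifelse(outer(is_h, is_h, "|"), 1.2, 1.9)
  same_res <- outer(a$key[bondable], a$key[bondable], "==")
  both_prot <- outer(a$role[bondable] == "protein", a$role[bondable] == "protein", "&")
  same_chain <- outer(a$chain[bondable], a$chain[bondable], "==")
  adjacent <- abs(outer(a$resno[bondable], a$resno[bondable], "-")) == 1
  allowed <- same_res | (both_prot & same_chain & adjacent)
  hits <- which(D > 0.1 & D <= cut & allowed & upper.tri(D), arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    i <- bondable[hits[r, 1]]; j <- bondable[hits[r, 2]]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  nbrs
}

# Enumerate simple 5- and 6-membered cycles in a neighbour list, candidates
# restricted to `allow`ed atoms. Returns a list of index vectors.
find_rings <- function(nbrs, allow) {
  rings <- list()
  seen <- character()
  nodes <- which(allow)
  nbrs <- lapply(nbrs, function(v) v[allow[v]])
  for (start in nodes) {
    stack <- list(start)
    paths <- list(start)
    while (length(paths)) {
      path <- paths[[1]]; paths <- paths[-1]
      tip <- path[length(path)]
      for (nb in nbrs[[tip]]) {
        if (nb == start && length(path) >= 5) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1]] <- path }
        } else if (nb > start && !nb %in% path && length(path) < 6) {
          paths[[length(paths) + 1]] <- c(path, nb)
        }
      }
    }
  }
  rings
}

ring_plane <- function(xyz) {
  centred <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(centred)
  list(centroid = colMeans(xyz), normal = s$v[, 3],
       max_dev = max(abs(centred %*% s$v[, 3])))
}

# --- feature perception ----------------------------------------------------

PROT_DONOR_SC <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), TRP = "NE1", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), HID = "ND1", HIE = "NE2", HIP = c("ND1", "NE2")
)
PROT_ACCEPTOR_SC <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", MET = "SD", CYS = "SG",
  HIS = c("ND1", "NE2"), HID = "NE2", HIE = "ND1"
)
PROT_CATION_SC <- list(
  LYS = "NZ", ARG = c("CZ", "NE", "NH1", "NH2"), HIP = c("ND1", "NE2")
)
PROT_ANION_SC <- list(
  ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"),
  ASH = c("CG", "OD1", "OD2"), GLH = c("CD", "OE1", "OE2")
)

#' Perceive pharmacophoric features of a system
#'
#' Classifies atoms of the protein side (protein residues + metal ions) and
#' the ligand into hydrophobic atoms, aromatic rings, hydrogen-bond donors
#' and acceptors, charged groups and metal ions. Protein side chains use
#' residue-name templates for polar/ionic roles (ionisation states at pH 7.4:
#' Lys/Arg positive, Asp/Glu negative, His neutral unless named HIP); the
#' ligand is perceived from its covalent-bond graph and any formal charges
#' present in the input. When explicit hydrogens are absent, donors are
#' inferred from free valence.
#'
#' @param system A [molecular_system()].
#' @param thresholds See [interaction_thresholds()] (ring planarity).
#' @return List with elements `protein` and `ligand`, each a feature set with
#'   `hydrophobic`, `rings`, `donors`, `acceptors`, `cations`, `anions`,
#'   `metals`; plus `bonds` (neighbour list).
#' @export
perceive_features <- function(system, thresholds = interaction_thresholds()) {
  a <- system$atoms
  xyz <- system_coords(system)
  nbrs <- perceive_bonds(system)
  elem <- a$element
  unknown <- !elem %in% c("C", "N", "O", "S", "H", "P", METAL_NAMES, "CL", "BR", "F", "I", "SE")
  if (any(unknown))
    warning("atoms with unrecognised element excluded from feature perception: ",
            paste(unique(elem[unknown]), collapse = ", "))

  heavy_nbrs <- lapply(nbrs, function(v) v[elem[v] != "H"])
  h_nbrs <- lapply(nbrs, function(v) v[elem[v] == "H"])
  n_heavy <- vapply(heavy_nbrs, length, 0L)
  n_h <- vapply(h_nbrs, length, 0L)

  hydrophobic_ok <- function(i) {
    elem[i] %in% c("C", "S") &
      vapply(i, function(k) all(elem[nbrs[[k]]] %in% c("C", "H", "S")), TRUE)
  }

  perceive_side <- function(idx, is_protein_side) {
    fs <- list(hydrophobic = integer(), rings = list(), donors = list(),
               acceptors = integer(), cations = list(), anions = list(),
               metals = integer())
    if (!length(idx)) return(fs)
    in_side <- rep(FALSE, nrow(a)); in_side[idx] <- TRUE
    excl <- unknown & in_side

    fs$metals <- idx[a$role[idx] == "ion" & elem[idx] %in% METAL_NAMES]

    hy_cand <- idx[hydrophobic_ok(idx) & !excl[idx]]
    fs$hydrophobic <- hy_cand

    # Aromatic rings: planar 5/6-cycles of C/N/O/S atoms with <= 3 heavy
    # neighbours (sp2-compatible), tested on reference coordinates.
    allow <- in_side & elem %in% c("C", "N", "O", "S") & n_heavy <= 3 & !excl
    for (ring in find_rings(nbrs, allow)) {
      pl <- ring_plane(xyz[ring, , drop = FALSE])
      if (pl$max_dev <= thresholds$ring_planarity)
        fs$rings[[length(fs$rings) + 1]] <- ring
    }

    has_h <- any(elem[idx] == "H")
    add_donor <- function(heavy, hyd = integer()) {
      fs$donors[[length(fs$donors) + 1]] <<- list(heavy = heavy, hydrogens = hyd)
    }

    if (is_protein_side) {
      prot <- idx[a$role[idx] == "protein"]
      if (has_h) {
        for (i in prot[elem[prot] %in% c("N", "O", "S") & n_h[prot] > 0])
          add_donor(i, h_nbrs[[i]])
      } else {
        for (i in prot[a$name[prot] == "N"]) add_donor(i)  # backbone amide
        for (i in prot) {
          sc <- PROT_DONOR_SC[[a$resid[i]]]
          if (!is.null(sc) && a$name[i] %in% sc) add_donor(i)
        }
      }
      acc <- prot[a$name[prot] %in% c("O", "OXT")]  # backbone carbonyl
      for (i in prot) {
        sc <- PROT_ACCEPTOR_SC[[a$resid[i]]]
        if (!is.null(sc) && a$name[i] %in% sc) acc <- c(acc, i)
      }
      fs$acceptors <- unique(acc)
      for (key in unique(a$key[prot])) {
        res_atoms <- prot[a$key[prot] == key]
        rn <- a$resid[res_atoms[1]]
        cat_names <- PROT_CATION_SC[[rn]]
        if (!is.null(cat_names)) {
          grp <- res_atoms[a$name[res_atoms] %in% cat_names]
          if (length(grp)) fs$cations[[length(fs$cations) + 1]] <- grp
        }
        an_names <- PROT_ANION_SC[[rn]]
        if (!is.null(an_names)) {
          grp <- res_atoms[a$name[res_atoms] %in% an_names]
          if (length(grp)) fs$anions[[length(fs$anions) + 1]] <- grp
        }
      }
    } else {
      lig <- idx[elem[idx] != "H"]
      fc <- a$charge[lig]; fc[is.na(fc)] <- 0
      terminal_o <- function(i) elem[i] == "O" & n_heavy[i] == 1 & n_h[i] == 0

      # Anions: carboxylate / phosphate / sulfonate heads and explicit O-.
      anion_atoms <- integer()
      for (i in lig[elem[lig] %in% c("C", "P", "S")]) {
        term <- heavy_nbrs[[i]][terminal_o(heavy_nbrs[[i]])]
        if (length(term) >= 2) {
          fs$anions[[length(fs$anions) + 1]] <- c(i, term)
          anion_atoms <- c(anion_atoms, i, term)
        }
      }
      for (i in lig[fc <= -0.5 & elem[lig] == "O"]) {
        if (!i %in% anion_atoms) {
          fs$anions[[length(fs$anions) + 1]] <- i
          anion_atoms <- c(anion_atoms, i)
        }
      }

      # Cations: explicit N+, guanidinium carbons, terminal aliphatic amines
      # (taken as protonated at physiological pH).
      cation_atoms <- integer()
      for (i in lig[fc >= 0.5 & elem[lig] == "N"]) {
        fs$cations[[length(fs$cations) + 1]] <- i
        cation_atoms <- c(cation_atoms, i)
      }
      for (i in lig[elem[lig] == "C"]) {
        nn <- heavy_nbrs[[i]][elem[heavy_nbrs[[i]]] == "N"]
        if (length(nn) == 3 && !i %in% cation_atoms) {
          fs$cations[[length(fs$cations) + 1]] <- c(i, nn)
          cation_atoms <- c(cation_atoms, i, nn)
        }
      }
      if (!has_h) {
        for (i in lig[elem[lig] == "N" & n_heavy[lig] == 1]) {
          cnb <- heavy_nbrs[[i]]
          if (length(cnb) == 1 && elem[cnb] == "C" &&
              all(elem[heavy_nbrs[[cnb]]] %in% c("C", "N")) &&
              !i %in% cation_atoms) {
            fs$cations[[length(fs$cations) + 1]] <- i
            cation_atoms <- c(cation_atoms, i)
          }
        }
      }

      if (has_h) {
        for (i in lig[elem[lig] %in% c("N", "O", "S") & n_h[lig] > 0])
          add_donor(i, h_nbrs[[i]])
      } else {
        for (i in lig) {
          if (elem[i] == "N" && n_heavy[i] <= 3 && !i %in% anion_atoms) add_donor(i)
          if (elem[i] == "O" && n_heavy[i] == 1 && !i %in% anion_atoms) {
            # hydroxyl, not carbonyl: single bond length to the parent atom
            d <- sqrt(sum((xyz[i, ] - xyz[heavy_nbrs[[i]], ])^2))
            if (d >= 1.3) add_donor(i)
          }
          if (elem[i] == "S" && n_heavy[i] <= 1) add_donor(i)
        }
      }
      acc <- c(lig[elem[lig] == "O"],
               lig[elem[lig] == "N" & n_heavy[lig] <= 2 & !lig %in% cation_atoms],
               lig[elem[lig] == "S" & n_heavy[lig] <= 2])
      fs$acceptors <- unique(acc)
    }
    fs
  }

  prot_idx <- which(a$role %in% c("protein", "ion"))
  lig_idx <- system$ligand_idx
  list(
    protein = perceive_side(prot_idx, TRUE),
    ligand = perceive_side(lig_idx, FALSE),
    bonds = nbrs
  )
}

# --- fingerprint context (per-residue feature index tables) ----------------

#' Precompute the per-residue fingerprint evaluation context
#'
#' Splits the protein-side features by fingerprint residue so that per-frame
#' fingerprint evaluation touches only small index vectors. Build once per
#' system, reuse across frames.
#'
#' @param system A [molecular_system()].
#' @param features Output of [perceive_features()].
#' @param thresholds See [interaction_thresholds()].
#' @return Object of class `fingerprint_context`.
#' @export
fingerprint_context <- function(system, features,
                                thresholds = interaction_thresholds()) {
  a <- system$atoms
  res_keys <- fingerprint_residues(system)
  pf <- features$protein
  lf <- features$ligand

  key_of <- a$key
  per_res <- lapply(res_keys, function(k) {
    list(
      atoms = which(key_of == k),
      hydrophobic = pf$hydrophobic[key_of[pf$hydrophobic] == k],
      rings = Filter(function(r) key_of[r[1]] == k, pf$rings),
      donors = Filter(function(d) key_of[d$heavy] == k, pf$donors),
      acceptors = pf$acceptors[key_of[pf$acceptors] == k],
      cation_atoms = unique(unlist(Filter(function(g) key_of[g[1]] == k,
                                          pf$cations))) %||% integer(),
      anion_atoms = unique(unlist(Filter(function(g) key_of[g[1]] == k,
                                         pf$anions))) %||% integer(),
      metals = pf$metals[key_of[pf$metals] == k]
    )
  })
  names(per_res) <- res_keys

  lig <- list(
    atoms = system$ligand_idx,
    heavy = system$ligand_idx[a$element[system$ligand_idx] != "H"],
    hydrophobic = lf$hydrophobic,
    rings = lf$rings,
    donors = lf$donors,
    acceptors = lf$acceptors,
    cation_atoms = unique(unlist(lf$cations)) %||% integer(),
    anion_atoms = unique(unlist(lf$anions)) %||% integer()
  )

  structure(
    list(residues = per_res, ligand = lig, thresholds = thresholds,
         n_res = length(res_keys), residue_order = res_keys,
         prefilter = max(unlist(thresholds[c("hy", "f2f_dist", "e2f_dist",
                                             "hb_dist", "sb", "met")])) + 3.0),
    class = "fingerprint_context"
  )
}

# Minimum squared distance between two index sets; Inf when either is empty.
min_d2 <- function(xyz, i, j) {
  if (!length(i) || !length(j)) return(Inf)
  a <- xyz[i, , drop = FALSE]
  b <- xyz[j, , drop = FALSE]
  m <- tcrossprod(a, b)
  m <- (rowSums(a * a) - 2 * m) + rep(rowSums(b * b), each = length(i))
  max(min(m), 0)
}

min_dist <- function(xyz, i, j) sqrt(min_d2(xyz, i, j))

# Squared distances from one point to an index set.
point_d2 <- function(xyz, p, j) {
  dx <- xyz[j, 1] - p[1]; dy <- xyz[j, 2] - p[2]; dz <- xyz[j, 3] - p[3]
  dx * dx + dy * dy + dz * dz
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

hb_match <- function(xyz, donors, acceptors, th) {
  if (!length(acceptors)) return(FALSE)
  hb2 <- th$hb_dist^2
  for (d in donors) {
    dd <- point_d2(xyz, xyz[d$heavy, ], acceptors)
    hits <- which(dd <= hb2)
    if (!length(hits)) next
    if (!length(d$hydrogens)) return(TRUE)
    for (acc in acceptors[hits]) {
      for (h in d$hydrogens) {
        ang <- angle_deg(xyz[d$heavy, ] - xyz[h, ], xyz[acc, ] - xyz[h, ])
        if (ang >= th$hb_angle) return(TRUE)
      }
    }
  }
  FALSE
}

# Ring centroid and plane normal per frame (Newell's method: exact on planar
# rings, a stable area-weighted estimate on thermally distorted ones).
ring_geoms <- function(xyz, rings) {
  lapply(rings, function(r) {
    p <- xyz[r, , drop = FALSE]
    centroid <- colMeans(p)
    q <- p[c(seq_len(nrow(p))[-1], 1), , drop = FALSE]
    n <- c(sum((p[, 2] - q[, 2]) * (p[, 3] + q[, 3])),
           sum((p[, 3] - q[, 3]) * (p[, 1] + q[, 1])),
           sum((p[, 1] - q[, 1]) * (p[, 2] + q[, 2])))
    list(centroid = centroid, normal = n / sqrt(sum(n * n)))
  })
}

#' Compute the interaction fingerprint of one frame
#'
#' Encodes each protein residue (and metal ion) into 8 bits, one per
#' interaction channel ([IFP_CHANNELS]), set when at least one ligand-residue
#' feature pair satisfies the channel's geometric criterion. A ligand far
#' from every residue yields an all-zero fingerprint.
#'
#' @param frame n x 3 coordinate matrix (or a frame from a trajectory).
#' @param system A [molecular_system()].
#' @param features Output of [perceive_features()], or a prebuilt
#'   [fingerprint_context()] for repeated evaluation.
#' @param thresholds See [interaction_thresholds()]; ignored when `features`
#'   is already a context.
#' @return Object of class `interaction_fingerprint`: integer 0/1 vector of
#'   length `8 * r` with attributes `residue_order` and `channels`.
#' @export
compute_fingerprint <- function(frame, system, features,
                                thresholds = interaction_thresholds()) {
  ctx <- if (inherits(features, "fingerprint_context")) features
         else fingerprint_context(system, features, thresholds)
  xyz <- if (is.matrix(frame)) frame else as.matrix(frame)
  th <- ctx$thresholds
  lig <- ctx$ligand
  bits <- matrix(0L, nrow = ctx$n_res, ncol = 8,
                 dimnames = list(ctx$residue_order, IFP_CHANNELS))

  lig_rings <- ring_geoms(xyz, lig$rings)
  pre2 <- ctx$prefilter^2

  for (ri in seq_len(ctx$n_res)) {
    res <- ctx$residues[[ri]]
    if (min_d2(xyz, res$atoms, lig$heavy) > pre2) next

    if (min_d2(xyz, res$hydrophobic, lig$hydrophobic) <= th$hy^2)
      bits[ri, "HY"] <- 1L

    if (length(res$rings) && length(lig_rings)) {
      for (pg in ring_geoms(xyz, res$rings)) {
        for (lg in lig_rings) {
          d <- vnorm(pg$centroid - lg$centroid)
          ang <- angle_deg(pg$normal, lg$normal)
          ang <- min(ang, 180 - ang)  # normals are sign-ambiguous
          if (d <= th$f2f_dist && ang <= th$f2f_angle) bits[ri, "F2F"] <- 1L
          if (d <= th$e2f_dist && ang >= th$e2f_angle_min && ang <= th$e2f_angle_max)
            bits[ri, "E2F"] <- 1L
        }
      }
    }

    if (length(res$donors) && length(lig$acceptors) &&
        hb_match(xyz, res$donors, lig$acceptors, th))
      bits[ri, "HB_PD"] <- 1L
    if (length(lig$donors) && length(res$acceptors) &&
        hb_match(xyz, lig$donors, res$acceptors, th))
      bits[ri, "HB_PA"] <- 1L

    if (min_d2(xyz, res$cation_atoms, lig$anion_atoms) <= th$sb^2)
      bits[ri, "SB_PP"] <- 1L
    if (min_d2(xyz, res$anion_atoms, lig$cation_atoms) <= th$sb^2)
      bits[ri, "SB_PN"] <- 1L

    if (min_d2(xyz, res$metals, lig$acceptors) <= th$met^2)
      bits[ri, "MET"] <- 1L
  }

  new_fingerprint(as.integer(t(bits)), ctx$residue_order)
}

new_fingerprint <- function(bits, residue_order) {
  stopifnot(length(bits) == 8L * length(residue_order),
            all(bits %in% c(0L, 1L)))
  structure(bits, residue_order = residue_order, channels = IFP_CHANNELS,
            class = "interaction_fingerprint")
}

#' @export
print.interaction_fingerprint <- function(x, ...) {
  m <- as.matrix(x)
  cat("<interaction_fingerprint>", length(attr(x, "residue_order")),
      "residues x 8 channels,", sum(x), "bits set\n")
  set <- which(m == 1L, arr.ind = TRUE)
  if (nrow(set)) {
    lab <- paste0(rownames(m)[set[, 1]], " ", colnames(m)[set[, 2]])
    cat(" ", paste(sort(lab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.interaction_fingerprint <- function(x, ...) {
  matrix(unclass(x), ncol = 8, byrow = TRUE,
         dimnames = list(attr(x, "residue_order"), attr(x, "channels")))
}

#' Residues with any bit set in a fingerprint
#' @param fp An `interaction_fingerprint`.
#' @return Character vector of residue keys in contact with the ligand.
#' @export
contacted_residues <- function(fp) {
  m <- as.matrix(fp)
  rownames(m)[rowSums(m) > 0]
}
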