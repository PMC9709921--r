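# Feature perception and the geometric interaction channels.
# (far_gly / benzene / phe_ring / fp_channels live in helper-fixtures.R.)

test_that("feature perception follows the chemistry rules", {
  sys <- build_system(far_gly(), benzene())
  lf <- perceive_features(sys)$ligand
  expect_length(lf$rings, 1)
  expect_length(lf$rings[[1]], 6)
  expect_length(lf$hydrophobic, 6)
  expect_length(lf$donors, 0)
  expect_length(lf$acceptors, 0)

  asp <- rbind(
    test_atom("N", "N", 1, "ASP", -4.7, 4.0, 0, "protein"),
    test_atom("CA", "C", 1, "ASP", -3.9, 2.8, 0, "protein"),
    test_atom("C", "C", 1, "ASP", -2.9, 3.8, 0, "protein"),
    test_atom("O", "O", 1, "ASP", -2.3, 4.9, 0, "protein"),
    test_atom("CB", "C", 1, "ASP", -2.7, 1.9, 0, "protein"),
    test_atom("CG", "C", 1, "ASP", -1.5, 1.0, 0, "protein"),
    test_atom("OD1", "O", 1, "ASP", -0.35, 0.5, 0, "protein"),
    test_atom("OD2", "O", 1, "ASP", -2.1, -0.05, 0, "protein")
  )
  sys2 <- build_system(asp, test_atom("C1", "C", 1, "LIG", 20, 0, 0, "ligand", chain = "L"))
  pf <- perceive_features(sys2)$protein
  expect_length(pf$anions, 1)
  expect_setequal(sys2$atoms$name[pf$anions[[1]]], c("CG", "OD1", "OD2"))

  lys <- rbind(
    far_gly(c(-8, 0, 0), resno = 1),
    test_atom("CB", "C", 2, "LYS", -4.56, -0.4, 0, "protein"),
    test_atom("CE", "C", 2, "LYS", -3.1, -0.8, 0, "protein"),
    test_atom("NZ", "N", 2, "LYS", -1.7, -1.0, 0, "protein")
  )
  lys$resid[5:7] <- "LYS"
  sys3 <- build_system(lys, test_atom("C1", "C", 1, "LIG", 20, 0, 0, "ligand", chain = "L"))
  pf3 <- perceive_features(sys3)$protein
  expect_length(pf3$cations, 1)
  expect_equal(sys3$atoms$name[pf3$cations[[1]]], "NZ")
})

test_that("a distant ligand yields an all-zero fingerprint", {
  sys <- build_system(far_gly(c(0, 0, 0), resno = 1),
                      benzene(c(40, 0, 0)))
  fp <- compute_fingerprint(system_coords(sys), sys, perceive_features(sys))
  expect_equal(sum(fp), 0)
})

test_that("an ideal amide hydrogen bond sets HB_PD for its residue only", {
  gly <- rbind(
    test_atom("N", "N", 1, "GLY", 0, 0, 0, "protein"),
    test_atom("H", "H", 1, "GLY", 0, 0, 1.0, "protein"),
    test_atom("CA", "C", 1, "GLY", 1.0, -1.0, -0.3, "protein"),
    test_atom("C", "C", 1, "GLY", 2.2, -1.9, -0.3, "protein"),
    test_atom("O", "O", 1, "GLY", 2.8, -3.0, -0.3, "protein")
  )
  # carbonyl acceptor 2.9 A from the donor N, D-H...A angle 170 degrees
  lig <- rbind(
    test_atom("O1", "O", 1, "LIG", 0, 0.3316, 2.8808, "ligand", chain = "L"),
    test_atom("C1", "C", 1, "LIG", 0, 1.56, 2.88, "ligand", chain = "L")
  )
  sys <- build_system(gly, far_gly(resno = 2), lig)
  fp <- compute_fingerprint(system_coords(sys), sys, perceive_features(sys))
  m <- as.matrix(fp)
  expect_equal(unname(m["A:1:", "HB_PD"]), 1L)
  expect_equal(sum(m), 1)

  # same distance, D-H...A angle 90 degrees: no hydrogen bond
  lig90 <- rbind(
    test_atom("O1", "O", 1, "LIG", 0, 2.722, 1.0, "ligand", chain = "L"),
    test_atom("C1", "C", 1, "LIG", 0, 3.952, 1.0, "ligand", chain = "L")
  )
  sys90 <- build_system(gly, far_gly(resno = 2), lig90)
  fp90 <- compute_fingerprint(system_coords(sys90), sys90, perceive_features(sys90))
  expect_equal(sum(fp90), 0)
})

test_that("salt bridges set exactly their charge channel at 3.8 A", {
  lys <- rbind(
    far_gly(c(-6, 0, 0), resno = 1),
    test_atom("CB", "C", 1, "LYS", -4.56, -0.4, 0, "protein"),
    test_atom("CE", "C", 1, "LYS", -3.1, -0.8, 0, "protein"),
    test_atom("NZ", "N", 1, "LYS", -1.7, -1.0, 0, "protein")
  )
  lys$resid <- "LYS"
  carboxylate <- rbind(
    test_atom("O1", "O", 1, "LIG", 2.1, -1.0, 0, "ligand", chain = "L"),
    test_atom("C7", "C", 1, "LIG", 3.35, -1.0, 0, "ligand", chain = "L"),
    test_atom("O2", "O", 1, "LIG", 3.95, -2.1, 0, "ligand", chain = "L")
  )
  sys <- build_system(lys, carboxylate)
  expect_equal(fp_channels(sys), "SB_PP")

  asp <- rbind(
    test_atom("N", "N", 1, "ASP", -4.7, 4.0, 0, "protein"),
    test_atom("CA", "C", 1, "ASP", -3.9, 2.8, 0, "protein"),
    test_atom("C", "C", 1, "ASP", -2.9, 3.8, 0, "protein"),
    test_atom("O", "O", 1, "ASP", -2.3, 4.9, 0, "protein"),
    test_atom("CB", "C", 1, "ASP", -2.7, 1.9, 0, "protein"),
    test_atom("CG", "C", 1, "ASP", -1.5, 1.0, 0, "protein"),
    test_atom("OD1", "O", 1, "ASP", -0.35, 0.5, 0, "protein"),
    test_atom("OD2", "O", 1, "ASP", -2.1, -0.05, 0, "protein")
  )
  ammonium <- rbind(
    test_atom("N1", "N", 1, "LIG", 3.45, 0.5, 0, "ligand", chain = "L", charge = 1),
    test_atom("C8", "C", 1, "LIG", 4.75, 1.0, 0, "ligand", chain = "L")
  )
  sys2 <- build_system(asp, ammonium)
  expect_equal(fp_channels(sys2), "SB_PN")

  # carboxylate-ammonium pair at 3.2 A sets the salt bridge (plus the
  # inherent charge-assisted hydrogen bond)
  carb32 <- carboxylate
  carb32$x <- carb32$x - 0.6
  sys32 <- build_system(lys, carb32)
  expect_true("SB_PP" %in% fp_channels(sys32))
})

test_that("aromatic stacking splits into face-to-face and edge-to-face", {
  base <- rbind(far_gly(c(-20, 0, 0), resno = 98),
                phe_ring(c(0, 0, 3.8), resno = 1))
  sys <- build_system(base, benzene())
  ch <- fp_channels(sys)
  expect_true("F2F" %in% ch)
  expect_false("E2F" %in% ch)

  # same rings tilted to 85 degrees: edge-to-face, no face-to-face
  sys85 <- build_system(
    rbind(far_gly(c(-20, 0, 0), resno = 98), phe_ring(c(0, 0, 4.5), resno = 1)),
    {
      b <- benzene()
      th <- 85 * pi / 180
      xyz <- as.matrix(b[, c("x", "y", "z")])
      rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                    3, byrow = TRUE)
      xyz <- xyz %*% rot
      b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
      b
    }
  )
  ch85 <- fp_channels(sys85)
  expect_true("E2F" %in% ch85)
  expect_false("F2F" %in% ch85)

  # staggered parallel rings at 4.3 A: face-to-face and nothing else
  sysx <- build_system(
    rbind(far_gly(c(-20, 0, 0), resno = 98),
          phe_ring(c(0, 0, 4.3), resno = 1, rot = pi / 6)),
    benzene()
  )
  expect_equal(fp_channels(sysx), "F2F")

  # perpendicular rings at 5.45 A: edge-to-face and nothing else
  syse <- build_system(
    rbind(far_gly(c(-20, 0, 0), resno = 98), phe_ring(c(0, 0, 0), resno = 1)),
    benzene(c(0, 0, 5.45), normal_axis = "y")
  )
  expect_equal(fp_channels(syse), "E2F")
})

test_that("hydrophobic and metal contacts set exactly their channel", {
  ala <- rbind(
    far_gly(c(0, 0, -6), resno = 1),
    test_atom("CB", "C", 1, "ALA", 0, 0, -4.5, "protein")
  )
  ala$resid <- "ALA"
  sys <- build_system(ala, test_atom("C1", "C", 1, "LIG", 0, 0, -1.0,
                                     "ligand", chain = "L"))
  expect_equal(fp_channels(sys), "HY")

  sysm <- build_system(
    far_gly(c(-12, 0, 0), resno = 1),
    test_atom("ZN", "ZN", 2, "ZN", 0, 0, 2.5, "ion"),
    rbind(test_atom("O1", "O", 1, "LIG", 0, 0, 0, "ligand", chain = "L"),
          test_atom("C1", "C", 1, "LIG", 0, 1.23, 0, "ligand", chain = "L"))
  )
  fpm <- as.matrix(compute_fingerprint(system_coords(sysm), sysm,
                                       perceive_features(sysm)))
  expect_equal(unname(fpm["A:2:", "MET"]), 1L)
  expect_equal(sum(fpm), 1)
})

test_that("fingerprints are deterministic and rigid-transform invariant", {
  sys <- make_toy_complex(1)
  feats <- perceive_features(sys)
  ctx <- fingerprint_context(sys, feats)
  xyz <- system_coords(sys)
  ref <- compute_fingerprint(xyz, sys, ctx)
  expect_identical(unclass(ref), unclass(compute_fingerprint(xyz, sys, ctx)))

  withr::local_seed(21)
  for (i in 1:10) {
    moved <- apply_rigid(xyz, random_rotation(), runif(3, -30, 30))
    expect_identical(unclass(compute_fingerprint(moved, sys, ctx)),
                     unclass(ref))
  }
})

test_that("pulling the ligand out of the pocket only clears bits", {
  sys <- make_toy_complex(1)
  ctx <- fingerprint_context(sys, perceive_features(sys))
  xyz <- system_coords(sys)
  lig <- sys$ligand_idx
  pocket <- colMeans(xyz[-lig, , drop = FALSE])
  ray <- unit(colMeans(xyz[lig, , drop = FALSE]) - pocket + c(0.3, 0.1, 0.2))

  prev <- as.logical(compute_fingerprint(xyz, sys, ctx))
  started_clearing <- FALSE
  for (step in seq(2, 40, by = 2)) {
    fr <- xyz
    fr[lig, ] <- sweep(fr[lig, , drop = FALSE], 2, step * ray, "+")
    cur <- as.logical(compute_fingerprint(fr, sys, ctx))
    if (started_clearing) expect_false(any(cur & !prev))
    if (any(prev & !cur)) started_clearing <- TRUE
    prev <- cur
  }
  expect_equal(sum(prev), 0)  # fully dissociated at 40 A
})
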