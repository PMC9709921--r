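# Titration profiles, the MS coefficient, the per-residue energy
# decomposition and the diagnostic plots.

stable_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- make_toy_complex(1)
      ramp <- build_ramp()
      eng <- synthetic_engine(sys, synthetic_scenario("stable",
                                                      frames_per_window = 10L),
                              ramp)
      cache <<- list(sys = sys, run = run_ttmd(sys, eng, ramp, ttmd_config(),
                                               seed = 8L))
    }
    cache
  }
})

test_that("the titration profile prepends the -1 initial state", {
  sr <- stable_run()
  prof <- titration_profile(sr$run)
  expect_equal(nrow(prof), 17)  # initial state + 16 windows
  expect_equal(prof$temperature[1], 300)
  expect_equal(prof$mean_ifp_cs[1], -1)
  expect_equal(prof$temperature[-1], seq(300, 450, by = 10))
  expect_equal(prof$mean_ifp_cs[-1],
               vapply(sr$run$steps, function(s) s$mean_ifp_cs, 0))

  expect_error(titration_profile(list()), class = "ttmd_usage_error")
  expect_error(new_titration_profile(c(300, 310, 305), c(-1, -0.5, -0.4)),
               class = "ttmd_usage_error")
  expect_error(new_titration_profile(c(300, 310, 310), c(-1, -0.5, -0.4)),
               class = "ttmd_usage_error")
  expect_error(new_titration_profile(c(300, 310), c(-1, 0.2)),
               class = "ttmd_usage_error")
  expect_error(new_titration_profile(c(300, 310), c(-1.2, -0.5)),
               class = "ttmd_usage_error")
  # the initial state may share the first window's temperature
  expect_silent(new_titration_profile(c(300, 300, 310), c(-1, -0.9, -0.8)))
})

test_that("the MS coefficient is the first-to-last slope of the profile", {
  # [DERIVED] binding mode fully retained: final mean -1 over 300..450 K
  full <- new_titration_profile(c(300, seq(300, 450, 10)),
                                c(-1, rep(-1, 16)))
  expect_equal(ms_coefficient(full)$value, 0)

  # [DERIVED] complete loss by the end of the ramp: (0 - (-1)) / 150
  lost <- new_titration_profile(c(300, 350, 450), c(-1, -0.6, 0))
  expect_equal(ms_coefficient(lost)$value, 1 / 150)

  # [DERIVED] early termination at 320 K with mean 0: 1 / 20 = 0.05
  early <- new_titration_profile(c(300, 300, 310, 320), c(-1, -0.9, -0.4, 0))
  ms <- ms_coefficient(early)
  expect_equal(ms$value, 0.05)
  expect_equal(ms$t_end, 320)

  # [DERIVED] half retention over 100 K: 0.5 / 100
  expect_equal(ms_coefficient(new_titration_profile(c(300, 400),
                                                    c(-1, -0.5)))$value,
               0.005)

  # a run and its own profile give the identical coefficient
  sr <- stable_run()
  expect_equal(ms_coefficient(sr$run)$value,
               ms_coefficient(titration_profile(sr$run))$value)

  expect_error(ms_coefficient(new_titration_profile(300, -1)),
               class = "ttmd_usage_error")
})

test_that("single-pair energies match the closed-form formulas", {
  pair_system <- function(d, q1, q2, sig = 3.4, eps = 0.1) {
    sys <- build_system(
      test_atom("CA", "C", 1, "GLY", 0, 0, 0, "protein"),
      test_atom("C1", "C", 1, "LIG", d, 0, 0, "ligand", chain = "L")
    )
    sys$atoms$charge <- c(q1, q2)
    sys$atoms$sigma <- sig
    sys$atoms$epsilon <- eps
    sys
  }

  # LJ vanishes exactly at r = sigma
  sys <- pair_system(3.4, 0, 0)
  e <- per_residue_energy(system_coords(sys), sys)
  expect_equal(e$etotal, 0, tolerance = 1e-12)

  # [DERIVED] unit charges at 3.32 A: 332.06 / 3.32 = 100.018... kcal/mol
  sys2 <- pair_system(3.32, 1, -1, eps = 0)
  e2 <- per_residue_energy(system_coords(sys2), sys2)
  expect_equal(e2$eelec, -332.06 / 3.32, tolerance = 1e-12)
  expect_equal(e2$elj, 0)

  # LJ minimum depth is -eps at r = 2^(1/6) sigma
  sys3 <- pair_system(2^(1 / 6) * 3.4, 0, 0, eps = 0.25)
  e3 <- per_residue_energy(system_coords(sys3), sys3)
  expect_equal(e3$elj, -0.25, tolerance = 1e-12)

  # beyond the 9 A cutoff nothing contributes
  sys4 <- pair_system(12, 1, -1)
  expect_equal(nrow(per_residue_energy(system_coords(sys4), sys4)), 0)

  # missing parameters are a parameter error
  expect_error(per_residue_energy(system_coords(make_polar_pair()),
                                  make_polar_pair()),
               class = "ttmd_parameter_error")
})

test_that("the decomposition matches a brute-force pairwise oracle", {
  sys <- make_toy_complex(1)
  xyz <- system_coords(sys)
  a <- sys$atoms
  e <- per_residue_energy(xyz, sys)

  oracle <- new.env()
  for (i in which(a$role != "ligand")) {
    for (j in sys$ligand_idx) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > 9 || r == 0) next
      sig <- (a$sigma[i] + a$sigma[j]) / 2
      eps <- sqrt(a$epsilon[i] * a$epsilon[j])
      sr6 <- (sig / r)^6
      v <- 4 * eps * (sr6^2 - sr6) + 332.06 * a$charge[i] * a$charge[j] / r
      k <- a$key[i]
      oracle[[k]] <- (oracle[[k]] %||% 0) + v
    }
  }
  for (k in e$residue)
    expect_equal(e$etotal[e$residue == k], oracle[[k]], tolerance = 1e-8)
  expect_equal(sum(e$etotal),
               sum(unlist(as.list(oracle))), tolerance = 1e-8)
  # the engineered pocket is attractive overall
  expect_lt(sum(e$etotal), 0)
})

test_that("energy_series and top_contacted_residues summarise the run", {
  sr <- stable_run()
  en <- energy_series(sr$run, sr$sys, stride = 5L)
  expect_true(all(c("time", "temperature", "window", "residue", "etotal")
                  %in% names(en)))
  expect_gt(nrow(en), 0)
  expect_equal(sort(unique(en$window)), 1:16)

  top <- top_contacted_residues(sr$run)
  expect_true(all(c("A:1:", "A:2:", "A:3:", "A:4:", "A:5:", "A:6:") %in% top))
  expect_equal(top_contacted_residues(sr$run, n = 3), top[1:3])

  nostore <- run_ttmd(sr$sys,
                      synthetic_engine(sr$sys,
                                       synthetic_scenario("stable",
                                                          frames_per_window = 5L),
                                       build_ramp(300, 310)),
                      build_ramp(300, 310),
                      ttmd_config(store_trajectories = FALSE))
  expect_error(energy_series(nostore, sr$sys), class = "ttmd_usage_error")
})

test_that("render_plots writes the three diagnostics with the MS in the label", {
  sr <- stable_run()
  out <- withr::local_tempdir()
  paths <- render_plots(sr$run, sr$sys, out, energy_stride = 5L,
                        rmsd_stride = 5L)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 1000))

  ms <- ms_coefficient(sr$run)
  expect_equal(attr(paths, "slope_label"),
               sprintf("MS = %.4f K^-1", ms$value))
})
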