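# The synthetic-data generator: geometry construction, tensors, shieldings,
# dataset simulation, decoys, and full determinism.

test_that("toy ensembles share labels, differ in geometry, and respect dihedral periodicity", {
  ens <- make_toy_ensemble(4, 23, dihedral_spec = list(first = c(0, 90, 180, 270)),
                           seed = 6)
  expect_equal(n_conformers(ens), 4L)
  labs <- lapply(ens$conformers, `[[`, "atom_labels")
  expect_true(all(vapply(labs, identical, logical(1), labs[[1L]])))
  for (i in 1:3) for (j in (i + 1):4) {
    rmsd <- sqrt(mean((ens$conformers[[i]]$coords -
                         ens$conformers[[j]]$coords)^2))
    expect_gt(rmsd, 0.1)
  }

  wrap <- make_toy_ensemble(2, 23, dihedral_spec = list(first = c(0, 360)),
                            seed = 6)
  expect_lt(max(abs(wrap$conformers[[1L]]$coords -
                      wrap$conformers[[2L]]$coords)), 1e-9)

  expect_error(make_toy_ensemble(2, 5), "\\[10, 60\\]")
})

test_that("generation is byte-identical under a fixed seed", {
  e1 <- make_toy_ensemble(3, 29, seed = 11)
  e2 <- make_toy_ensemble(3, 29, seed = 11)
  expect_identical(e1, e2)

  f1 <- tempfile(fileext = ".xyz"); f2 <- tempfile(fileext = ".xyz")
  write_xyz_ensemble(e1, f1); write_xyz_ensemble(e2, f2)
  expect_identical(readLines(f1), readLines(f2))

  tt <- make_true_tensor(5e-4, 0.3, 4)
  s1 <- simulate_dataset(e1, tt, uniform_pops(e1), seed = 9)
  s2 <- simulate_dataset(e2, tt, uniform_pops(e2), seed = 9)
  expect_identical(s1, s2)
})

test_that("true tensors have the requested eigenstructure", {
  t_ax <- make_true_tensor(5e-4, 0, 3)
  ev <- tensor_eigen(t_ax)$values
  expect_equal(ev[["Sxx"]], ev[["Syy"]], tolerance = 1e-12)
  expect_equal(sum(ev), 0, tolerance = 1e-15)
  expect_equal(ev[["Szz"]], 5e-4, tolerance = 1e-12)

  for (rh in c(0.2, 0.5, 2 / 3)) {
    tt <- make_true_tensor(1e-3, rh, 5)
    ev <- sort(tensor_eigen(tt)$values)
    want <- sort(c(1e-3, -(1e-3 / 2) * (1 - 1.5 * rh),
                   -(1e-3 / 2) * (1 + 1.5 * rh)))
    expect_equal(as.numeric(ev), want, tolerance = 1e-12)
  }
  expect_error(make_true_tensor(5e-4, 0.8), "rhombicity")
  expect_error(make_true_tensor(0.5, 0), "axial_magnitude")
})

test_that("simulated datasets cover every C-H pair and carbon, and close the loop at zero noise", {
  ens <- make_toy_ensemble(3, 29, seed = 2)
  pops <- c(c1 = 0.5, c2 = 0.3, c3 = 0.2)
  truth <- make_true_tensor(6e-4, 0.25, 13)
  sim <- simulate_dataset(ens, truth, pops,
                          noise = list(rdc_hz = 0, rcsa_ppb = 0,
                                       shift_c13_ppm = 0, shift_h1_ppm = 0),
                          seed = 3)

  expect_equal(nrow(sim$rdc), nrow(find_ch_pairs(ens)))
  n_carbons <- sum(ensemble_elements(ens) == "C")
  expect_equal(nrow(sim$rcsa), n_carbons)
  expect_equal(nrow(sim$shieldings), n_carbons * 3L)

  fit <- fit_tensor_to_data(ens, pops, rdc = sim$rdc, rcsa = sim$rcsa,
                            shieldings = sim$shieldings,
                            reference = "EXTERNAL")
  expect_lt(max(abs(attr(fit$tensor, "svec") - attr(truth, "svec"))), 1e-8)

  # CASE-3D on the noise-free shifts recovers the generating populations
  f <- fit_populations(sim$shifts, sim$computed,
                       subset = c("c1", "c2", "c3"))
  expect_equal(as.numeric(f$populations), as.numeric(pops), tolerance = 1e-6)
})

test_that("generated noise matches the requested sigma", {
  ens <- make_toy_ensemble(1, 29, seed = 4)
  pops <- c(c1 = 1)
  truth <- make_true_tensor(5e-4, 0.3, 6)
  sim0 <- simulate_dataset(ens, truth, pops,
                           noise = list(rdc_hz = 0, rcsa_ppb = 0,
                                        shift_c13_ppm = 0, shift_h1_ppm = 0),
                           seed = 1)
  resid <- unlist(lapply(1:350, function(s) {
    sim <- simulate_dataset(ens, truth, pops,
                            noise = list(rdc_hz = 0.5, rcsa_ppb = 2,
                                         shift_c13_ppm = 0, shift_h1_ppm = 0),
                            seed = s, shieldings = sim0$shieldings)
    c((sim$rdc$value_hz - sim0$rdc$value_hz) / 0.5,
      (sim$rcsa$value_ppb - sim0$rcsa$value_ppb) / 2)
  }))
  expect_gte(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 1), 0.05)
})

test_that("stereocenter inversion is an isometric involution that moves a branch", {
  ens <- toy3()
  dec <- make_decoy_configuration(ens, "C1")
  expect_identical(ensemble_labels(dec), ensemble_labels(ens))

  back <- make_decoy_configuration(dec, "C1", label = "")
  for (k in seq_along(ens$conformers)) {
    expect_lt(max(abs(back$conformers[[k]]$coords -
                        ens$conformers[[k]]$coords)), 1e-6)
  }

  # bond lengths preserved
  d0 <- as.matrix(dist(ens$conformers[[1]]$coords))
  d1 <- as.matrix(dist(dec$conformers[[1]]$coords))
  bonded <- d0 < 1.6 & upper.tri(d0)
  expect_lt(max(abs(d1[bonded] - d0[bonded])), 1e-6)

  # the moved branch (methyl + stereocenter H) is genuinely displaced
  moved <- c("H1", "C2", "H2a", "H2b", "H2c")
  idx <- match(moved, ensemble_labels(ens))
  rmsd_moved <- sqrt(mean((dec$conformers[[1]]$coords[idx, ] -
                             ens$conformers[[1]]$coords[idx, ])^2))
  expect_gt(rmsd_moved, 0.3)

  expect_error(make_decoy_configuration(ens, "H1"), "exactly 4")
})

test_that("decoy fits are worse than truth fits at moderate noise", {
  ens <- toy3()
  dec <- make_decoy_configuration(ens)
  pops <- c(c1 = 0.5, c2 = 0.3, c3 = 0.2)
  dec_sh <- generate_shieldings(dec, seed = 1001)
  wins <- 0L
  for (trial in 1:10) {
    truth <- make_true_tensor(5e-4, 0.3, trial)
    sim0 <- simulate_dataset(ens, truth, pops,
                             noise = list(rdc_hz = 0, rcsa_ppb = 0,
                                          shift_c13_ppm = 0,
                                          shift_h1_ppm = 0), seed = 1)
    sd_rdc <- 0.05 * sqrt(mean(sim0$truth$rdc_true^2))
    sd_rcsa <- 0.05 * sqrt(mean(sim0$truth$rcsa_true^2))
    sim <- simulate_dataset(ens, truth, pops,
                            noise = list(rdc_hz = sd_rdc, rcsa_ppb = sd_rcsa,
                                         shift_c13_ppm = 0.2,
                                         shift_h1_ppm = 0.02),
                            seed = 5000 + trial)
    q_true <- fit_tensor_to_data(ens, pops, rdc = sim$rdc, rcsa = sim$rcsa,
                                 shieldings = sim$shieldings,
                                 reference = "EXTERNAL")$q_combined
    q_dec <- fit_tensor_to_data(dec, pops, rdc = sim$rdc, rcsa = sim$rcsa,
                                shieldings = dec_sh,
                                reference = "EXTERNAL")$q_combined
    if (q_true < q_dec) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
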