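# CASE-3D machinery: shift scaling, simplex-constrained population fits,
# AIC scoring, and subset enumeration.

# small deterministic shift system: k conformer columns, two nucleus classes
make_shift_system <- function(n_c = 8, n_h = 10, k = 3, seed = 1) {
  with_seed(seed, {
    labels <- c(paste0("C", 1:n_c), paste0("H", 1:n_h))
    nucleus <- c(rep("C13", n_c), rep("H1", n_h))
    base <- c(runif(n_c, 20, 170), runif(n_h, 1, 9))
    computed <- base + matrix(rnorm((n_c + n_h) * k, 0,
                                    rep(c(2, 0.15), c(n_c, n_h))),
                              n_c + n_h, k)
    colnames(computed) <- paste0("c", 1:k)
    list(shifts = data.frame(label = labels, nucleus = nucleus,
                             exp_ppm = NA_real_),
         computed = computed)
  })
}

test_that("shift scaling recovers exact and affine relations, disables below 3 points", {
  sys <- make_shift_system(seed = 2)
  exp_vals <- sys$computed[, 1]
  sys$shifts$exp_ppm <- exp_vals
  sc <- scale_computed_shifts(sys$shifts, exp_vals)
  for (cls in c("C13", "H1")) {
    expect_equal(sc$params[[cls]]$slope, 1, tolerance = 1e-12)
    expect_equal(sc$params[[cls]]$intercept, 0, tolerance = 1e-10)
  }

  # computed = 2*exp + 5 -> recovered slope 0.5 maps back exactly
  sys$shifts$exp_ppm <- exp_vals
  sc2 <- scale_computed_shifts(sys$shifts, 2 * exp_vals + 5)
  expect_equal(sc2$params$C13$slope, 0.5, tolerance = 1e-10)
  expect_equal(sc2$scaled, exp_vals, tolerance = 1e-10)

  # known affine + noise: recovered within 3 standard errors
  with_seed(31, {
    comp <- sys$computed[1:8, 1]
    truth_slope <- 1.07; truth_int <- -2.1
    exp_noisy <- truth_slope * comp + truth_int + rnorm(8, 0, 0.1)
    sh <- data.frame(label = paste0("C", 1:8), nucleus = "C13",
                     exp_ppm = exp_noisy)
    sc3 <- scale_computed_shifts(sh, comp)
    se_slope <- 0.1 / (sd(comp) * sqrt(7))
    expect_lt(abs(sc3$params$C13$slope - truth_slope), 3 * se_slope)
  })

  sh_small <- data.frame(label = c("C1", "C2", "H1", "H2", "H3"),
                         nucleus = c("C13", "C13", "H1", "H1", "H1"),
                         exp_ppm = c(10, 20, 1, 2, 3))
  expect_warning(sc4 <- scale_computed_shifts(sh_small, c(11, 19, 1, 2, 3)),
                 "scaling disabled")
  expect_false(sc4$params$C13$scaled)
  expect_equal(sc4$scaled[1:2], c(11, 19))   # identity map on that class
})

test_that("population fitting handles singletons, exact mixtures, and obeys simplex constraints", {
  sys <- make_shift_system(k = 4, seed = 5)

  sys$shifts$exp_ppm <- sys$computed[, 2]
  f1 <- fit_populations(sys$shifts, sys$computed, subset = "c2",
                        scaling = "none")
  expect_equal(as.numeric(f1$populations), 1)

  # exact 50/50 mixture is recovered with essentially zero residual
  sys$shifts$exp_ppm <- 0.5 * sys$computed[, 1] + 0.5 * sys$computed[, 3]
  f2 <- fit_populations(sys$shifts, sys$computed, subset = c("c1", "c3"),
                        scaling = "none")
  expect_equal(as.numeric(f2$populations), c(0.5, 0.5), tolerance = 1e-8)
  expect_lt(f2$rss, 1e-12)

  # simplex constraints hold on noisy fits over all 4 conformers
  with_seed(13, {
    for (i in 1:10) {
      sys$shifts$exp_ppm <- 0.8 * sys$computed[, 1] + 0.2 * sys$computed[, 2] +
        rnorm(nrow(sys$computed), 0, rep(c(0.3, 0.03), c(8, 10)))
      f <- fit_populations(sys$shifts, sys$computed)
      expect_true(all(f$populations >= -1e-12))
      expect_equal(sum(f$populations), 1, tolerance = 1e-9)
    }
  })
})

test_that("active-set population solver matches the support-enumeration oracle", {
  with_seed(17, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      A <- matrix(rnorm(12 * k), 12, k)
      y <- rnorm(12)
      got <- anisofit:::simplex_ls(A, y)
      want <- oracle_simplex_ls(A, y)
      expect_lt(abs(got$rss - want$rss), 1e-8)
    }
  })
})

test_that("AIC arithmetic: halving rss, parameter threshold, perfect-fit sentinel", {
  n <- 30; k <- 4
  expect_equal(aic_score(10, n, k) - aic_score(5, n, k), n * log(2),
               tolerance = 1e-12)

  # one extra parameter must buy > 2 + correction-increase in fit term
  a1 <- aic_score(10, n, k, correction = TRUE)
  delta_pen <- (2 * (k + 1) + 2 * (k + 1) * (k + 2) / (n - k - 2)) -
    (2 * k + 2 * k * (k + 1) / (n - k - 1))
  rss_break <- 10 * exp(-delta_pen / n)
  expect_equal(aic_score(rss_break, n, k + 1, correction = TRUE), a1,
               tolerance = 1e-10)
  expect_gt(aic_score(rss_break * 1.01, n, k + 1), a1)

  perfect <- aic_score(0, n, k)
  expect_identical(as.numeric(perfect), -Inf)
  expect_true(attr(perfect, "perfect_fit"))
  expect_error(aic_score(1, 5, 4), "n > k \\+ 1")
})

test_that("enumeration scores all subsets, best RSS is non-increasing in size, ranking matches the brute-force oracle", {
  sys <- make_shift_system(k = 4, seed = 8)
  with_seed(23, {
    sys$shifts$exp_ppm <- 0.6 * sys$computed[, 1] + 0.4 * sys$computed[, 4] +
      rnorm(nrow(sys$computed), 0, rep(c(0.2, 0.02), c(8, 10)))
  })
  enum <- enumerate_models(sys$shifts, sys$computed, max_subset_size = 4)
  expect_equal(nrow(enum$table), 2^4 - 1)

  best_rss <- tapply(enum$table$rss, enum$table$size, min)
  expect_true(all(diff(best_rss) <= 1e-10))

  oracle <- oracle_case3d_rank(sys$shifts, sys$computed, 4)
  expect_equal(
    vapply(enum$models, function(m) paste(m$subset, collapse = "|"),
           character(1)),
    vapply(oracle, function(m) paste(m$subset, collapse = "|"), character(1)))
  expect_equal(vapply(enum$models, `[[`, numeric(1), "aic"),
               vapply(oracle, `[[`, numeric(1), "aic"), tolerance = 1e-8)

  expect_error(enumerate_models(sys$shifts, sys$computed, max_subset_size = 9),
               "exceeds")
})

test_that("3-conformer enumeration yields 7 models and duplicate conformers tie stably", {
  sys <- make_shift_system(k = 3, seed = 9)
  sys$shifts$exp_ppm <- sys$computed[, 1]
  enum <- enumerate_models(sys$shifts, sys$computed, max_subset_size = 3)
  expect_equal(nrow(enum$table), 7L)

  dup <- cbind(sys$computed, c9 = sys$computed[, 2])
  enum2 <- enumerate_models(sys$shifts, dup, max_subset_size = 1)
  aics <- enum2$table$aic[enum2$table$subset %in% c("c2", "c9")]
  expect_equal(aics[1], aics[2], tolerance = 1e-10)
  # lexicographic tie-break: c2 ranks before c9
  expect_lt(which(enum2$table$subset == "c2"),
            which(enum2$table$subset == "c9"))
})

test_that("noise-free mixtures select exactly the generating subset", {
  sys <- make_shift_system(k = 5, seed = 10)
  sys$shifts$exp_ppm <- 0.65 * sys$computed[, 2] + 0.35 * sys$computed[, 4]
  enum <- enumerate_models(sys$shifts, sys$computed, max_subset_size = 3)
  best <- enum$models[[1L]]
  expect_setequal(best$subset, c("c2", "c4"))
  expect_equal(unname(best$populations[c("c2", "c4")]), c(0.65, 0.35),
               tolerance = 1e-6)
})

test_that("CASE-3D prefers the true configuration over a decoy with offset computed shifts", {
  ens <- toy3()
  pops <- c(c1 = 0.7, c2 = 0.3, c3 = 0)
  truth <- make_true_tensor(5e-4, 0.3, 3)
  wins <- 0L
  for (trial in 1:100) {
    sim <- simulate_dataset(ens, truth, pops, seed = 2000 + trial)
    decoy_computed <- perturb_computed_shifts(sim$computed, sim$shifts,
                                              c13_sd = 0.5, h1_sd = 0.05,
                                              seed = 3000 + trial)
    rep <- case3d_select(
      list(truth = list(ensemble = ens, shifts = sim$shifts,
                        computed = sim$computed),
           decoy = list(ensemble = ens, shifts = sim$shifts,
                        computed = decoy_computed)),
      max_subset_size = 2, tie_tolerance = 0)
    if (rep$best == "truth") wins <- wins + 1L
  }
  expect_gte(wins / 100, 0.95)
})

test_that("case3d_select ties identical configurations, exports consistent FITTED populations, rejects mismatched shifts", {
  ens <- toy3()
  pops <- c(c1 = 0.7, c2 = 0.3, c3 = 0)
  sim <- simulate_dataset(ens, make_true_tensor(5e-4, 0.3, 3), pops, seed = 12)
  cfg <- list(ensemble = ens, shifts = sim$shifts, computed = sim$computed)

  rep <- case3d_select(list(A = cfg, B = cfg), max_subset_size = 2)
  expect_true(rep$tie)
  expect_equal(rep$configurations$A$S1$aic, rep$configurations$B$S1$aic)

  sel <- rep$selected$A
  expect_s3_class(sel$populations, "population_set")
  expect_equal(attr(sel$populations, "source"), "FITTED")
  expect_equal(sum(sel$populations), 1, tolerance = 1e-12)
  refit <- fit_populations(sim$shifts, sim$computed,
                           subset = rep$configurations$A$S1$subset)
  expect_equal(as.numeric(sel$populations), as.numeric(refit$populations),
               tolerance = 1e-12)

  cfg2 <- cfg
  cfg2$shifts$exp_ppm[1] <- cfg2$shifts$exp_ppm[1] + 1
  expect_error(case3d_select(list(A = cfg, B = cfg2)), "identical data")
})
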