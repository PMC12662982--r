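# Single-tensor ensemble fitting: design matrix correctness, SVD solution,
# Q factors, and configuration discrimination.

test_that("design matrix rows match a finite-difference oracle", {
  ens <- toy3()
  pops <- c(c1 = 0.5, c2 = 0.3, c3 = 0.2)
  sim <- simulate_dataset(ens, make_true_tensor(5e-4, 0.2, 4), pops,
                          noise = list(rdc_hz = 0, rcsa_ppb = 0,
                                       shift_c13_ppm = 0, shift_h1_ppm = 0),
                          seed = 2)
  rdc <- sim$rdc[1:8, ]
  design <- build_design_matrix(ens, pops, rdc = rdc)

  eps <- 1e-5
  for (i in seq_len(nrow(rdc))) {
    for (k in 1:5) {
      vp <- numeric(5); vp[k] <- eps
      d_plus <- sum(vapply(seq_along(ens$conformers), function(c)
        pops[[c]] * back_calc_rdc(ens$conformers[[c]], rdc$label_a[i],
                                  rdc$label_b[i], alignment_tensor(vp)),
        numeric(1)))
      d_minus <- sum(vapply(seq_along(ens$conformers), function(c)
        pops[[c]] * back_calc_rdc(ens$conformers[[c]], rdc$label_a[i],
                                  rdc$label_b[i], alignment_tensor(-vp)),
        numeric(1)))
      expect_equal(unname(design$A[i, k]), (d_plus - d_minus) / (2 * eps),
                   tolerance = 1e-6)
    }
  }
})

test_that("degenerate ensembles: single conformer equals rigid fit, duplicates average idempotently", {
  ens <- toy3()
  conf <- ens$conformers[[1L]]
  single <- conformational_ensemble("single", list(conf))
  rdc <- find_ch_pairs(ens)[1:6, ]
  rdc$value_hz <- 1; rdc$sigma_hz <- 0.5

  d1 <- build_design_matrix(single, c(c1 = 1), rdc = rdc)
  dup <- conformational_ensemble("dup", list(
    conf, conformer("c1b", conf$atom_labels, conf$elements, conf$coords)))
  d2 <- build_design_matrix(dup, c(c1 = 0.5, c1b = 0.5), rdc = rdc)
  expect_equal(d1$A, d2$A, tolerance = 1e-12)
})

test_that("RCSA design rows apply the reference subtraction and report data gaps", {
  ens <- toy3()
  pops <- uniform_pops(ens)
  sim <- simulate_dataset(ens, make_true_tensor(5e-4, 0.2, 4), pops, seed = 2)

  d_ext <- build_design_matrix(ens, pops, rcsa = sim$rcsa,
                               shieldings = sim$shieldings,
                               reference = "EXTERNAL")
  d_ref <- build_design_matrix(ens, pops, rcsa = sim$rcsa,
                               shieldings = sim$shieldings, reference = "C2")
  # the reference atom's own row is dropped; others get its row subtracted
  expect_equal(nrow(d_ref$A), nrow(d_ext$A) - 1L)
  ref_row <- d_ext$A[d_ext$meta$label == "C2", ]
  other <- setdiff(d_ext$meta$label, "C2")[1L]
  expect_equal(d_ref$A[d_ref$meta$label == other, ],
               d_ext$A[d_ext$meta$label == other, ] - ref_row,
               tolerance = 1e-12)

  gappy <- sim$shieldings[sim$shieldings$conformer_id != "c2" |
                            sim$shieldings$label != "C4", ]
  expect_error(
    build_design_matrix(ens, pops, rcsa = sim$rcsa, shieldings = gappy),
    "missing shielding.*C4.*c2")
})

test_that("re-referencing RCSA observations matches manual subtraction and rejects impossible conversions", {
  ens <- toy3()
  pops <- uniform_pops(ens)
  sim <- simulate_dataset(ens, make_true_tensor(5e-4, 0.2, 4), pops, seed = 2)

  d <- build_design_matrix(ens, pops, rcsa = sim$rcsa,
                           shieldings = sim$shieldings, reference = "C2")
  manual <- sim$rcsa$value_ppb - sim$rcsa$value_ppb[sim$rcsa$label == "C2"]
  names(manual) <- sim$rcsa$label
  expect_equal(d$y, unname(manual[d$meta$label]), tolerance = 1e-12)

  internal <- sim$rcsa
  internal$reference <- "C2"
  internal$value_ppb <- manual
  expect_error(build_design_matrix(ens, pops, rcsa = internal,
                                   shieldings = sim$shieldings,
                                   reference = "EXTERNAL"),
               "cannot convert")
  # converting between two internal references is fine
  d2 <- build_design_matrix(ens, pops, rcsa = internal,
                            shieldings = sim$shieldings, reference = "C5")
  want <- manual - manual[["C5"]]
  expect_equal(d2$y, unname(want[d2$meta$label]), tolerance = 1e-12)
})

test_that("SVD fit recovers a known tensor from noise-free data and matches a dense-solve oracle", {
  ens <- toy3()
  pops <- c(c1 = 0.6, c2 = 0.25, c3 = 0.15)
  truth <- make_true_tensor(8e-4, 0.4, 9)
  sim <- simulate_dataset(ens, truth, pops,
                          noise = list(rdc_hz = 0, rcsa_ppb = 0,
                                       shift_c13_ppm = 0, shift_h1_ppm = 0),
                          seed = 3)
  fit <- fit_tensor_to_data(ens, pops, rdc = sim$rdc, rcsa = sim$rcsa,
                            shieldings = sim$shieldings,
                            reference = "EXTERNAL")
  expect_lt(max(abs(attr(fit$tensor, "svec") - attr(truth, "svec"))), 1e-8)
  expect_lt(fit$q_combined, 1e-6)
  expect_false(fit$rank_deficient)

  # exactly determined 5-datum system equals the direct linear solve
  d5 <- build_design_matrix(ens, pops, rdc = sim$rdc[c(1, 4, 7, 10, 13), ])
  fit5 <- fit_alignment_tensor(d5)
  s_direct <- solve(d5$A_w, d5$y_w)
  expect_equal(as.numeric(attr(fit5$tensor, "svec")), as.numeric(s_direct),
               tolerance = 1e-9)
})

test_that("collinear bond geometry triggers a rank-deficiency warning, small n an error", {
  # six parallel C-H bonds: all rows proportional, rank 1
  n <- 6
  labels <- c(paste0("C", 1:n), paste0("H", 1:n))
  coords <- rbind(matrix(rnorm(3 * n, 0, 4), n, 3), matrix(0, n, 3))
  coords[(n + 1):(2 * n), ] <- coords[1:n, ] +
    matrix(rep(c(0, 0, 1.09), each = n), n, 3)
  conf <- conformer("c1", labels, c(rep("C", n), rep("H", n)), coords)
  ens <- conformational_ensemble("flat", list(conf))
  rdc <- data.frame(label_a = paste0("C", 1:n), label_b = paste0("H", 1:n),
                    value_hz = rnorm(n, 0, 10), sigma_hz = 0.5)
  d <- build_design_matrix(ens, c(c1 = 1), rdc = rdc)
  expect_warning(fit <- fit_alignment_tensor(d), "rank-deficient")
  expect_true(fit$rank_deficient)

  expect_error(fit_alignment_tensor(
    build_design_matrix(ens, c(c1 = 1), rdc = rdc[1:4, ])),
    "under-determined")
})

test_that("Q factor definition and edge cases", {
  expect_equal(q_factor(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(q_factor(c(1, 2), c(0, 0)), 1)
  expect_equal(q_factor(c(1, 1), c(1, 0)), sqrt(1) / sqrt(2))
  expect_equal(q_factor(c(1, 1), c(1, 0)), 0.70711, tolerance = 1e-5)
  expect_error(q_factor(c(0, 0), c(1, 1)), "all-zero")
  expect_error(q_factor(1:3, 1:2), "equal length")
})

test_that("SVD solution equals the normal-equations oracle and scales equivariantly", {
  set.seed(21)
  ens <- toy3()
  pops <- uniform_pops(ens)
  sim <- simulate_dataset(ens, make_true_tensor(5e-4, 0.3, 1), pops, seed = 9)
  for (i in 1:10) {
    d <- build_design_matrix(ens, pops, rdc = sim$rdc, rcsa = sim$rcsa,
                             shieldings = sim$shieldings)
    d$y <- d$y + rnorm(length(d$y), 0, d$sigma)
    d$y_w <- d$y / d$sigma
    fit <- fit_alignment_tensor(d)
    s_ne <- solve(crossprod(d$A_w), crossprod(d$A_w, d$y_w))
    rss_svd <- sum((d$y_w - drop(d$A_w %*% attr(fit$tensor, "svec")))^2)
    rss_ne <- sum((d$y_w - drop(d$A_w %*% s_ne))^2)
    expect_lt(abs(rss_svd - rss_ne), 1e-9)

    # scaling all values and sigmas by c leaves Q unchanged
    d2 <- d
    d2$y <- 3 * d$y; d2$sigma <- 3 * d$sigma
    d2$A_w <- d$A / d2$sigma; d2$y_w <- d2$y / d2$sigma
    fit2 <- fit_alignment_tensor(d2)
    expect_equal(fit2$q_combined, fit$q_combined, tolerance = 1e-9)
    expect_equal(fit2$data$calc, 3 * fit$data$calc, tolerance = 1e-8)
  }
})

test_that("Q decreases monotonically as noise shrinks (noise-free recovery limit)", {
  ens <- toy3()
  pops <- uniform_pops(ens)
  truth <- make_true_tensor(5e-4, 0.3, 5)
  sim0 <- simulate_dataset(ens, truth, pops,
                           noise = list(rdc_hz = 0, rcsa_ppb = 0,
                                        shift_c13_ppm = 0, shift_h1_ppm = 0),
                           seed = 4)
  qs <- vapply(c(2, 1, 0.5, 0.1, 0.01), function(sd_hz) {
    d <- build_design_matrix(ens, pops, rdc = sim0$rdc)
    set.seed(77)
    d$y <- d$y + rnorm(length(d$y), 0, sd_hz)
    d$y_w <- d$y / d$sigma
    fit_alignment_tensor(d)$q_rdc
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_lt(qs[length(qs)], 0.01)
})

test_that("discriminate reports ties for identical ensembles and flags incomplete configurations", {
  ens <- toy3()
  pops <- uniform_pops(ens)
  sim <- simulate_dataset(ens, make_true_tensor(5e-4, 0.3, 2), pops, seed = 6)

  rep_tie <- discriminate(
    list(A = list(ensemble = ens, populations = pops,
                  shieldings = sim$shieldings),
         B = list(ensemble = ens, populations = pops,
                  shieldings = sim$shieldings)),
    rdc = sim$rdc, rcsa = sim$rcsa, references = "EXTERNAL")
  expect_true(rep_tie$tie)
  expect_equal(rep_tie$verdict$q_combined[1], rep_tie$verdict$q_combined[2],
               tolerance = 1e-12)

  rep_flag <- discriminate(
    list(good = list(ensemble = ens, populations = pops,
                     shieldings = sim$shieldings),
         broken = list(ensemble = ens, populations = pops,
                       shieldings = sim$shieldings[0, ])),
    rdc = sim$rdc, rcsa = sim$rcsa, references = "EXTERNAL")
  expect_equal(rep_flag$best, "good")
  v <- rep_flag$verdict
  expect_true(v$flagged[v$configuration == "broken"])
  expect_false(is.null(rep_flag$configurations$broken$error))
})

test_that("reference choice does not change fit quality for EXTERNAL-referenced synthetic data", {
  ens <- toy3()
  pops <- uniform_pops(ens)
  truth <- make_true_tensor(5e-4, 0.3, 8)
  qs <- replicate(8, {
    seed <- sample.int(1e6, 1)
    sim <- simulate_dataset(ens, truth, pops,
                            noise = list(rdc_hz = 0, rcsa_ppb = 1,
                                         shift_c13_ppm = 0, shift_h1_ppm = 0),
                            seed = seed)
    vapply(c("EXTERNAL", "C2", "C5"), function(ref) {
      # build_design_matrix re-references the observations internally
      fit_tensor_to_data(ens, pops, rcsa = sim$rcsa,
                         shieldings = sim$shieldings,
                         reference = ref)$q_rcsa
    }, numeric(1))
  })
  # per-seed spread across references is below the seed-to-seed noise spread
  within <- apply(qs, 2, function(x) diff(range(x)))
  between <- diff(range(qs["EXTERNAL", ]))
  expect_lt(stats::median(within), between + 0.05)
})

test_that("Monte-Carlo uncertainty of the fit is reproducible and noise-scaled", {
  ens <- toy3()
  pops <- uniform_pops(ens)
  sim <- simulate_dataset(ens, make_true_tensor(5e-4, 0.3, 2), pops, seed = 8)
  d <- build_design_matrix(ens, pops, rdc = sim$rdc)
  mc1 <- tensor_fit_mc(d, draws = 50, seed = 42)
  mc2 <- tensor_fit_mc(d, draws = 50, seed = 42)
  expect_identical(mc1$q, mc2$q)
  expect_true(all(mc1$tensor_sd > 0))
})
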