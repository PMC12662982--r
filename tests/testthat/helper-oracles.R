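# Independent oracles used across the suite. These deliberately take
# different computational paths from the package implementation.

# dipolar constant by direct constant arithmetic (CODATA 2018)
oracle_dipolar <- function(gamma_a, gamma_b, r_angstrom) {
  mu0 <- 1.25663706212e-6
  hbar <- 1.054571817e-34
  -(mu0 / (4 * pi)) * gamma_a * gamma_b * hbar /
    (2 * pi * (r_angstrom * 1e-10)^3)
}

# explicit 9-term contraction for the RCSA back-calculation (ppb)
oracle_rcsa <- function(S, sigma) {
  sym <- (sigma + t(sigma)) / 2
  st <- sym - diag(sum(diag(sym)) / 3, 3)
  acc <- 0
  for (a in 1:3) for (b in 1:3) acc <- acc + S[a, b] * st[a, b]
  -(2 / 3) * acc * 1000
}

# simplex-constrained least squares by exhaustive support enumeration
# (independent of the package's active-set path)
oracle_simplex_ls <- function(A, y) {
  k <- ncol(A)
  best <- NULL
  for (mask in 1:(2^k - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    Af <- A[, idx, drop = FALSE]
    m <- length(idx)
    K <- rbind(cbind(2 * crossprod(Af), rep(1, m)), c(rep(1, m), 0))
    rhs <- c(2 * drop(crossprod(Af, y)), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    p <- sol[seq_len(m)]
    if (any(p < -1e-9)) next
    pf <- numeric(k); pf[idx] <- pmax(p, 0); pf <- pf / sum(pf)
    rss <- sum((drop(A %*% pf) - y)^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(p = pf, rss = rss)
  }
  best
}

# independent CASE-3D scoring: same model definition (alternating scaling +
# simplex population fit, AICc), different solvers throughout
oracle_case3d_rank <- function(shifts, computed, max_subset_size,
                               h_weight = 5, correction = TRUE,
                               tol = 1e-10, max_iter = 100) {
  w_all <- ifelse(shifts$nucleus == "H1", h_weight, 1)
  keep <- w_all > 0
  sh <- shifts[keep, , drop = FALSE]
  C_all <- as.matrix(computed)[keep, , drop = FALSE]
  w <- w_all[keep]
  n <- nrow(sh)
  ids <- colnames(C_all)

  score_subset <- function(sub) {
    C <- C_all[, sub, drop = FALSE]
    p <- rep(1 / length(sub), length(sub))
    params_old <- NULL
    for (it in seq_len(max_iter)) {
      avg <- drop(C %*% p)
      Cs <- C
      params <- c()
      n_classes <- 0L
      for (cls in unique(sh$nucleus)) {
        sel <- sh$nucleus == cls
        if (sum(sel) < 3) { params <- c(params, 1, 0); next }
        b <- stats::coef(stats::lm(sh$exp_ppm[sel] ~ avg[sel]))
        Cs[sel, ] <- b[1] + b[2] * C[sel, , drop = FALSE]
        params <- c(params, b[2], b[1])
        n_classes <- n_classes + 1L
      }
      sol <- oracle_simplex_ls(w * Cs, w * sh$exp_ppm)
      dp <- max(abs(sol$p - p)); p <- sol$p
      dpar <- if (is.null(params_old)) Inf else max(abs(params - params_old))
      params_old <- params
      if (dp < tol && dpar < tol) break
    }
    rss <- sol$rss
    k <- (length(sub) - 1) + 2 * n_classes
    aic <- n * log(rss / n) + 2 * k
    if (correction) aic <- aic + 2 * k * (k + 1) / (n - k - 1)
    list(subset = sub, aic = aic, rss = rss, p = p)
  }

  out <- list()
  for (sz in seq_len(max_subset_size)) {
    for (sub in utils::combn(ids, sz, simplify = FALSE)) {
      out[[length(out) + 1L]] <- score_subset(sub)
    }
  }
  key <- vapply(out, function(x) paste(x$subset, collapse = "|"), character(1))
  out[order(vapply(out, `[[`, numeric(1), "aic"), key)]
}

# shared small fixtures
toy3 <- function() make_toy_ensemble(3, 23, seed = 3)

uniform_pops <- function(ensemble) {
  ids <- conformer_ids(ensemble)
  stats::setNames(rep(1 / length(ids), length(ids)), ids)
}
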