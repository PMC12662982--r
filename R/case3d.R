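# CASE-3D-style ensemble selection from chemical shifts: linear scaling of
# computed shifts, simplex-constrained population fitting, and Akaike-based
# model selection over conformer subsets. Conformers are selected by what
# the experimental shifts support, not by computed energies.

#' Least-squares shift scaling per nucleus class
#'
#' Fits an ordinary least-squares line per nucleus class (1H and 13C
#' separately) mapping computed to experimental shifts, the standard
#' empirical correction for systematic DFT shift errors. A class with fewer
#' than 3 points keeps the identity map (with a warning): two parameters on
#' two points would fit noise exactly.
#'
#' @param shifts data frame with columns `label`, `nucleus` (`"H1"`/`"C13"`),
#'   `exp_ppm`
#' @param computed_avg numeric vector of (population-averaged) computed
#'   shifts, ppm, aligned with the rows of `shifts`
#' @return list with `scaled` (computed values mapped through the fitted
#'   lines) and `params`: per-class list of `slope`, `intercept`, `scaled`
#'   (logical)
#' @export
scale_computed_shifts <- function(shifts, computed_avg) {
  stopifnot(length(computed_avg) == nrow(shifts))
  scaled <- computed_avg
  params <- list()
  for (cls in unique(shifts$nucleus)) {
    sel <- shifts$nucleus == cls
    if (sum(sel) < 3L) {
      warning("fewer than 3 shifts of class ", cls,
              ": scaling disabled (identity map)", call. = FALSE)
      params[[cls]] <- list(slope = 1, intercept = 0, scaled = FALSE)
      next
    }
    fit <- stats::lm.fit(cbind(1, computed_avg[sel]), shifts$exp_ppm[sel])
    b <- fit$coefficients
    scaled[sel] <- b[1L] + b[2L] * computed_avg[sel]
    params[[cls]] <- list(slope = unname(b[2L]), intercept = unname(b[1L]),
                          scaled = TRUE)
  }
  list(scaled = scaled, params = params)
}

# deterministic active-set solver for min ||A p - y||^2, p >= 0, sum(p) = 1.
# Equality-constrained subproblems are solved through the KKT system; a tiny
# ridge handles exactly duplicated columns (duplicate conformers) with a
# deterministic symmetric split.
simplex_ls <- function(A, y, tol = 1e-10, max_iter = 200L) {
  A <- as.matrix(A)
  k <- ncol(A)
  if (k == 1L) {
    p <- 1
    return(list(p = p, rss = sum((drop(A) - y)^2)))
  }
  G <- crossprod(A)
  h <- drop(crossprod(A, y))
  ridge <- 1e-12 * max(1, mean(diag(G)))

  solve_eq <- function(free) {
    idx <- which(free); m <- length(idx)
    K <- rbind(cbind(2 * (G[idx, idx, drop = FALSE] + diag(ridge, m)),
                     rep(1, m)),
               c(rep(1, m), 0))
    rhs <- c(2 * h[idx], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      solve(K + diag(1e-9, m + 1L), rhs)
    })
    list(p = sol[seq_len(m)], lambda = sol[m + 1L])
  }

  free <- rep(TRUE, k)
  p <- rep(1 / k, k)
  for (iter in seq_len(max_iter)) {
    sol <- solve_eq(free)
    p_full <- numeric(k)
    p_full[free] <- sol$p
    if (any(sol$p < -tol)) {
      # bind the most negative free variable
      worst <- which(free)[which.min(sol$p)]
      if (sum(free) == 1L) break
      free[worst] <- FALSE
      next
    }
    p_full[p_full < 0] <- 0
    p_full <- p_full / sum(p_full)
    # KKT check for bound variables: mu_i = 2 (G p - h)_i + lambda >= 0
    if (any(!free)) {
      mu <- 2 * (drop(G %*% p_full) - h) + sol$lambda
      viol <- which(!free & mu < -max(tol, 1e-9 * max(abs(h), 1)))
      if (length(viol) > 0L) {
        free[viol[which.min(mu[viol])]] <- TRUE
        next
      }
    }
    p <- p_full
    break
  }
  list(p = p, rss = sum((drop(A %*% p) - y)^2))
}

#' Fit conformer populations to experimental chemical shifts
#'
#' Minimizes the class-weighted residual sum of squares between experimental
#' shifts and the population-weighted average of (scaled) per-conformer
#' computed shifts, subject to populations on the simplex (non-negative,
#' summing to one). The shift-scaling lines and the populations are
#' optimized jointly by alternation until convergence; a single-pass and a
#' no-scaling mode are available.
#'
#' 1H residuals are multiplied by `h_weight` (default 5) so that the ~5-10x
#' smaller 1H shift dispersion still informs the fit alongside 13C.
#'
#' @param shifts data frame: `label`, `nucleus`, `exp_ppm`
#' @param computed numeric matrix of per-conformer computed shifts, ppm;
#'   rows aligned with `shifts`, columns named by conformer id
#' @param subset character vector of conformer ids to fit (default: all
#'   columns)
#' @param h_weight residual multiplier for 1H shifts (default 5); set to 0
#'   for a 13C-only fit
#' @param scaling `"iterative"` (default), `"single"` (one scaling pass) or
#'   `"none"`
#' @param tol convergence tolerance on populations and scale parameters
#' @param max_iter maximum alternation iterations
#' @return list with `populations` (named, on the simplex), `rss`
#'   (class-weighted, ppm^2), `scale_params`, `fitted` (scaled
#'   population-averaged shifts), `n_iter`
#' @export
fit_populations <- function(shifts, computed, subset = colnames(computed),
                            h_weight = 5.0, scaling = c("iterative", "single",
                                                        "none"),
                            tol = 1e-10, max_iter = 100L) {
  scaling <- match.arg(scaling)
  computed <- as.matrix(computed)
  missing <- setdiff(subset, colnames(computed))
  if (length(missing) > 0L) {
    stop("no computed shifts for conformer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  C <- computed[, subset, drop = FALSE]
  if (nrow(C) != nrow(shifts)) {
    stop("computed shift matrix must align with the shift table",
         call. = FALSE)
  }
  if (anyNA(C)) stop("computed shifts contain NA", call. = FALSE)
  w <- ifelse(shifts$nucleus == "H1", h_weight, 1)
  if (!any(w > 0)) stop("all shift weights are zero", call. = FALSE)
  # zero-weight rows (e.g. 1H in 13C-only mode) leave the analysis entirely:
  # they contribute neither residuals nor scaling parameters
  shifts <- shifts[w > 0, , drop = FALSE]
  C <- C[w > 0, , drop = FALSE]
  w <- w[w > 0]
  use <- rep(TRUE, length(w))

  k <- ncol(C)
  p <- rep(1 / k, k)
  params <- NULL
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    avg <- drop(C %*% p)
    if (scaling == "none") {
      sc <- list(scaled = C,
                 params = lapply(stats::setNames(nm = unique(shifts$nucleus)),
                                 function(.) list(slope = 1, intercept = 0,
                                                  scaled = FALSE)))
      C_scaled <- C
    } else {
      sp <- suppressWarnings(scale_computed_shifts(shifts, avg))
      C_scaled <- C
      for (cls in names(sp$params)) {
        sel <- shifts$nucleus == cls
        pr <- sp$params[[cls]]
        C_scaled[sel, ] <- pr$intercept + pr$slope * C[sel, , drop = FALSE]
      }
      sc <- list(params = sp$params)
    }
    sol <- simplex_ls(w[use] * C_scaled[use, , drop = FALSE],
                      w[use] * shifts$exp_ppm[use])
    p_new <- sol$p
    delta <- max(abs(p_new - p))
    p <- p_new
    params_new <- unlist(lapply(sc$params, function(x) c(x$slope, x$intercept)))
    param_delta <- if (is.null(params)) Inf else max(abs(params_new - params))
    params <- params_new
    if (scaling %in% c("none", "single") ||
        (delta < tol && param_delta < tol) || n_iter >= max_iter) {
      break
    }
  }
  fitted <- drop(C_scaled %*% p)
  rss <- sum((w[use] * (shifts$exp_ppm[use] - fitted[use]))^2)
  names(p) <- subset
  list(populations = p, rss = rss, scale_params = sc$params,
       fitted = fitted, n_iter = n_iter)
}

#' Akaike information criterion for a shift-fit model
#'
#' `AIC = n log(rss / n) + 2 k`, with the small-sample (second-order)
#' correction `AICc = AIC + 2 k (k + 1) / (n - k - 1)` applied by default —
#' appropriate at the n ~ 30 shifts typical here. A perfect fit (rss = 0)
#' returns `-Inf` with attribute `perfect_fit = TRUE`.
#'
#' @param rss residual sum of squares (>= 0)
#' @param n number of observations
#' @param k number of free parameters; must satisfy `n > k + 1`
#' @param correction apply the AICc small-sample correction (default TRUE)
#' @return the criterion value (scalar)
#' @export
aic_score <- function(rss, n, k, correction = TRUE) {
  if (rss < 0) stop("rss must be non-negative", call. = FALSE)
  if (n <= k + 1) {
    stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  if (rss == 0) return(structure(-Inf, perfect_fit = TRUE))
  aic <- n * log(rss / n) + 2 * k
  if (correction) aic <- aic + 2 * k * (k + 1) / (n - k - 1)
  aic
}

#' Enumerate and rank conformer-subset models by AIC
#'
#' Scores every subset of conformers of size 1 to `max_subset_size`:
#' populations and shift-scaling lines are fitted per subset, and the model
#' is scored by (corrected) AIC with `k = (subset size - 1)` population
#' freedoms plus 2 parameters per scaled nucleus class. Models are ranked
#' ascending by AIC, ties broken by subset lexicographic order, so the
#' ranking is fully deterministic.
#'
#' @inheritParams fit_populations
#' @param max_subset_size largest subset size to consider
#' @param correction use AICc (default TRUE)
#' @param guard maximum number of subsets allowed (default 1e6)
#' @return list with `models` (list of model records: `subset`,
#'   `populations`, `scale_params`, `rss`, `n`, `k`, `aic`, `rank`) and
#'   `table` (summary data frame in rank order)
#' @export
enumerate_models <- function(shifts, computed, max_subset_size = NULL,
                             h_weight = 5.0, scaling = "iterative",
                             correction = TRUE, guard = 1e6) {
  computed <- as.matrix(computed)
  ids <- colnames(computed)
  n_conf <- length(ids)
  if (is.null(max_subset_size)) max_subset_size <- n_conf
  if (max_subset_size > n_conf) {
    stop("max_subset_size exceeds the number of conformers", call. = FALSE)
  }
  total <- sum(choose(n_conf, seq_len(max_subset_size)))
  if (total > guard) {
    stop("subset enumeration too large (", format(total, big.mark = ","),
         " subsets); lower max_subset_size", call. = FALSE)
  }
  n_obs <- sum(ifelse(shifts$nucleus == "H1", h_weight, 1) > 0)

  models <- vector("list", total)
  m <- 0L
  for (sz in seq_len(max_subset_size)) {
    combos <- utils::combn(ids, sz, simplify = FALSE)
    for (sub in combos) {
      fit <- fit_populations(shifts, computed, subset = sub,
                             h_weight = h_weight, scaling = scaling)
      n_classes <- sum(vapply(fit$scale_params, `[[`, logical(1), "scaled"))
      k <- (sz - 1L) + 2L * n_classes
      aic <- aic_score(fit$rss, n_obs, k, correction = correction)
      m <- m + 1L
      models[[m]] <- list(subset = sub, populations = fit$populations,
                          scale_params = fit$scale_params, rss = fit$rss,
                          n = n_obs, k = k, aic = as.numeric(aic),
                          perfect_fit = isTRUE(attr(aic, "perfect_fit")))
    }
  }
  subset_key <- vapply(models, function(x) paste(x$subset, collapse = "|"),
                       character(1))
  ord <- order(vapply(models, `[[`, numeric(1), "aic"), subset_key)
  models <- models[ord]
  for (i in seq_along(models)) models[[i]]$rank <- i
  table <- data.frame(
    rank = seq_along(models),
    subset = vapply(models, function(x) paste(x$subset, collapse = "+"),
                    character(1)),
    size = vapply(models, function(x) length(x$subset), integer(1)),
    rss = vapply(models, `[[`, numeric(1), "rss"),
    k = vapply(models, `[[`, integer(1), "k"),
    aic = vapply(models, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE
  )
  list(models = models, table = table)
}

#' CASE-3D configuration selection from chemical shifts
#'
#' Runs the subset enumeration for every candidate configuration against the
#' same experimental shifts, reports the best (S1) and second-best (S2)
#' models per configuration, and declares the configuration holding the
#' lowest global AIC the verdict. The winning subsets are exported as
#' pruned ensembles with FITTED populations, ready for a subsequent
#' alignment-tensor fit.
#'
#' @param configurations named list; each element a list with `ensemble`
#'   (a [conformational_ensemble()]), `shifts` (experimental shift table,
#'   identical across configurations), `computed` (per-conformer computed
#'   shift matrix for that configuration)
#' @inheritParams enumerate_models
#' @param tie_tolerance AIC gap below which the verdict is declared a tie
#' @return an object of class `"case3d_report"`: per-configuration `S1`/`S2`
#'   models and full ranking, `verdict`, `best`, `tie`, and `selected` (per
#'   configuration: pruned ensemble + FITTED [population_set()])
#' @export
case3d_select <- function(configurations, max_subset_size = NULL,
                          h_weight = 5.0, scaling = "iterative",
                          correction = TRUE, tie_tolerance = 2.0) {
  if (length(configurations) < 1L || is.null(names(configurations))) {
    stop("configurations must be a named list", call. = FALSE)
  }
  ref_shifts <- configurations[[1L]]$shifts
  for (label in names(configurations)) {
    sh <- configurations[[label]]$shifts
    if (!isTRUE(all.equal(sh[c("label", "nucleus", "exp_ppm")],
                          ref_shifts[c("label", "nucleus", "exp_ppm")],
                          check.attributes = FALSE))) {
      stop("experimental shift sets differ across configurations ",
           "(protocol requires identical data)", call. = FALSE)
    }
  }
  per_config <- list()
  selected <- list()
  for (label in names(configurations)) {
    cfg <- configurations[[label]]
    enum <- enumerate_models(cfg$shifts, cfg$computed,
                             max_subset_size = max_subset_size,
                             h_weight = h_weight, scaling = scaling,
                             correction = correction)
    s1 <- enum$models[[1L]]
    s2 <- if (length(enum$models) >= 2L) enum$models[[2L]] else NULL
    per_config[[label]] <- list(S1 = s1, S2 = s2, ranking = enum$table)
    sub_ens <- conformational_ensemble(
      cfg$ensemble$configuration_label,
      cfg$ensemble$conformers[s1$subset],
      s1$populations
    )
    selected[[label]] <- list(
      ensemble = sub_ens,
      populations = population_set(s1$populations, source = "FITTED")
    )
  }
  best_aic <- vapply(per_config, function(x) x$S1$aic, numeric(1))
  ord <- order(best_aic, names(per_config))
  verdict <- data.frame(configuration = names(per_config)[ord],
                        aic = best_aic[ord],
                        subset = vapply(per_config[ord], function(x)
                          paste(x$S1$subset, collapse = "+"), character(1)),
                        rank = seq_along(ord),
                        stringsAsFactors = FALSE)
  rownames(verdict) <- NULL
  tie <- nrow(verdict) >= 2L &&
    abs(verdict$aic[1L] - verdict$aic[2L]) < tie_tolerance

  structure(
    list(configurations = per_config, verdict = verdict,
         best = verdict$configuration[1L], tie = tie,
         selected = selected,
         settings = list(max_subset_size = max_subset_size,
                         h_weight = h_weight, scaling = scaling,
                         correction = correction)),
    class = "case3d_report"
  )
}

#' @export
print.case3d_report <- function(x, ...) {
  cat("<case3d_report>", length(x$configurations), "configuration(s)\n")
  print(x$verdict, digits = 6)
  cat(if (isTRUE(x$tie)) "verdict: tie (AIC gap below tolerance)\n"
      else paste("verdict:", x$best, "\n"))
  invisible(x)
}
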