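# Single-alignment-tensor least-squares fitting of RDC and Delta-Delta-RCSA
# data over population-weighted conformer ensembles, Q-factor computation,
# and diastereomer discrimination.
#
# The model is linear: every observable is b * u' S u (RDC) or
# -(2/3) * <S, sigma_tilde> (RCSA), both linear in the 5 independent Saupe
# components. One tensor is shared by all conformers ("single tensor
# approximation"); conformer populations are held fixed during the fit.

# 5 basis tensors for extracting linear coefficients exactly (built lazily:
# alignment_tensor lives in a file collated later)
.saupe_basis_env <- new.env(parent = emptyenv())
.saupe_basis <- function() {
  if (is.null(.saupe_basis_env$basis)) {
    .saupe_basis_env$basis <- lapply(1:5, function(k) {
      v <- numeric(5); v[k] <- 1
      alignment_tensor(v)
    })
  }
  .saupe_basis_env$basis
}

# per-conformer 5-coefficient row for one RDC datum
.rdc_row <- function(conf, label_a, label_b, r_scale = 1.0) {
  vapply(.saupe_basis(), function(B)
    back_calc_rdc(conf, label_a, label_b, B, r_scale = r_scale), numeric(1))
}

# per-conformer 5-coefficient row for one RCSA datum
.rcsa_row <- function(sigma) {
  vapply(.saupe_basis(), function(B) back_calc_rcsa(sigma, B), numeric(1))
}

# pull the 3x3 shielding matrix for (conformer_id, label) from the long table
.shielding_matrix <- function(shieldings, conformer_id, label) {
  hit <- shieldings$conformer_id == conformer_id & shieldings$label == label
  if (sum(hit) == 0L) return(NULL)
  row <- shieldings[which(hit)[1L], , drop = FALSE]
  matrix(as.numeric(row[1L, c("s_xx", "s_xy", "s_xz",
                              "s_yx", "s_yy", "s_yz",
                              "s_zx", "s_zy", "s_zz")]),
         3L, 3L, byrow = TRUE)
}

#' Build the design matrix of a single-tensor ensemble fit
#'
#' Each row maps the five Saupe components to one observed datum. Rows are
#' population-weighted averages of per-conformer linear coefficients. For
#' Delta-Delta-RCSA data, the reference carbon's (population-averaged)
#' coefficient row is subtracted from every RCSA row, mirroring the
#' experimental referencing; the sentinel reference `"EXTERNAL"` subtracts
#' nothing. A datum whose atom is the reference itself is excluded. Rows and
#' observations are returned both raw and divided by the per-datum sigma.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param populations [population_set()] or named weights covering the
#'   ensemble
#' @param rdc optional data frame with columns `label_a`, `label_b`,
#'   `value_hz`, `sigma_hz`
#' @param rcsa optional data frame with columns `label`, `value_ppb`,
#'   `sigma_ppb`, and optionally `reference`
#' @param shieldings data frame of per-conformer shielding tensors (columns
#'   `conformer_id`, `label`, `s_xx` .. `s_zz`, ppm); required when `rcsa`
#'   is given
#' @param reference reference specification for the RCSA block: an atom
#'   label, `"EXTERNAL"`, or `NULL` to use each datum's own `reference`
#'   column
#' @param r_scale uniform one-bond distance scale factor (default 1)
#' @return list with `A` (n x 5, raw units), `y` (raw observations),
#'   `sigma`, `A_w`/`y_w` (sigma-weighted), and `meta` (data frame with
#'   `type`, `label`, `exp`, `sigma`)
#' @export
build_design_matrix <- function(ensemble, populations, rdc = NULL,
                                rcsa = NULL, shieldings = NULL,
                                reference = NULL, r_scale = 1.0) {
  ids <- conformer_ids(ensemble)
  w <- as.numeric(populations)[match(ids, names(populations))]
  if (anyNA(w)) {
    stop("populations must cover every conformer of the ensemble",
         call. = FALSE)
  }
  w <- w / sum(w)

  rows <- list(); obs <- numeric(0); sig <- numeric(0)
  type <- character(0); lab <- character(0)

  if (!is.null(rdc) && nrow(rdc) > 0L) {
    for (i in seq_len(nrow(rdc))) {
      coeff <- Reduce(`+`, Map(function(conf, p)
        p * .rdc_row(conf, rdc$label_a[i], rdc$label_b[i], r_scale),
        ensemble$conformers, w))
      rows[[length(rows) + 1L]] <- coeff
      obs <- c(obs, rdc$value_hz[i]); sig <- c(sig, rdc$sigma_hz[i])
      type <- c(type, "rdc")
      lab <- c(lab, paste0(rdc$label_a[i], "-", rdc$label_b[i]))
    }
  }

  if (!is.null(rcsa) && nrow(rcsa) > 0L) {
    if (is.null(shieldings)) {
      stop("RCSA data require per-conformer shielding tensors", call. = FALSE)
    }
    stored <- if (is.null(rcsa$reference)) rep("EXTERNAL", nrow(rcsa)) else rcsa$reference
    refs <- if (is.null(reference)) stored else rep(reference, nrow(rcsa))
    values <- rcsa$value_ppb
    # re-reference the observations when the requested scheme differs from
    # the one the data were recorded against: subtracting the new reference
    # atom's (equally-referenced) value cancels the old common offset
    if (!is.null(reference)) {
      for (i in seq_len(nrow(rcsa))) {
        if (identical(refs[i], stored[i])) next
        if (identical(refs[i], "EXTERNAL")) {
          stop("cannot convert internally referenced RCSA data (reference '",
               stored[i], "') back to EXTERNAL referencing", call. = FALSE)
        }
        j <- which(rcsa$label == refs[i])
        if (length(j) != 1L) {
          stop("cannot re-reference RCSA data to '", refs[i],
               "': no datum for that atom", call. = FALSE)
        }
        if (!identical(stored[j], stored[i])) {
          stop("mixed stored references prevent re-referencing to '",
               refs[i], "'", call. = FALSE)
        }
        values[i] <- rcsa$value_ppb[i] - rcsa$value_ppb[j]
      }
    }

    # population-averaged coefficient row per carbon (computed lazily)
    avg_row <- local({
      cache <- new.env(parent = emptyenv())
      function(label) {
        if (!is.null(cache[[label]])) return(cache[[label]])
        gaps <- character(0)
        acc <- numeric(5)
        for (k in seq_along(ids)) {
          sg <- .shielding_matrix(shieldings, ids[k], label)
          if (is.null(sg)) { gaps <- c(gaps, ids[k]); next }
          acc <- acc + w[k] * .rcsa_row(sg)
        }
        if (length(gaps) > 0L) {
          stop("missing shielding tensor(s) for atom '", label,
               "' in conformer(s): ", paste(gaps, collapse = ", "),
               call. = FALSE)
        }
        cache[[label]] <- acc
        acc
      }
    })

    for (i in seq_len(nrow(rcsa))) {
      ref_i <- refs[i]
      if (!identical(ref_i, "EXTERNAL") && identical(rcsa$label[i], ref_i)) {
        next    # the reference's own entry is identically zero, not a residual
      }
      coeff <- avg_row(rcsa$label[i])
      if (!identical(ref_i, "EXTERNAL")) {
        if (!ref_i %in% ensemble_labels(ensemble)) {
          stop("RCSA reference atom '", ref_i, "' not in the ensemble",
               call. = FALSE)
        }
        coeff <- coeff - avg_row(ref_i)
      }
      rows[[length(rows) + 1L]] <- coeff
      obs <- c(obs, values[i]); sig <- c(sig, rcsa$sigma_ppb[i])
      type <- c(type, "rcsa"); lab <- c(lab, rcsa$label[i])
    }
  }

  if (length(rows) == 0L) stop("no data rows to fit", call. = FALSE)
  if (any(sig <= 0)) stop("all sigmas must be positive", call. = FALSE)
  A <- do.call(rbind, rows)
  colnames(A) <- c("Szz", "Sxx_yy", "Sxy", "Sxz", "Syz")
  list(A = A, y = obs, sigma = sig,
       A_w = A / sig, y_w = obs / sig,
       meta = data.frame(type = type, label = lab, exp = obs, sigma = sig,
                         stringsAsFactors = FALSE))
}

#' Q factor: normalized RMS deviation between experiment and back-calculation
#'
#' `Q = sqrt(sum((exp - calc)^2)) / sqrt(sum(exp^2))`. Zero iff the
#' back-calculation reproduces every value; a calc vector of zeros gives
#' Q = 1. For mixed-unit (combined RDC + RCSA) blocks, compute it on
#' sigma-normalized values so Hz and ppb are commensurate.
#'
#' @param exp experimental values
#' @param calc back-calculated values, same length
#' @return dimensionless Q
#' @export
q_factor <- function(exp, calc) {
  if (length(exp) != length(calc) || length(exp) < 1L) {
    stop("exp and calc must be non-empty vectors of equal length",
         call. = FALSE)
  }
  denom <- sqrt(sum(exp^2))
  if (denom == 0) stop("Q factor undefined for an all-zero exp vector",
                       call. = FALSE)
  sqrt(sum((exp - calc)^2)) / denom
}

#' Fit the alignment tensor by singular value decomposition
#'
#' Minimum-norm least-squares solution of the sigma-weighted linear system.
#' Singular values below `1e-10` times the largest are treated as rank
#' deficiency: the corresponding directions are dropped (pseudo-inverse) and
#' the result is flagged with a warning rather than failing silently.
#'
#' @param design output of [build_design_matrix()]
#' @param weighting `"sigma"` (default; rows already divided by per-datum
#'   sigma) or `"balanced"` (each data block additionally rescaled to unit
#'   RMS of its weighted observations, so RDC and RCSA blocks contribute
#'   equally regardless of how many data they have)
#' @return an object of class `"aniso_fit"`: tensor, per-datum
#'   back-calculated values and residuals, block Q factors (`q_rdc`,
#'   `q_rcsa` on raw values; `q_combined` on sigma-normalized values),
#'   `n_data`, `condition_number`, `singular_values`, `rank_deficient`
#' @export
fit_alignment_tensor <- function(design, weighting = c("sigma", "balanced")) {
  weighting <- match.arg(weighting)
  A_w <- design$A_w; y_w <- design$y_w
  if (nrow(A_w) < 5L) {
    stop("under-determined fit: need at least 5 data (got ", nrow(A_w), ")",
         call. = FALSE)
  }
  if (weighting == "balanced") {
    for (tp in unique(design$meta$type)) {
      sel <- design$meta$type == tp
      rms <- sqrt(mean(y_w[sel]^2))
      if (rms > 0) { A_w[sel, ] <- A_w[sel, ] / rms; y_w[sel] <- y_w[sel] / rms }
    }
  }

  sv <- svd(A_w)
  tol <- 1e-10 * max(sv$d)
  keep <- sv$d > tol
  if (!all(keep)) {
    warning("rank-deficient design matrix (rank ", sum(keep),
            " of 5): minimum-norm solution returned", call. = FALSE)
  }
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  s_hat <- sv$v %*% (d_inv * (t(sv$u) %*% y_w))
  tensor <- alignment_tensor(as.numeric(s_hat))

  calc <- drop(design$A %*% as.numeric(s_hat))
  resid <- design$y - calc
  meta <- design$meta
  meta$calc <- calc
  meta$residual <- resid

  is_rdc <- meta$type == "rdc"
  is_rcsa <- meta$type == "rcsa"
  q_rdc <- if (any(is_rdc)) q_factor(design$y[is_rdc], calc[is_rdc]) else NA_real_
  q_rcsa <- if (any(is_rcsa)) q_factor(design$y[is_rcsa], calc[is_rcsa]) else NA_real_
  q_combined <- q_factor(design$y / design$sigma, calc / design$sigma)

  structure(
    list(tensor = tensor,
         data = meta,
         q_rdc = q_rdc, q_rcsa = q_rcsa, q_combined = q_combined,
         n_data = c(rdc = sum(is_rdc), rcsa = sum(is_rcsa)),
         condition_number = max(sv$d) / min(sv$d[keep]),
         singular_values = sv$d,
         rank_deficient = !all(keep),
         weighting = weighting),
    class = "aniso_fit"
  )
}

#' @export
print.aniso_fit <- function(x, ...) {
  cat("<aniso_fit>", sum(x$n_data), "data (",
      x$n_data[["rdc"]], "RDC,", x$n_data[["rcsa"]], "RCSA )\n")
  cat(sprintf("  Q(rdc)=%s Q(rcsa)=%s Q(combined)=%.4f cond=%.1f\n",
              ifelse(is.na(x$q_rdc), "-", sprintf("%.4f", x$q_rdc)),
              ifelse(is.na(x$q_rcsa), "-", sprintf("%.4f", x$q_rcsa)),
              x$q_combined, x$condition_number))
  invisible(x)
}

#' Monte-Carlo uncertainty of a tensor fit
#'
#' Resamples the observations within their stated sigmas (Gaussian), refits,
#' and reports the spread of the Q factor and of the five tensor components.
#'
#' @param design output of [build_design_matrix()]
#' @param draws number of Monte-Carlo draws (default 500)
#' @param seed integer seed for reproducibility
#' @param weighting passed to [fit_alignment_tensor()]
#' @return list with `q_sd`, `tensor_sd` (length-5), and the draws' Q values
#' @export
tensor_fit_mc <- function(design, draws = 500, seed = 1,
                          weighting = "sigma") {
  set.seed(seed)
  qs <- numeric(draws)
  svecs <- matrix(0, draws, 5)
  for (b in seq_len(draws)) {
    d2 <- design
    d2$y <- design$y + stats::rnorm(length(design$y), 0, design$sigma)
    d2$y_w <- d2$y / d2$sigma
    fit <- suppressWarnings(fit_alignment_tensor(d2, weighting = weighting))
    qs[b] <- fit$q_combined
    svecs[b, ] <- attr(fit$tensor, "svec")
  }
  list(q_sd = stats::sd(qs), tensor_sd = apply(svecs, 2, stats::sd), q = qs)
}

#' Fit one configuration against RDC and/or RCSA data
#'
#' Convenience wrapper: builds the design matrix and fits in one call.
#'
#' @inheritParams build_design_matrix
#' @inheritParams fit_alignment_tensor
#' @return an `"aniso_fit"` object
#' @export
fit_tensor_to_data <- function(ensemble, populations, rdc = NULL, rcsa = NULL,
                               shieldings = NULL, reference = NULL,
                               weighting = "sigma", r_scale = 1.0) {
  design <- build_design_matrix(ensemble, populations, rdc = rdc, rcsa = rcsa,
                                shieldings = shieldings, reference = reference,
                                r_scale = r_scale)
  fit_alignment_tensor(design, weighting = weighting)
}

#' Discriminate candidate configurations by fit quality
#'
#' Fits every candidate configuration against the same experimental data:
#' an RDC-only fit, one Delta-Delta-RCSA fit per reference scheme, and one
#' combined (simultaneous RDC + RCSA) fit per reference scheme. The verdict
#' orders configurations by the combined Q of the primary (first) reference
#' scheme, breaking ties by the RDC-only Q and then by label; differences in
#' combined Q below `tie_tolerance` are declared indistinguishable (Q
#' differences at the third decimal are below experimental reproducibility).
#'
#' @param configurations named list; each element a list with components
#'   `ensemble` (a [conformational_ensemble()]), `populations`, and
#'   `shieldings` (per-conformer shielding table for that configuration's
#'   geometries)
#' @param rdc experimental RDC data frame (shared by all configurations)
#' @param rcsa experimental RCSA data frame (shared by all configurations)
#' @param references character vector of reference schemes (atom labels
#'   and/or `"EXTERNAL"`); the first is the primary scheme for the verdict
#' @param weighting `"sigma"` or `"balanced"`, see [fit_alignment_tensor()]
#' @param tie_tolerance combined-Q difference below which two configurations
#'   are reported as indistinguishable (default 0.005)
#' @return an object of class `"discrimination_report"`
#' @export
discriminate <- function(configurations, rdc = NULL, rcsa = NULL,
                         references = "EXTERNAL", weighting = "sigma",
                         tie_tolerance = 0.005) {
  if (length(configurations) < 1L || is.null(names(configurations))) {
    stop("configurations must be a named list", call. = FALSE)
  }
  results <- list()
  for (label in names(configurations)) {
    cfg <- configurations[[label]]
    fits <- list()
    err <- NULL
    fit_try <- function(expr) tryCatch(expr, error = function(e) e)

    if (!is.null(rdc)) {
      fits[["rdc"]] <- fit_try(fit_tensor_to_data(
        cfg$ensemble, cfg$populations, rdc = rdc, weighting = weighting))
    }
    if (!is.null(rcsa)) {
      for (ref in references) {
        fits[[paste0("rcsa:", ref)]] <- fit_try(fit_tensor_to_data(
          cfg$ensemble, cfg$populations, rcsa = rcsa,
          shieldings = cfg$shieldings, reference = ref,
          weighting = weighting))
        if (!is.null(rdc)) {
          fits[[paste0("combined:", ref)]] <- fit_try(fit_tensor_to_data(
            cfg$ensemble, cfg$populations, rdc = rdc, rcsa = rcsa,
            shieldings = cfg$shieldings, reference = ref,
            weighting = weighting))
        }
      }
    }
    failed <- vapply(fits, inherits, logical(1), "error")
    if (any(failed)) {
      err <- paste(vapply(fits[failed], conditionMessage, character(1)),
                   collapse = "; ")
    }
    results[[label]] <- list(fits = fits[!failed], error = err,
                             populations = cfg$populations)
  }

  primary <- if (!is.null(rcsa) && !is.null(rdc)) {
    paste0("combined:", references[1L])
  } else if (!is.null(rdc)) "rdc" else paste0("rcsa:", references[1L])

  verdict <- data.frame(configuration = names(results),
                        q_combined = NA_real_, q_rdc = NA_real_,
                        flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(verdict))) {
    res <- results[[verdict$configuration[i]]]
    f <- res$fits[[primary]]
    if (is.null(f)) { verdict$flagged[i] <- TRUE; next }
    verdict$q_combined[i] <- f$q_combined
    verdict$q_rdc[i] <- if (!is.null(res$fits[["rdc"]]))
      res$fits[["rdc"]]$q_rdc else f$q_rdc
  }
  ord <- order(verdict$flagged, verdict$q_combined, verdict$q_rdc,
               verdict$configuration)
  verdict <- verdict[ord, , drop = FALSE]
  rownames(verdict) <- NULL
  verdict$rank <- seq_len(nrow(verdict))
  tie <- nrow(verdict) >= 2L && !any(verdict$flagged[1:2]) &&
    abs(verdict$q_combined[1L] - verdict$q_combined[2L]) < tie_tolerance

  structure(
    list(configurations = results, verdict = verdict,
         best = verdict$configuration[1L], tie = tie,
         primary_block = primary, references = references,
         weighting = weighting, tie_tolerance = tie_tolerance,
         n_data = c(rdc = if (is.null(rdc)) 0L else nrow(rdc),
                    rcsa = if (is.null(rcsa)) 0L else nrow(rcsa))),
    class = "discrimination_report"
  )
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("<discrimination_report>", length(x$configurations),
      "configuration(s);", x$n_data[["rdc"]], "RDC,",
      x$n_data[["rcsa"]], "RCSA; primary block:", x$primary_block, "\n")
  print(x$verdict, digits = 4)
  if (isTRUE(x$tie)) {
    cat("verdict: indistinguishable (combined-Q gap below ",
        x$tie_tolerance, ")\n", sep = "")
  } else if (length(x$configurations) >= 2L) {
    cat("verdict:", x$best, "\n")
  } else {
    cat("verdict: no comparison (single configuration)\n")
  }
  invisible(x)
}
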