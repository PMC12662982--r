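# Alignment (Saupe) tensor algebra and back-calculation of anisotropic NMR
# observables: one-bond (or generic two-spin) RDCs and 13C RCSAs.
#
# Conventions, fixed and tested for self-consistency:
#  * dipolar constant b = -(mu0/4pi) * gamma_a * gamma_b * hbar / (2 pi r^3),
#    in Hz, r the internuclear distance. For 1H-13C at 1.09 A this gives
#    b ~ -23.3 kHz.
#  * RDC(u) = b * t(u) %*% S %*% u for the internuclear unit vector u.
#  * RCSA = -(2/3) * sum_ab S_ab * sigma_tilde_ab, reported on the
#    chemical-shift (delta) scale in ppb; sigma_tilde is the traceless
#    symmetric part of the shielding tensor (ppm) in the conformer frame.
#    The minus sign is the single shielding-to-shift flip.

#' Construct an alignment (Saupe) tensor
#'
#' The alignment tensor is a traceless symmetric 3x3 order matrix with five
#' independent components. It can be built from a full matrix (symmetrized
#' and trace-projected if marginally off) or from the 5-vector
#' `(S_zz, S_xx - S_yy, S_xy, S_xz, S_yz)`.
#'
#' @param x a 3x3 numeric matrix, or a numeric vector of length 5
#' @return an object of class `"alignment_tensor"`: the 3x3 matrix with the
#'   5-vector in attribute `"svec"`
#' @export
alignment_tensor <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3L, 3L))) stop("matrix must be 3x3", call. = FALSE)
    if (max(abs(x - t(x))) > 1e-8) {
      stop("alignment tensor must be symmetric", call. = FALSE)
    }
    S <- (x + t(x)) / 2
    if (abs(sum(diag(S))) > 1e-8 * max(1, max(abs(S)))) {
      stop("alignment tensor must be traceless", call. = FALSE)
    }
    S <- S - diag(sum(diag(S)) / 3, 3L)
  } else {
    x <- as.numeric(x)
    if (length(x) != 5L) stop("need a 3x3 matrix or a 5-vector", call. = FALSE)
    S <- saupe_from_vec(x)
  }
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(S, svec = saupe_to_vec(S), class = c("alignment_tensor", "matrix"))
}

#' 5-vector of a Saupe matrix
#'
#' @param S 3x3 traceless symmetric matrix
#' @return numeric length-5 vector `(S_zz, S_xx - S_yy, S_xy, S_xz, S_yz)`
#' @export
saupe_to_vec <- function(S) {
  c(Szz = S[3, 3], Sxx_yy = S[1, 1] - S[2, 2],
    Sxy = S[1, 2], Sxz = S[1, 3], Syz = S[2, 3])
}

#' Saupe matrix from its 5-vector
#'
#' @param v numeric length-5 `(S_zz, S_xx - S_yy, S_xy, S_xz, S_yz)`
#' @return 3x3 traceless symmetric matrix
#' @export
saupe_from_vec <- function(v) {
  stopifnot(length(v) == 5L)
  szz <- v[[1L]]; d <- v[[2L]]
  sxx <- (-szz + d) / 2
  syy <- (-szz - d) / 2
  matrix(c(sxx,    v[[3L]], v[[4L]],
           v[[3L]], syy,    v[[5L]],
           v[[4L]], v[[5L]], szz), 3L, 3L)
}

#' Principal-frame decomposition of an alignment tensor
#'
#' Eigenvalues are ordered by magnitude, `|S_zz| >= |S_yy| >= |S_xx|`, the
#' usual convention for reporting axial component and rhombicity.
#'
#' @param tensor an [alignment_tensor()] or 3x3 matrix
#' @return list with `values` (named `Sxx`, `Syy`, `Szz`) and `vectors`
#'   (columns in the same order)
#' @export
tensor_eigen <- function(tensor) {
  e <- eigen(unclass(tensor)[1:3, 1:3], symmetric = TRUE)
  ord <- order(abs(e$values))          # |Sxx| <= |Syy| <= |Szz|
  values <- e$values[ord]
  names(values) <- c("Sxx", "Syy", "Szz")
  list(values = values, vectors = e$vectors[, ord, drop = FALSE])
}

#' Dipolar coupling constant of a two-spin pair
#'
#' `b = -(mu0 / 4 pi) * gamma_a * gamma_b * hbar / (2 pi r^3)` in Hz, with
#' CODATA-2018 constants and `r` in Angstrom. For a one-bond 1H-13C pair at
#' r = 1.09 A the magnitude is about 23.3 kHz.
#'
#' @param isotope_a,isotope_b isotope codes (or element symbols), see
#'   [gyromagnetic_ratio()]
#' @param r internuclear distance, Angstrom; must exceed 0.5 A
#' @return the dipolar constant in Hz (signed)
#' @export
dipolar_constant <- function(isotope_a, isotope_b, r) {
  if (any(r <= 0.5)) {
    stop("internuclear distance must exceed 0.5 Angstrom (got ",
         paste(format(r[r <= 0.5]), collapse = ", "), ")", call. = FALSE)
  }
  ga <- gyromagnetic_ratio(isotope_a)
  gb <- gyromagnetic_ratio(isotope_b)
  r_m <- r * 1e-10
  -(aniso_constants$mu0 / (4 * pi)) * ga * gb * aniso_constants$hbar /
    (2 * pi * r_m^3)
}

#' Back-calculate an RDC for one conformer
#'
#' `D = b * t(u) S u` with `u` the internuclear unit vector in the conformer
#' frame; linear in the five tensor components.
#'
#' @param conf a [conformer()]
#' @param label_a,label_b atom labels of the coupled pair
#' @param tensor an [alignment_tensor()]
#' @param r_scale uniform scale factor applied to the internuclear distance
#'   before the `r^-3` factor (hook for effective bond lengths; default 1)
#' @return back-calculated RDC in Hz
#' @export
back_calc_rdc <- function(conf, label_a, label_b, tensor, r_scale = 1.0) {
  if (identical(label_a, label_b)) {
    stop("a dipolar pair needs two distinct atoms", call. = FALSE)
  }
  idx <- .atom_index(conf, c(label_a, label_b))
  rvec <- conf$coords[idx[2L], ] - conf$coords[idx[1L], ]
  r <- sqrt(sum(rvec^2))
  if (r < 1e-6) {
    stop("zero-length internuclear vector for pair ", label_a, "-", label_b,
         " in conformer '", conf$conformer_id, "'", call. = FALSE)
  }
  u <- rvec / r
  b <- dipolar_constant(conf$elements[idx[1L]], conf$elements[idx[2L]],
                        r * r_scale)
  S <- unclass(tensor)[1:3, 1:3]
  b * drop(u %*% S %*% u)
}

#' Back-calculate an RCSA from a shielding tensor
#'
#' `RCSA = -(2/3) * sum_ab S_ab sigma_tilde_ab`, in ppb, where `sigma_tilde`
#' is the traceless symmetric part of the shielding tensor (ppm, conformer
#' frame). The isotropic part of the shielding never contributes (it is
#' annihilated by the traceless Saupe matrix); the minus sign converts from
#' the shielding to the chemical-shift scale.
#'
#' @param sigma 3x3 nuclear shielding tensor, ppm (need not be symmetric or
#'   traceless; the traceless symmetric part is used)
#' @param tensor an [alignment_tensor()]
#' @return RCSA in ppb
#' @export
back_calc_rcsa <- function(sigma, tensor) {
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(3L, 3L)) || !all(is.finite(sigma))) {
    stop("shielding tensor must be a finite 3x3 matrix", call. = FALSE)
  }
  sym <- (sigma + t(sigma)) / 2
  sig_tilde <- sym - diag(sum(diag(sym)) / 3, 3L)
  S <- unclass(tensor)[1:3, 1:3]
  # ppm * 1000 -> ppb
  -(2 / 3) * sum(S * sig_tilde) * 1000
}

#' Apply Delta-Delta referencing to RCSA values
#'
#' Experimental RCSAs are measured as differences between two alignment
#' states and additionally referenced to a chosen carbon to cancel isotropic
#' drifts. This subtracts the reference atom's value from every entry; the
#' sentinel `"EXTERNAL"` (e.g. the solvent carbon) subtracts zero. The
#' reference atom's own entry becomes exactly 0 and should be excluded from
#' fit residuals.
#'
#' @param values named numeric vector, ppb, keyed by atom label
#' @param reference_spec an atom label present in `values`, or `"EXTERNAL"`
#' @return named numeric vector of the same length, referenced
#' @export
delta_delta_rcsa <- function(values, reference_spec) {
  if (identical(reference_spec, "EXTERNAL")) return(values)
  if (!reference_spec %in% names(values)) {
    stop("reference atom '", reference_spec, "' not among the RCSA values",
         call. = FALSE)
  }
  out <- values - values[[reference_spec]]
  out[reference_spec] <- 0
  out
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat("<alignment_tensor>\n")
  print(unclass(x)[1:3, 1:3], digits = 4)
  ev <- tensor_eigen(x)$values
  cat("principal values:",
      paste(sprintf("%s=%.3e", names(ev), ev), collapse = ", "), "\n")
  invisible(x)
}
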