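# Ground-truthed synthetic inputs: toy conformer ensembles built from
# internal coordinates, alignment tensors with chosen eigenstructure,
# per-conformer shielding tensors attached to local molecular frames, noisy
# RDC/RCSA/shift tables, and inverted-stereocenter decoy configurations.
# Every output is a pure function of (parameters, seed).

# run code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rotation matrix about unit axis by angle (radians), Rodrigues
.rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# seeded uniform random rotation (QR of Gaussian matrix, det fixed to +1)
.random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3L, 3L)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

.BOND_CC <- 1.53   # Angstrom
.BOND_CH <- 1.09
.TETRA <- acos(-1 / 3)   # 109.47 deg

# directions of m substituents on an atom whose incoming bond direction
# (parent -> atom) is d: tetrahedral angle to -d, azimuths phase + k*120 deg
.substituent_dirs <- function(d, m, phase = 0) {
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  lapply(seq_len(m) - 1L, function(k) {
    phi <- phase + k * 2 * pi / 3
    ang <- pi - .TETRA   # angle from +d
    cos(ang) * d + sin(ang) * (cos(phi) * e1 + sin(phi) * e2)
  })
}

# grow an all-trans -CH2-...-CH3 zig-zag chain of n_c carbons from parent at
# p0 along initial bond direction d0. Bond vectors alternate between two
# directions 70.53 deg apart (tetrahedral trans chain), so the chain extends
# away from the core without folding back.
.grow_chain <- function(p0, d0, n_c, c_start) {
  d0 <- d0 / sqrt(sum(d0^2))
  ref <- if (abs(d0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- c(d0[2] * ref[3] - d0[3] * ref[2],
         d0[3] * ref[1] - d0[1] * ref[3],
         d0[1] * ref[2] - d0[2] * ref[1])
  w <- w / sqrt(sum(w^2))
  b1 <- d0
  b2 <- drop(.rotation_about(w, pi - .TETRA) %*% b1)
  bonds <- list(b1, b2)
  half <- .TETRA / 2

  labels <- character(0); elements <- character(0); coords <- NULL
  pos <- p0
  for (i in seq_len(n_c)) {
    b_in <- bonds[[(i - 1L) %% 2L + 1L]]
    c_pos <- pos + .BOND_CC * b_in
    labels <- c(labels, paste0("C", c_start + i - 1L))
    elements <- c(elements, "C")
    coords <- rbind(coords, c_pos)
    terminal <- i == n_c
    if (!terminal) {
      b_out <- bonds[[i %% 2L + 1L]]
      u <- -b_in; v <- b_out
      s <- -(u + v); s <- s / sqrt(sum(s^2))
      for (h in 1:2) {
        hdir <- cos(half) * s + (if (h == 1L) 1 else -1) * sin(half) * w
        labels <- c(labels, paste0("H", c_start + i - 1L, letters[h]))
        elements <- c(elements, "H")
        coords <- rbind(coords, c_pos + .BOND_CH * hdir)
      }
      pos <- c_pos
    } else {
      subs <- .substituent_dirs(b_in, 3L, phase = pi / 3)
      for (h in 1:3) {
        labels <- c(labels, paste0("H", c_start + i - 1L, letters[h]))
        elements <- c(elements, "H")
        coords <- rbind(coords, c_pos + .BOND_CH * subs[[h]])
      }
    }
  }
  list(labels = labels, elements = elements, coords = coords)
}

#' Generate a toy conformational ensemble
#'
#' Builds a small saturated molecule from internal coordinates — a
#' stereogenic carbon carrying a hydrogen, a methyl group, and two alkyl
#' chains of unequal length — and produces conformers by rotating the two
#' chains about their bonds to the stereocenter. This emulates conformer
#' families that differ by ring/substituent rotation. Bond lengths are
#' realistic (C-H 1.09 A, C-C 1.53 A), labels are NMR-style (`C1`, `H3a`),
#' and a small seeded coordinate jitter (shared by all conformers) breaks
#' exact symmetry. Purely deterministic per seed.
#'
#' @param n_conformers number of conformers (>= 1)
#' @param n_atoms requested atom count in `[10, 60]`; realized by sizing the
#'   longer chain, so the actual count is the nearest realizable size
#'   (reported in the returned object)
#' @param dihedral_spec list with numeric vectors `first` and optionally
#'   `second`: rotation angles in degrees for the two chains, recycled to
#'   `n_conformers`. Default: `first` evenly spaced over 0-360.
#' @param seed integer seed
#' @param jitter_sd coordinate jitter SD in Angstrom (default 0.02)
#' @return a [conformational_ensemble()]; conformer ids `"c1"`, `"c2"`, ...
#' @export
make_toy_ensemble <- function(n_conformers, n_atoms = 23,
                              dihedral_spec = NULL, seed = 1,
                              jitter_sd = 0.02) {
  if (n_conformers < 1L) stop("need at least one conformer", call. = FALSE)
  if (n_atoms < 10L || n_atoms > 60L) {
    stop("n_atoms must be in [10, 60]", call. = FALSE)
  }
  # atoms = 2 (C1, H1) + 4 (methyl) + (3*n3 + 1) + (3*n4 + 1)
  n3 <- 2L
  n4 <- max(1L, as.integer(round((n_atoms - 8L - 3L * n3) / 3)))
  if (is.null(dihedral_spec)) {
    dihedral_spec <- list(first = seq(0, 360, length.out = n_conformers + 1L)[
      seq_len(n_conformers)])
  }
  first <- rep_len(dihedral_spec$first, n_conformers)
  second <- if (!is.null(dihedral_spec$second)) {
    rep_len(dihedral_spec$second, n_conformers)
  } else rep(0, n_conformers)

  with_seed(seed, {
    # tetrahedral frame at the stereocenter C1 (origin)
    t_dirs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    t_dirs <- lapply(t_dirs, function(v) v / sqrt(3))

    labels <- "C1"; elements <- "C"; coords <- rbind(c(0, 0, 0))
    # H on the stereocenter
    labels <- c(labels, "H1"); elements <- c(elements, "H")
    coords <- rbind(coords, .BOND_CH * t_dirs[[1L]])
    # methyl branch
    c2 <- .BOND_CC * t_dirs[[2L]]
    labels <- c(labels, "C2"); elements <- c(elements, "C")
    coords <- rbind(coords, c2)
    for (h in 1:3) {
      labels <- c(labels, paste0("H2", letters[h])); elements <- c(elements, "H")
      coords <- rbind(coords,
                      c2 + .BOND_CH * .substituent_dirs(t_dirs[[2L]], 3L)[[h]])
    }
    # first chain (n3 carbons) from C3
    ch3 <- .grow_chain(c(0, 0, 0), t_dirs[[3L]], n3, 3L)
    labels <- c(labels, ch3$labels); elements <- c(elements, ch3$elements)
    coords <- rbind(coords, ch3$coords)
    branch3 <- ch3$labels
    # second chain (n4 carbons) from C(3 + n3)
    ch4 <- .grow_chain(c(0, 0, 0), t_dirs[[4L]], n4, 3L + n3)
    labels <- c(labels, ch4$labels); elements <- c(elements, ch4$elements)
    coords <- rbind(coords, ch4$coords)
    branch4 <- ch4$labels

    coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                              nrow(coords), 3L)

    rotate_branch <- function(xyz, branch_labels, axis_label, angle_deg) {
      if (abs(angle_deg) < 1e-12) return(xyz)
      centre <- xyz[match("C1", labels), ]
      axis_to <- xyz[match(axis_label, labels), ]
      R <- .rotation_about(axis_to - centre, angle_deg * pi / 180)
      move <- setdiff(branch_labels, axis_label)
      idx <- match(move, labels)
      xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, axis_to) %*% t(R),
                          2, axis_to, `+`)
      xyz
    }

    conformers <- lapply(seq_len(n_conformers), function(j) {
      xyz <- coords
      xyz <- rotate_branch(xyz, branch3, "C3", first[j])
      xyz <- rotate_branch(xyz, branch4, paste0("C", 3L + n3), second[j])
      conformer(paste0("c", j), labels, elements, xyz)
    })
    conformational_ensemble("toy", conformers)
  })
}

#' Generate an alignment tensor with chosen eigenstructure
#'
#' Builds a traceless symmetric Saupe matrix with principal values
#' `S_zz = axial_magnitude`, `S_xx = -(S_zz/2)(1 - 3R/2)`,
#' `S_yy = -(S_zz/2)(1 + 3R/2)` for rhombicity `R`, then applies a seeded
#' uniform random rotation. Magnitudes around 1e-4 to 1e-3 correspond to the
#' weak alignment regime of stretched-gel / liquid-crystal media.
#'
#' @param axial_magnitude principal component `S_zz`, dimensionless, absolute
#'   value in `[1e-5, 1e-2]`
#' @param rhombicity `R` in `[0, 2/3]`; 0 is axially symmetric
#' @param orientation_seed integer seed for the random orientation
#' @return an [alignment_tensor()]
#' @export
make_true_tensor <- function(axial_magnitude = 5e-4, rhombicity = 0,
                             orientation_seed = 1) {
  if (abs(axial_magnitude) < 1e-5 || abs(axial_magnitude) > 1e-2) {
    stop("axial_magnitude must have absolute value in [1e-5, 1e-2]",
         call. = FALSE)
  }
  if (rhombicity < 0 || rhombicity > 2 / 3) {
    stop("rhombicity must be in [0, 2/3]", call. = FALSE)
  }
  szz <- axial_magnitude
  sxx <- -(szz / 2) * (1 - 1.5 * rhombicity)
  syy <- -(szz / 2) * (1 + 1.5 * rhombicity)
  with_seed(orientation_seed, {
    R <- .random_rotation()
    alignment_tensor(R %*% diag(c(sxx, syy, szz)) %*% t(R))
  })
}

# bonded-neighbour lists by distance (single conformer)
.connectivity <- function(conf, cutoff = 1.6) {
  d <- as.matrix(stats::dist(conf$coords))
  diag(d) <- Inf
  apply(d < cutoff, 1L, which, simplify = FALSE)
}

#' One-bond C-H pairs of an ensemble
#'
#' Detects covalent C-H pairs by distance (< 1.2 A) in the first conformer;
#' connectivity is shared across the ensemble by construction.
#'
#' @param ensemble a [conformational_ensemble()]
#' @return data frame with columns `label_a` (carbon), `label_b` (hydrogen)
#' @export
find_ch_pairs <- function(ensemble) {
  conf <- ensemble$conformers[[1L]]
  d <- as.matrix(stats::dist(conf$coords))
  is_c <- conf$elements == "C"
  is_h <- conf$elements == "H"
  pairs <- which(outer(is_c, is_h) & d < 1.2, arr.ind = TRUE)
  data.frame(label_a = conf$atom_labels[pairs[, 1L]],
             label_b = conf$atom_labels[pairs[, 2L]],
             stringsAsFactors = FALSE)
}

# local orthonormal frame of an atom from its bonded neighbours: first axis
# along the bond to the lowest-index neighbour, second in the plane of the
# next neighbour. Makes shielding tensors ride with the local structure.
.local_frame <- function(conf, atom_idx, neighbours) {
  nb <- neighbours[[atom_idx]]
  p0 <- conf$coords[atom_idx, ]
  v1 <- conf$coords[nb[1L], ] - p0
  e1 <- v1 / sqrt(sum(v1^2))
  v2 <- if (length(nb) >= 2L) conf$coords[nb[2L], ] - p0 else {
    if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  e2 <- v2 - sum(v2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

#' Generate per-conformer nuclear shielding tensors
#'
#' Draws, per carbon, a set of principal shielding components — anisotropy
#' log-uniform in `aniso_range` (spanning aliphatic to aromatic/carbonyl
#' carbons), asymmetry uniform in `[0, 1]`, isotropic part uniform in
#' `iso_range` — and a fixed orientation relative to the atom's local bonded
#' frame. Expressed in the laboratory frame of each conformer, the tensors
#' therefore follow the structure the way DFT shieldings do. A small seeded
#' per-(atom, conformer) isotropic perturbation makes conformers
#' distinguishable by their isotropic shifts.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param seed integer seed
#' @param aniso_range shielding anisotropy range, ppm (default 30-200)
#' @param iso_range isotropic shielding range, ppm (default 20-180)
#' @param conf_iso_sd SD of the per-conformer isotropic perturbation, ppm
#'   (default 2, of the order of conformational 13C shift differences)
#' @param elements element symbols to cover (default `"C"`)
#' @return data frame with columns `conformer_id`, `label`, `s_xx` .. `s_zz`
#'   (ppm, laboratory frame, row-major)
#' @export
generate_shieldings <- function(ensemble, seed = 1,
                                aniso_range = c(30, 200),
                                iso_range = c(20, 180),
                                conf_iso_sd = 2.0,
                                elements = "C") {
  conf1 <- ensemble$conformers[[1L]]
  atom_idx <- which(conf1$elements %in% elements)
  ids <- conformer_ids(ensemble)
  with_seed(seed, {
    per_atom <- lapply(atom_idx, function(i) {
      d_aniso <- exp(stats::runif(1, log(aniso_range[1L]), log(aniso_range[2L])))
      eta <- stats::runif(1, 0, 1)
      iso <- stats::runif(1, iso_range[1L], iso_range[2L])
      pv <- c(-(d_aniso / 3) * (1 + eta),
              -(d_aniso / 3) * (1 - eta),
              2 * d_aniso / 3)
      list(pv = pv, R0 = .random_rotation(), iso = iso)
    })
    conf_shift <- matrix(stats::rnorm(length(atom_idx) * length(ids),
                                      0, conf_iso_sd),
                         length(atom_idx), length(ids))

    out <- vector("list", length(ids) * length(atom_idx))
    m <- 0L
    for (k in seq_along(ids)) {
      conf <- ensemble$conformers[[k]]
      nbs <- .connectivity(conf)
      for (a in seq_along(atom_idx)) {
        i <- atom_idx[a]
        pa <- per_atom[[a]]
        Rl <- .local_frame(conf, i, nbs) %*% pa$R0
        sig <- Rl %*% diag(pa$pv) %*% t(Rl) +
          diag(pa$iso + conf_shift[a, k], 3L)
        m <- m + 1L
        out[[m]] <- data.frame(
          conformer_id = ids[k], label = conf$atom_labels[i],
          s_xx = sig[1, 1], s_xy = sig[1, 2], s_xz = sig[1, 3],
          s_yx = sig[2, 1], s_yy = sig[2, 2], s_yz = sig[2, 3],
          s_zx = sig[3, 1], s_zy = sig[3, 2], s_zz = sig[3, 3],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a full ground-truthed dataset from an ensemble
#'
#' Back-calculates one-bond C-H RDCs for every C-H pair and RCSAs for every
#' carbon through the true alignment tensor and populations, adds seeded
#' Gaussian noise, and generates per-conformer "computed" chemical shifts
#' through a known affine map of the isotropic shieldings (with a distinct
#' affine map defining the "experimental" truth, so the shift-scaling step
#' has a real transform to recover).
#'
#' Default noise presets mirror typical small-molecule anisotropic-NMR data
#' quality: RDC 0.5 Hz, Delta-Delta-RCSA 2 ppb, 13C shifts 0.2 ppm, 1H
#' shifts 0.02 ppm.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param tensor the true [alignment_tensor()]
#' @param populations true conformer populations (named, simplex)
#' @param noise list with elements `rdc_hz`, `rcsa_ppb`, `shift_c13_ppm`,
#'   `shift_h1_ppm`; zero entries add no noise (sigmas then default to the
#'   preset values so fitting weights stay defined)
#' @param seed integer seed
#' @param shieldings optionally, a precomputed [generate_shieldings()] table
#'   (so decoy configurations can share the generation settings)
#' @param conf_iso_sd passed to [generate_shieldings()]
#' @return list with `rdc`, `rcsa`, `shieldings`, `shifts` (experimental
#'   table), `computed` (per-conformer computed shift matrix), and `truth`
#'   (tensor, populations, noise, seed, affine maps)
#' @export
simulate_dataset <- function(ensemble, tensor, populations,
                             noise = list(rdc_hz = 0.5, rcsa_ppb = 2,
                                          shift_c13_ppm = 0.2,
                                          shift_h1_ppm = 0.02),
                             seed = 1, shieldings = NULL,
                             conf_iso_sd = 2.0) {
  preset <- list(rdc_hz = 0.5, rcsa_ppb = 2, shift_c13_ppm = 0.2,
                 shift_h1_ppm = 0.02)
  for (nm in names(preset)) if (is.null(noise[[nm]])) noise[[nm]] <- preset[[nm]]
  ids <- conformer_ids(ensemble)
  w <- as.numeric(populations)[match(ids, names(populations))]
  if (anyNA(w)) stop("populations must cover the ensemble", call. = FALSE)
  w <- w / sum(w)

  if (is.null(shieldings)) {
    shieldings <- generate_shieldings(ensemble, seed = seed + 1000L,
                                      conf_iso_sd = conf_iso_sd)
  }
  pairs <- find_ch_pairs(ensemble)
  carbons <- shieldings$label[!duplicated(shieldings$label)]

  # population-averaged true observables (noise-free)
  rdc_true <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(vapply(seq_along(ids), function(k)
      w[k] * back_calc_rdc(ensemble$conformers[[k]],
                           pairs$label_a[i], pairs$label_b[i], tensor),
      numeric(1)))
  }, numeric(1))
  rcsa_true <- vapply(carbons, function(lab) {
    sum(vapply(seq_along(ids), function(k)
      w[k] * back_calc_rcsa(.shielding_matrix(shieldings, ids[k], lab), tensor),
      numeric(1)))
  }, numeric(1))

  # isotropic shieldings per (carbon/hydrogen, conformer)
  iso_c <- vapply(ids, function(id) vapply(carbons, function(lab) {
    sig <- .shielding_matrix(shieldings, id, lab)
    mean(diag(sig))
  }, numeric(1)), numeric(length(carbons)))
  iso_c <- matrix(iso_c, nrow = length(carbons),
                  dimnames = list(carbons, ids))

  conf1 <- ensemble$conformers[[1L]]
  hydrogens <- conf1$atom_labels[conf1$elements == "H"]

  with_seed(seed, {
    iso_h_base <- stats::runif(length(hydrogens), 24, 31)
    iso_h <- outer(iso_h_base, rep(1, length(ids))) +
      matrix(stats::rnorm(length(hydrogens) * length(ids), 0,
                          conf_iso_sd * 0.075),
             length(hydrogens), length(ids))
    dimnames(iso_h) <- list(hydrogens, ids)

    # shielding -> shift maps; "computed" and "true" differ so that shift
    # scaling has a genuine affine transform to recover
    map_comp <- list(C13 = c(slope = -1.00, intercept = 185),
                     H1  = c(slope = -1.00, intercept = 31.5))
    map_true <- list(C13 = c(slope = -0.96, intercept = 180),
                     H1  = c(slope = -0.97, intercept = 30.8))
    comp_c <- map_comp$C13[["slope"]] * iso_c + map_comp$C13[["intercept"]]
    comp_h <- map_comp$H1[["slope"]] * iso_h + map_comp$H1[["intercept"]]
    true_c <- map_true$C13[["slope"]] * iso_c + map_true$C13[["intercept"]]
    true_h <- map_true$H1[["slope"]] * iso_h + map_true$H1[["intercept"]]

    computed <- rbind(comp_c, comp_h)
    exp_c <- drop(true_c %*% w) +
      stats::rnorm(length(carbons), 0, noise$shift_c13_ppm)
    exp_h <- drop(true_h %*% w) +
      stats::rnorm(length(hydrogens), 0, noise$shift_h1_ppm)

    shifts <- data.frame(
      label = c(carbons, hydrogens),
      nucleus = c(rep("C13", length(carbons)), rep("H1", length(hydrogens))),
      exp_ppm = c(exp_c, exp_h),
      stringsAsFactors = FALSE)

    sigma_rdc <- if (noise$rdc_hz > 0) noise$rdc_hz else preset$rdc_hz
    sigma_rcsa <- if (noise$rcsa_ppb > 0) noise$rcsa_ppb else preset$rcsa_ppb
    rdc <- data.frame(
      label_a = pairs$label_a, label_b = pairs$label_b,
      value_hz = rdc_true +
        if (noise$rdc_hz > 0) stats::rnorm(length(rdc_true), 0, noise$rdc_hz)
        else 0,
      sigma_hz = sigma_rdc, stringsAsFactors = FALSE)
    rcsa <- data.frame(
      label = carbons,
      value_ppb = unname(rcsa_true) +
        if (noise$rcsa_ppb > 0) stats::rnorm(length(rcsa_true), 0,
                                             noise$rcsa_ppb) else 0,
      sigma_ppb = sigma_rcsa, reference = "EXTERNAL",
      stringsAsFactors = FALSE)

    list(rdc = rdc, rcsa = rcsa, shieldings = shieldings, shifts = shifts,
         computed = computed,
         truth = list(tensor = tensor,
                      populations = stats::setNames(w, ids),
                      rdc_true = stats::setNames(rdc_true,
                                                 paste0(pairs$label_a, "-",
                                                        pairs$label_b)),
                      rcsa_true = rcsa_true,
                      noise = noise, seed = seed,
                      map_comp = map_comp, map_true = map_true))
  })
}

#' Invert a stereocenter to create a decoy configuration
#'
#' Detects the four substituent branches of the stereocenter from
#' distance-based connectivity and, in every conformer, reflects the two
#' smallest branches through the plane spanned by the bonds to the two
#' largest branches. The reflection is an isometry fixing that plane, so
#' bond lengths are preserved while the center's configuration is inverted
#' (the two small branches exchange sides). Applying the operation twice
#' restores the original geometry.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param stereocenter_label atom label of the stereogenic carbon (default
#'   `"C1"`, the toy generator's stereocenter)
#' @param label suffix appended to the configuration label (default
#'   `"-decoy"`)
#' @return a [conformational_ensemble()] with identical atom labels
#' @export
make_decoy_configuration <- function(ensemble, stereocenter_label = "C1",
                                     label = "-decoy") {
  conf1 <- ensemble$conformers[[1L]]
  centre_idx <- .atom_index(conf1, stereocenter_label)
  nbs <- .connectivity(conf1)
  neigh <- nbs[[centre_idx]]
  if (length(neigh) != 4L) {
    stop("stereocenter '", stereocenter_label, "' must have exactly 4 ",
         "bonded substituents (found ", length(neigh), ")", call. = FALSE)
  }
  # branch = connected component reachable from each neighbour, centre removed
  branches <- lapply(neigh, function(start) {
    seen <- c(centre_idx, start)
    frontier <- start
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(unlist(nbs[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    setdiff(seen, centre_idx)
  })
  for (i in 1:3) for (j in (i + 1):4) {
    if (length(intersect(branches[[i]], branches[[j]])) > 0L) {
      stop("branch detection ambiguous at '", stereocenter_label,
           "': substituents ", conf1$atom_labels[neigh[i]], " and ",
           conf1$atom_labels[neigh[j]], " are connected through a ring",
           call. = FALSE)
    }
  }
  sizes <- lengths(branches)
  ord <- order(-sizes, conf1$atom_labels[neigh])
  anchor <- neigh[ord[1:2]]            # bonds spanning the mirror plane
  move_atoms <- unlist(branches[ord[3:4]])

  conformers <- lapply(ensemble$conformers, function(conf) {
    xyz <- conf$coords
    c0 <- xyz[centre_idx, ]
    u1 <- xyz[anchor[1L], ] - c0; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- xyz[anchor[2L], ] - c0; u2 <- u2 / sqrt(sum(u2^2))
    nrm <- c(u1[2] * u2[3] - u1[3] * u2[2],
             u1[3] * u2[1] - u1[1] * u2[3],
             u1[1] * u2[2] - u1[2] * u2[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-6) {
      stop("branch geometry degenerate at '", stereocenter_label,
           "' in conformer '", conf$conformer_id, "': anchor bonds ",
           conf1$atom_labels[anchor[1L]], " and ",
           conf1$atom_labels[anchor[2L]], " are collinear", call. = FALSE)
    }
    nrm <- nrm / nn
    rel <- sweep(xyz[move_atoms, , drop = FALSE], 2, c0)
    xyz[move_atoms, ] <- sweep(rel - 2 * (rel %*% nrm) %*% t(nrm), 2, c0, `+`)
    conformer(conf$conformer_id, conf$atom_labels, conf$elements, xyz)
  })
  conformational_ensemble(paste0(ensemble$configuration_label, label),
                          conformers, ensemble$populations)
}

#' Perturb computed shifts to emulate a wrong-configuration prediction
#'
#' Computed chemical shifts of a wrong diastereomer differ from the true
#' configuration's by systematic per-atom offsets (the stereocenter
#' inversion changes each nucleus's environment by a fixed amount, shared
#' across conformers). This adds seeded per-atom Gaussian offsets to a
#' computed-shift matrix -- around 0.5 ppm for 13C and 0.05 ppm for 1H by
#' default, typical of diastereomeric shift differences.
#'
#' @param computed per-conformer computed shift matrix (rows aligned with
#'   `shifts`)
#' @param shifts shift table (`label`, `nucleus`, `exp_ppm`) identifying the
#'   nucleus class of each row
#' @param c13_sd,h1_sd per-atom offset SD in ppm
#' @param seed integer seed
#' @return the perturbed matrix
#' @export
perturb_computed_shifts <- function(computed, shifts, c13_sd = 0.5,
                                    h1_sd = 0.05, seed = 1) {
  stopifnot(nrow(computed) == nrow(shifts))
  with_seed(seed, {
    off <- stats::rnorm(nrow(shifts), 0,
                        ifelse(shifts$nucleus == "H1", h1_sd, c13_sd))
    computed + off
  })
}

#' Synthetic conformer energies realizing requested populations
#'
#' Inverts the Boltzmann relation: `E_i = -kT log(p_i)` (in Hartree, plus an
#' arbitrary offset), so that [boltzmann_weights()] applied to the output
#' reproduces `populations` exactly. Useful for exercising energy-based
#' selection without quantum chemistry.
#'
#' @param populations named weights on the simplex
#' @param temperature K (default 298.15)
#' @param kind energy kind tag for the output records
#' @param offset_hartree constant added to all energies (default -500, a
#'   typical mid-size-molecule electronic energy scale)
#' @return data frame with columns `conformer_id`, `kind`, `hartree`
#' @export
energies_for_populations <- function(populations, temperature = 298.15,
                                     kind = "G_THERMAL",
                                     offset_hartree = -500) {
  p <- as.numeric(populations)
  if (is.null(names(populations)) || any(p <= 0)) {
    stop("populations must be named and strictly positive", call. = FALSE)
  }
  kT <- aniso_constants$kB * temperature / aniso_constants$hartree_J
  data.frame(conformer_id = names(populations), kind = kind,
             hartree = offset_hartree - kT * log(p / max(p)),
             stringsAsFactors = FALSE)
}
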