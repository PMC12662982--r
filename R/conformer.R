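# Conformers and conformational ensembles: labelled Cartesian geometries
# sharing one atom-label scheme, with optional populations.

.valid_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Br", "I", "Se", "Fe", "Zn"
)

#' Construct a conformer
#'
#' A conformer is one Cartesian geometry of the molecule: a set of atoms
#' identified by NMR-style labels (`"C2"`, `"H3a"`, `"S-CH3"`), their element
#' symbols and their coordinates in Angstrom.
#'
#' @param conformer_id character scalar identifying this conformer
#' @param atom_labels character vector of unique atom labels
#' @param elements character vector of element symbols, same length
#' @param coords numeric matrix, n_atoms x 3, Angstrom
#' @return an object of class `"conformer"`
#' @export
conformer <- function(conformer_id, atom_labels, elements, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(atom_labels)
  if (length(elements) != n || nrow(coords) != n || ncol(coords) != 3L) {
    stop("atom_labels, elements and coords must describe the same ", n,
         " atoms (coords must be n x 3)", call. = FALSE)
  }
  if (anyDuplicated(atom_labels)) {
    stop("duplicate atom labels in conformer '", conformer_id, "': ",
         paste(unique(atom_labels[duplicated(atom_labels)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(elements), .valid_elements)
  if (length(bad) > 0L) {
    stop("non-element symbol(s) in conformer '", conformer_id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("non-finite coordinates in conformer '", conformer_id, "'",
         call. = FALSE)
  }
  rownames(coords) <- atom_labels
  structure(
    list(conformer_id = as.character(conformer_id),
         atom_labels = as.character(atom_labels),
         elements = as.character(elements),
         coords = coords),
    class = "conformer"
  )
}

#' Construct a conformational ensemble
#'
#' All conformers of an ensemble must share identical atom labels in identical
#' order: the labels are the join key against shielding tensors and
#' experimental tables. Populations, when given, must be non-negative and sum
#' to one.
#'
#' @param configuration_label character scalar, e.g. `"2R,2'R"`
#' @param conformers list of [conformer()] objects
#' @param populations optional numeric vector of conformer weights (named by
#'   conformer id or in conformer order)
#' @return an object of class `"conformational_ensemble"`
#' @export
conformational_ensemble <- function(configuration_label, conformers,
                                    populations = NULL) {
  if (length(conformers) < 1L) {
    stop("an ensemble needs at least one conformer", call. = FALSE)
  }
  if (!all(vapply(conformers, inherits, logical(1), "conformer"))) {
    stop("conformers must be a list of conformer objects", call. = FALSE)
  }
  ids <- vapply(conformers, `[[`, character(1), "conformer_id")
  if (anyDuplicated(ids)) {
    stop("duplicate conformer ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ref_labels <- conformers[[1L]]$atom_labels
  for (k in seq_along(conformers)) {
    if (!identical(conformers[[k]]$atom_labels, ref_labels)) {
      stop("conformer '", ids[k], "' does not share the ensemble atom ",
           "labelling (same labels, same order, required)", call. = FALSE)
    }
  }
  if (!is.null(populations)) {
    populations <- .align_populations(populations, ids)
  }
  names(conformers) <- ids
  structure(
    list(configuration_label = as.character(configuration_label),
         conformers = conformers,
         populations = populations),
    class = "conformational_ensemble"
  )
}

# order/validate a population vector against conformer ids
.align_populations <- function(populations, ids) {
  p <- as.numeric(populations)
  if (!is.null(names(populations))) {
    missing <- setdiff(ids, names(populations))
    if (length(missing) > 0L) {
      stop("populations missing for conformer(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    p <- as.numeric(populations[ids])
  } else if (length(p) != length(ids)) {
    stop("unnamed populations must match the number of conformers",
         call. = FALSE)
  }
  if (any(p < 0)) stop("populations must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("populations must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  names(p) <- ids
  p
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> id:", x$conformer_id, "|", length(x$atom_labels),
      "atoms\n")
  invisible(x)
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat("<conformational_ensemble> '", x$configuration_label, "': ",
      length(x$conformers), " conformer(s), ",
      length(x$conformers[[1L]]$atom_labels), " atoms\n", sep = "")
  if (!is.null(x$populations)) {
    cat("  populations:",
        paste(sprintf("%s=%.3f", names(x$populations), x$populations),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ensemble a [conformational_ensemble()]
#' @return integer count
#' @export
n_conformers <- function(ensemble) length(ensemble$conformers)

#' Atom labels of an ensemble
#' @param ensemble a [conformational_ensemble()]
#' @return character vector of labels shared by every conformer
#' @export
ensemble_labels <- function(ensemble) ensemble$conformers[[1L]]$atom_labels

#' Elements of an ensemble's atoms
#' @param ensemble a [conformational_ensemble()]
#' @return character vector of element symbols
#' @export
ensemble_elements <- function(ensemble) ensemble$conformers[[1L]]$elements

#' Conformer ids of an ensemble
#' @param ensemble a [conformational_ensemble()]
#' @return character vector
#' @export
conformer_ids <- function(ensemble) {
  unname(vapply(ensemble$conformers, `[[`, character(1), "conformer_id"))
}

# resolve atom labels in a conformer, with a clear error
.atom_index <- function(conf, labels) {
  idx <- match(labels, conf$atom_labels)
  if (anyNA(idx)) {
    stop("atom label(s) not found in conformer '", conf$conformer_id, "': ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}
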