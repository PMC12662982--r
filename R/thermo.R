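# Boltzmann populations from conformer energies, and population-cutoff
# ensemble selection.

#' Boltzmann populations from conformer energies
#'
#' `w_i` is proportional to `exp(-(E_i - E_min) / (kB T))` with energies in
#' Hartree. Shifting all energies by a constant leaves the weights unchanged;
#' as `T -> Inf` weights become uniform, as `T -> 0+` the minimum-energy
#' conformer takes all the weight.
#'
#' @param energies data frame with columns `conformer_id`, `kind`, `hartree`
#'   (as returned by [read_table()] with schema `"energy"`), or a named
#'   numeric vector of energies in Hartree
#' @param kind which energy to use when `energies` is a data frame: one of
#'   `"E_ZPE"` (electronic + zero-point), `"G_THERMAL"` (Gibbs free energy),
#'   `"E_ELEC"` (electronic only)
#' @param temperature absolute temperature in K; default 298.15 K (the
#'   thermochemistry convention). 300 K, a typical NMR measurement
#'   temperature, is another common choice.
#' @return an object of class `"population_set"`: a named numeric vector of
#'   weights summing to 1, with attributes `temperature` and `source`
#' @export
boltzmann_weights <- function(energies, kind = "G_THERMAL",
                              temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (is.data.frame(energies)) {
    kind <- match.arg(kind, c("E_ZPE", "G_THERMAL", "E_ELEC"))
    sub <- energies[energies$kind == kind, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no energy records of kind '", kind, "'", call. = FALSE)
    }
    if (anyDuplicated(sub$conformer_id)) {
      stop("duplicate energy records of kind '", kind, "' for conformer(s): ",
           paste(unique(sub$conformer_id[duplicated(sub$conformer_id)]),
                 collapse = ", "), call. = FALSE)
    }
    e <- stats::setNames(sub$hartree, sub$conformer_id)
  } else {
    e <- energies
    if (is.null(names(e))) stop("energies must be named by conformer id",
                                call. = FALSE)
    if (!is.data.frame(energies)) kind <- if (missing(kind)) "E_ELEC" else kind
  }
  if (!all(is.finite(e))) stop("non-finite energies", call. = FALSE)
  kT_hartree <- aniso_constants$kB * temperature / aniso_constants$hartree_J
  x <- exp(-(e - min(e)) / kT_hartree)
  w <- x / sum(x)
  population_set(w, temperature = temperature, source = kind)
}

#' Construct a population set
#'
#' @param weights named non-negative numeric vector summing to 1 (within
#'   1e-9; renormalized exactly)
#' @param temperature temperature in K, or `NA` for fitted/uniform weights
#' @param source provenance tag: `"E_ZPE"`, `"G_THERMAL"`, `"E_ELEC"`,
#'   `"UNIFORM"` or `"FITTED"`
#' @return a `"population_set"` object
#' @export
population_set <- function(weights, temperature = NA_real_,
                           source = "UNIFORM") {
  if (is.null(names(weights))) {
    stop("population weights must be named by conformer id", call. = FALSE)
  }
  w <- as.numeric(weights)
  if (any(w < 0)) stop("populations must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("populations must sum to 1 (got ", format(sum(w), digits = 12), ")",
         call. = FALSE)
  }
  w <- w / sum(w)
  names(w) <- names(weights)
  structure(w, temperature = temperature, source = source,
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat("<population_set> source:", attr(x, "source"),
      if (!is.na(attr(x, "temperature")))
        paste0("T=", attr(x, "temperature"), " K"), "\n")
  print(stats::setNames(round(as.numeric(x), 4), names(x)))
  invisible(x)
}

#' Select conformers by a population cutoff
#'
#' Keeps conformers whose weight is greater than or equal to `cutoff`
#' (inclusive: a conformer at exactly 5% survives a 5% cutoff), renormalizes
#' the survivors, and records the discarded probability mass. This is the
#' usual "Boltzmann population of 5% or higher" ensemble-pruning rule.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param populations a [population_set()] (or named weights) covering every
#'   conformer of the ensemble
#' @param cutoff population fraction in `[0, 1)`; default 0.05
#' @return list with `ensemble` (the pruned [conformational_ensemble()] with
#'   renormalized populations attached), `populations` (the renormalized
#'   [population_set()]), `kept` and `dropped` conformer ids, and
#'   `discarded_mass`
#' @export
select_by_population <- function(ensemble, populations, cutoff = 0.05) {
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)", call. = FALSE)
  ids <- conformer_ids(ensemble)
  missing <- setdiff(ids, names(populations))
  if (length(missing) > 0L) {
    stop("populations missing for conformer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- as.numeric(populations)[match(ids, names(populations))]
  names(w) <- ids
  keep <- w >= cutoff
  if (!any(keep)) {
    stop("no conformer reaches the ", format(100 * cutoff),
         "% population cutoff; cannot empty an ensemble", call. = FALSE)
  }
  w_kept <- w[keep] / sum(w[keep])
  sub <- conformational_ensemble(
    ensemble$configuration_label,
    ensemble$conformers[keep],
    w_kept
  )
  list(
    ensemble = sub,
    populations = population_set(w_kept,
                                 temperature = attr(populations, "temperature"),
                                 source = attr(populations, "source") %||% "UNIFORM"),
    kept = ids[keep],
    dropped = ids[!keep],
    discarded_mass = sum(w[!keep])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
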