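# Orchestration of the full study workflow from one config: ensembles ->
# Boltzmann populations -> population cutoff -> RDC/RCSA/combined tensor
# fits per reference scheme -> optional CASE-3D selection with subsequent
# anisotropic fits of the selected ensembles -> one consolidated report.

.default_options <- list(
  temperature = 298.15,
  cutoff = 0.05,
  energy_kind = "G_THERMAL",
  references = "EXTERNAL",
  weighting = "sigma",
  r_scale = 1.0,
  case3d = FALSE,
  max_subset_size = 4,
  h_weight = 5.0,
  scaling = "iterative",
  seed = 1
)

#' Resolve a run configuration
#'
#' Accepts a YAML/JSON file path or an R list with elements
#' `configurations` (named list of per-configuration file paths: `geometry`,
#' `shieldings`, optionally `energies` and `shifts`), `experimental`
#' (`rdc`, `rcsa` file paths), and `options`. Every option is filled with
#' its recorded default so the resolved configuration embedded in the
#' report is fully explicit; referenced files are checked for existence.
#'
#' @param config path or list
#' @return the resolved config list (class `"run_config"`)
#' @export
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$configurations) || length(config$configurations) < 1L) {
    stop("config must name at least one configuration", call. = FALSE)
  }
  opts <- utils::modifyList(.default_options, config$options %||% list())
  config$options <- opts
  for (label in names(config$configurations)) {
    cfg <- config$configurations[[label]]
    for (field in intersect(names(cfg),
                            c("geometry", "shieldings", "energies", "shifts"))) {
      if (is.character(cfg[[field]]) && !file.exists(cfg[[field]])) {
        stop("configuration '", label, "': file not found: ", cfg[[field]],
             call. = FALSE)
      }
    }
  }
  for (field in intersect(names(config$experimental %||% list()),
                          c("rdc", "rcsa"))) {
    f <- config$experimental[[field]]
    if (is.character(f) && !file.exists(f)) {
      stop("experimental ", field, " file not found: ", f, call. = FALSE)
    }
  }
  class(config) <- "run_config"
  config
}

# load one configuration's inputs (paths or already-typed objects)
.load_configuration <- function(label, cfg) {
  ensemble <- if (inherits(cfg$geometry, "conformational_ensemble")) {
    cfg$geometry
  } else {
    read_xyz_ensemble(cfg$geometry, configuration_label = label)
  }
  shieldings <- if (is.character(cfg$shieldings)) {
    read_table(cfg$shieldings, "shielding")
  } else cfg$shieldings
  energies <- if (is.character(cfg$energies)) {
    read_table(cfg$energies, "energy")
  } else cfg$energies
  shifts <- if (is.character(cfg$shifts)) {
    read_table(cfg$shifts, "shift")
  } else cfg$shifts
  list(ensemble = ensemble, shieldings = shieldings, energies = energies,
       shifts = shifts)
}

#' Run the full discrimination workflow
#'
#' For every candidate configuration: computes Boltzmann populations (for
#' each energy kind present), applies the population cutoff, fits the
#' alignment tensor against the RDC, Delta-Delta-RCSA (one fit per reference
#' scheme) and combined data blocks, and — when requested and chemical
#' shifts are provided — runs the CASE-3D subset selection and refits the
#' selected ensembles against the anisotropic data. Stage failures are
#' recorded per configuration; the pipeline continues for the rest.
#'
#' @param config a path to a YAML/JSON run configuration, or the equivalent
#'   list (see [resolve_config()]); per-configuration entries may hold
#'   in-memory objects instead of file paths
#' @return an object of class `"pipeline_report"`: resolved config,
#'   per-configuration population sets and selections, the
#'   [discriminate()] report, and (optionally) the [case3d_select()] report
#'   plus anisotropic fits of the CASE-3D-selected ensembles
#' @export
run_discrimination <- function(config) {
  config <- resolve_config(config)
  opts <- config$options

  rdc <- config$experimental$rdc
  if (is.character(rdc)) rdc <- read_table(rdc, "rdc")
  rcsa <- config$experimental$rcsa
  if (is.character(rcsa)) rcsa <- read_table(rcsa, "rcsa")

  boltzmann <- list()
  fit_inputs <- list()
  case3d_inputs <- list()
  stage_errors <- list()

  for (label in names(config$configurations)) {
    loaded <- tryCatch(.load_configuration(label,
                                           config$configurations[[label]]),
                       error = function(e) e)
    if (inherits(loaded, "error")) {
      stage_errors[[label]] <- conditionMessage(loaded)
      next
    }
    ens <- loaded$ensemble
    if (!is.null(loaded$energies)) {
      kinds <- intersect(c("E_ZPE", "G_THERMAL", "E_ELEC"),
                         unique(loaded$energies$kind))
      pops <- lapply(stats::setNames(nm = kinds), function(kd)
        boltzmann_weights(loaded$energies, kind = kd,
                          temperature = opts$temperature))
      sel_kind <- if (opts$energy_kind %in% kinds) opts$energy_kind else kinds[1L]
      sel <- select_by_population(ens, pops[[sel_kind]],
                                  cutoff = opts$cutoff)
      boltzmann[[label]] <- list(populations = pops, selection_kind = sel_kind,
                                 kept = sel$kept, dropped = sel$dropped,
                                 discarded_mass = sel$discarded_mass)
      ens_fit <- sel$ensemble
      pops_fit <- sel$populations
    } else {
      ids <- conformer_ids(ens)
      pops_fit <- population_set(
        stats::setNames(rep(1 / length(ids), length(ids)), ids),
        source = "UNIFORM")
      ens_fit <- ens
      boltzmann[[label]] <- list(populations = list(UNIFORM = pops_fit),
                                 selection_kind = "UNIFORM",
                                 kept = ids, dropped = character(0),
                                 discarded_mass = 0)
    }
    fit_inputs[[label]] <- list(ensemble = ens_fit, populations = pops_fit,
                                shieldings = loaded$shieldings)
    if (!is.null(loaded$shifts)) {
      case3d_inputs[[label]] <- list(
        ensemble = ens,
        shifts = loaded$shifts[, c("label", "nucleus", "exp_ppm")],
        computed = shift_computed_matrix(loaded$shifts),
        shieldings = loaded$shieldings)
    }
  }

  if (length(fit_inputs) == 0L) {
    stop("every configuration failed to load: ",
         paste(unlist(stage_errors), collapse = " | "), call. = FALSE)
  }

  report <- discriminate(fit_inputs, rdc = rdc, rcsa = rcsa,
                         references = opts$references,
                         weighting = opts$weighting)

  case3d <- NULL
  case3d_fits <- NULL
  if (isTRUE(opts$case3d) && length(case3d_inputs) == length(fit_inputs)) {
    case3d <- case3d_select(case3d_inputs,
                            max_subset_size = opts$max_subset_size,
                            h_weight = opts$h_weight,
                            scaling = opts$scaling)
    selected_inputs <- lapply(stats::setNames(nm = names(case3d$selected)),
                              function(label) {
      list(ensemble = case3d$selected[[label]]$ensemble,
           populations = case3d$selected[[label]]$populations,
           shieldings = case3d_inputs[[label]]$shieldings)
    })
    case3d_fits <- discriminate(selected_inputs, rdc = rdc, rcsa = rcsa,
                                references = opts$references,
                                weighting = opts$weighting)
  }

  structure(
    list(config = config,
         boltzmann = boltzmann,
         discrimination = report,
         case3d = case3d,
         case3d_fits = case3d_fits,
         stage_errors = stage_errors,
         best = report$best,
         versions = list(anisofit = as.character(
           utils::packageVersion("anisofit")), r = R.version.string),
         seed = opts$seed),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (label in names(x$boltzmann)) {
    b <- x$boltzmann[[label]]
    cat("  ", label, ": ", length(b$kept), " conformer(s) kept (",
        b$selection_kind, " populations, ",
        sprintf("%.1f%%", 100 * b$discarded_mass), " mass discarded)\n",
        sep = "")
  }
  if (length(x$stage_errors) > 0L) {
    for (label in names(x$stage_errors)) {
      cat("  ", label, ": FAILED - ", x$stage_errors[[label]], "\n", sep = "")
    }
  }
  print(x$discrimination)
  if (!is.null(x$case3d)) {
    print(x$case3d)
    cat("anisotropic fits of CASE-3D-selected ensembles:\n")
    print(x$case3d_fits)
  }
  invisible(x)
}
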