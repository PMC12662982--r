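# Readers and writers for the on-disk artifacts: multi-record XYZ
# geometries, CSV data tables (fixed schemas, canonical units), and JSON
# discrimination reports. Everything downstream consumes validated, typed
# records only.

.table_schemas <- list(
  rdc       = c("label_a", "label_b", "value_hz", "sigma_hz"),
  rcsa      = c("label", "value_ppb", "sigma_ppb", "reference"),
  shielding = c("conformer_id", "label", "s_xx", "s_xy", "s_xz",
                "s_yx", "s_yy", "s_yz", "s_zx", "s_zy", "s_zz"),
  energy    = c("conformer_id", "kind", "hartree"),
  shift     = c("label", "nucleus", "exp_ppm")
)

#' Read a multi-record XYZ file as a conformational ensemble
#'
#' Standard multi-record XYZ: each record is an atom count line, a comment
#' line (an optional `id=<conformer_id>` token names the conformer;
#' otherwise ids default to 1-based file order), then one `element x y z`
#' line per atom, optionally with the NMR-style atom label as a fifth
#' column. Labels may instead be supplied through `labels` (one per atom,
#' shared by all records); with neither, `element + index` fallback labels
#' are generated. All records must agree in atom count and ordering.
#'
#' @param path file path
#' @param configuration_label label for the resulting ensemble
#' @param labels optional character vector of atom labels (sidecar label map)
#' @return a [conformational_ensemble()]
#' @export
read_xyz_ensemble <- function(path, configuration_label = basename(path),
                              labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  conformers <- list()
  i <- 1L; rec <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    rec <- rec + 1L
    if (is.na(n) || n < 1L) {
      stop("XYZ format error in record ", rec, " of '", path,
           "': expected an atom count, got '", trimws(lines[i]), "'",
           call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("XYZ format error: record ", rec, " of '", path, "' is truncated",
           call. = FALSE)
    }
    comment <- lines[i + 1L]
    id <- regmatches(comment, regexpr("id=\\S+", comment))
    id <- if (length(id) == 1L) sub("^id=", "", id) else as.character(rec)
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 4L)) {
      stop("XYZ format error in record ", rec, " ('", id,
           "'): atom lines need 'element x y z [label]'", call. = FALSE)
    }
    elements <- vapply(toks, `[[`, character(1), 1L)
    coords <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(v)) stop("XYZ format error in record ", rec,
                         ": non-numeric coordinate", call. = FALSE)
      v
    }, numeric(3)))
    rec_labels <- if (all(nf >= 5L)) {
      vapply(toks, `[[`, character(1), 5L)
    } else if (!is.null(labels)) {
      if (length(labels) != n) {
        stop("label map length (", length(labels),
             ") does not match atom count (", n, ")", call. = FALSE)
      }
      labels
    } else {
      paste0(elements, seq_len(n))
    }
    conformers[[length(conformers) + 1L]] <-
      conformer(id, rec_labels, elements, coords)
    i <- i + 2L + n
  }
  if (length(conformers) == 0L) {
    stop("no XYZ records found in '", path, "'", call. = FALSE)
  }
  tryCatch(
    conformational_ensemble(configuration_label, conformers),
    error = function(e) {
      stop("XYZ records in '", path, "' are inconsistent: ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

#' Write a conformational ensemble as multi-record XYZ
#'
#' Inverse of [read_xyz_ensemble()]: atom labels are written as a fifth
#' column and conformer ids in the comment line, so the file round-trips.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param path output file path
#' @param digits coordinate decimals (default 10, ample for 1e-9 round-trip)
#' @export
write_xyz_ensemble <- function(ensemble, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  for (conf in ensemble$conformers) {
    writeLines(as.character(length(conf$atom_labels)), con)
    writeLines(paste0("id=", conf$conformer_id), con)
    writeLines(sprintf(paste0("%-2s %.", digits, "f %.", digits, "f %.",
                              digits, "f %s"),
                       conf$elements, conf$coords[, 1L], conf$coords[, 2L],
                       conf$coords[, 3L], conf$atom_labels), con)
  }
  invisible(path)
}

#' Read a typed CSV data table
#'
#' Fixed, documented header per schema (canonical units): `rdc`
#' (`label_a,label_b,value_hz,sigma_hz`), `rcsa`
#' (`label,value_ppb,sigma_ppb,reference`), `shielding`
#' (`conformer_id,label,s_xx,...,s_zz` in ppm), `energy`
#' (`conformer_id,kind,hartree`), `shift`
#' (`label,nucleus,exp_ppm` plus one computed-ppm column per conformer id).
#' Sigmas must be strictly positive; duplicate keys are rejected; an empty
#' data section yields an empty table with a warning.
#'
#' @param path CSV file path
#' @param schema one of `"rdc"`, `"rcsa"`, `"shielding"`, `"energy"`,
#'   `"shift"`
#' @return a validated data frame (for `"shift"`, computed columns included;
#'   see [shift_computed_matrix()])
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(.table_schemas))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- .table_schemas[[schema]]
  if (schema == "rcsa") required <- setdiff(required, "reference")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("'", path, "' (schema ", schema, "): missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("'", path, "': empty ", schema, " table", call. = FALSE)
    return(df)
  }
  key <- switch(schema,
                rdc = paste(df$label_a, df$label_b),
                rcsa = df$label,
                shielding = paste(df$conformer_id, df$label),
                energy = paste(df$conformer_id, df$kind),
                shift = paste(df$label, df$nucleus))
  if (anyDuplicated(key)) {
    stop("'", path, "': duplicate ", schema, " record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  sigma_col <- switch(schema, rdc = "sigma_hz", rcsa = "sigma_ppb", NULL)
  if (!is.null(sigma_col) && any(df[[sigma_col]] <= 0 | !is.finite(df[[sigma_col]]))) {
    stop("'", path, "': ", sigma_col, " must be strictly positive",
         call. = FALSE)
  }
  if (schema == "rcsa" && is.null(df$reference)) df$reference <- "EXTERNAL"
  if (schema == "rdc" && any(df$label_a == df$label_b)) {
    stop("'", path, "': a dipolar pair needs two distinct atoms",
         call. = FALSE)
  }
  if (schema == "energy") {
    bad <- setdiff(unique(df$kind), c("E_ZPE", "G_THERMAL", "E_ELEC"))
    if (length(bad) > 0L) {
      stop("'", path, "': unknown energy kind(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (schema == "shift") {
    bad <- setdiff(unique(df$nucleus), c("H1", "C13"))
    if (length(bad) > 0L) {
      stop("'", path, "': unknown nucleus class(es) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  num_cols <- setdiff(names(df), c("label_a", "label_b", "label",
                                   "conformer_id", "kind", "reference",
                                   "nucleus"))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]]) || !all(is.finite(df[[cl]]))) {
      stop("'", path, "': column '", cl, "' must be finite numeric",
           call. = FALSE)
    }
  }
  df
}

#' Write a typed CSV data table
#'
#' @param df data frame as produced/consumed by [read_table()]
#' @param path output path
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Computed-shift matrix of a shift table
#'
#' Extracts the per-conformer computed columns of a `shift` table into the
#' matrix form the CASE-3D functions consume (rows aligned with the table).
#'
#' @param df shift table from [read_table()]
#' @return numeric matrix, one column per conformer id
#' @export
shift_computed_matrix <- function(df) {
  cols <- setdiff(names(df), .table_schemas$shift)
  if (length(cols) == 0L) {
    stop("shift table has no per-conformer computed columns", call. = FALSE)
  }
  as.matrix(df[, cols, drop = FALSE])
}

# ---- report serialization ---------------------------------------------------

.tensor_to_list <- function(tensor) {
  ev <- tensor_eigen(tensor)
  list(svec = as.numeric(attr(tensor, "svec")),
       matrix = lapply(1:3, function(i) as.numeric(unclass(tensor)[i, 1:3])),
       eigenvalues = as.numeric(ev$values),
       eigenvectors = lapply(1:3, function(i) as.numeric(ev$vectors[i, ])))
}

.tensor_from_list <- function(x) {
  alignment_tensor(as.numeric(x$svec))
}

.fit_to_list <- function(fit, block) {
  if (is.null(fit$tensor)) {
    stop("integrity error: fitted block '", block, "' lacks a tensor",
         call. = FALSE)
  }
  list(block = block,
       tensor = .tensor_to_list(fit$tensor),
       q_rdc = fit$q_rdc, q_rcsa = fit$q_rcsa, q_combined = fit$q_combined,
       n_data = as.list(fit$n_data),
       condition_number = fit$condition_number,
       singular_values = as.numeric(fit$singular_values),
       rank_deficient = fit$rank_deficient,
       weighting = fit$weighting,
       data = as.list(fit$data))
}

.fit_from_list <- function(x) {
  structure(
    list(tensor = .tensor_from_list(x$tensor),
         data = as.data.frame(lapply(x$data, unlist),
                              stringsAsFactors = FALSE),
         q_rdc = x$q_rdc %||% NA_real_, q_rcsa = x$q_rcsa %||% NA_real_,
         q_combined = x$q_combined,
         n_data = c(rdc = x$n_data$rdc, rcsa = x$n_data$rcsa),
         condition_number = x$condition_number,
         singular_values = as.numeric(x$singular_values),
         rank_deficient = isTRUE(x$rank_deficient),
         weighting = x$weighting),
    class = "aniso_fit")
}

#' Write a discrimination report to JSON
#'
#' Machine-readable report: per configuration, per data block, the fitted
#' tensor (5 independent components plus eigen-decomposition), Q factors,
#' per-datum values, populations, and the verdict. Numbers are written at
#' full precision so the report round-trips losslessly through
#' [read_report()]. A fitted block lacking its tensor is an integrity error.
#'
#' @param report a `"discrimination_report"` from [discriminate()]
#' @param path output path (`.json`)
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "discrimination_report")) {
    stop("write_report expects a discrimination_report", call. = FALSE)
  }
  configs <- lapply(names(report$configurations), function(label) {
    res <- report$configurations[[label]]
    list(configuration = label,
         populations = as.list(stats::setNames(as.numeric(res$populations),
                                               names(res$populations))),
         error = res$error,
         fits = lapply(names(res$fits), function(block)
           .fit_to_list(res$fits[[block]], block)))
  })
  obj <- list(
    type = "discrimination_report",
    configurations = configs,
    verdict = as.list(report$verdict),
    best = report$best, tie = report$tie,
    primary_block = report$primary_block,
    references = as.list(report$references),
    weighting = report$weighting,
    tie_tolerance = report$tie_tolerance,
    n_data = as.list(report$n_data)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a discrimination report written by [write_report()]
#'
#' @param path JSON path
#' @return a `"discrimination_report"` object
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$type, "discrimination_report")) {
    stop("'", path, "' is not a discrimination report", call. = FALSE)
  }
  configurations <- list()
  for (cfg in x$configurations) {
    fits <- list()
    for (f in cfg$fits) fits[[f$block]] <- .fit_from_list(f)
    configurations[[cfg$configuration]] <- list(
      fits = fits,
      error = cfg$error,
      populations = stats::setNames(as.numeric(unlist(cfg$populations)),
                                    names(cfg$populations)))
  }
  verdict <- as.data.frame(lapply(x$verdict, unlist),
                           stringsAsFactors = FALSE)
  structure(
    list(configurations = configurations, verdict = verdict,
         best = x$best, tie = x$tie, primary_block = x$primary_block,
         references = as.character(unlist(x$references)),
         weighting = x$weighting, tie_tolerance = x$tie_tolerance,
         n_data = c(rdc = x$n_data$rdc, rcsa = x$n_data$rcsa)),
    class = "discrimination_report")
}
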