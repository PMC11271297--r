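# Reading and writing model configurations. The canonical document (YAML or
# JSON, chosen by extension) carries settings, epidemiology, parameter values
# and distribution specs; long blocks may be outsourced to CSV files referenced
# by relative path (`values_csv`, `dists_csv`).

#' Write a parameter set to a configuration file
#'
#' Serialises a `parameter_set` to YAML (`.yaml`/`.yml`) or JSON (`.json`).
#' The written document round-trips through [load_parameter_set()].
#'
#' @param ps a validated `parameter_set`
#' @param path output file path; the extension selects the format
#' @return `path`, invisibly
#' @export
write_parameter_set <- function(ps, path) {
  validate_parameter_set(ps)
  doc <- list(
    settings = ps$settings,
    epi = ps$epi,
    values = as.list(ps$values),
    dists = lapply(seq_len(nrow(ps$dists)), function(i) {
      row <- as.list(ps$dists[i, ])
      row[!vapply(row, function(x) is.na(x) || (is.character(x) && !nzchar(x)),
                  logical(1))]
    })
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("write_parameter_set: unsupported extension '", ext, "'")
  }
  invisible(path)
}

#' Load a parameter set from a configuration file
#'
#' Reads a YAML or JSON model definition (see [write_parameter_set()] for the
#' schema). The document may reference CSV tables by relative path:
#' `values_csv` (columns `name`, `value`) is merged into the value vector and
#' `dists_csv` (columns `name`, `mean`, `family`, and `se` or
#' `ci_low`/`ci_high`) into the distribution table. The result is validated;
#' validation failures name the offending key.
#'
#' @param path configuration file path
#' @return a validated `parameter_set`
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("load_parameter_set: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("load_parameter_set: unsupported extension '", ext, "'")
  }
  base <- dirname(path)

  values <- vapply(doc[["values"]], as.numeric, numeric(1))
  if (!is.null(doc[["values_csv"]])) {
    tab <- utils::read.csv(file.path(base, doc[["values_csv"]]))
    extra <- stats::setNames(as.numeric(tab$value), tab$name)
    values <- c(values[setdiff(names(values), names(extra))], extra)
  }
  if (is.null(doc[["values"]]) && is.null(doc[["values_csv"]]))
    stop("parameter values required (values or values_csv)")

  dist_rows <- lapply(doc[["dists"]], function(row) {
    data.frame(
      name = row$name,
      mean = as.numeric(if (is.null(row$mean)) values[[row$name]] else row$mean),
      family = if (is.null(row$family)) "FIXED" else row$family,
      se = as.numeric(if (is.null(row$se)) NA else row$se),
      ci_low = as.numeric(if (is.null(row$ci_low)) NA else row$ci_low),
      ci_high = as.numeric(if (is.null(row$ci_high)) NA else row$ci_high),
      label = if (is.null(row$label)) row$name else row$label,
      stringsAsFactors = FALSE
    )
  })
  dists <- if (length(dist_rows)) do.call(rbind, dist_rows) else NULL
  if (!is.null(doc[["dists_csv"]])) {
    tab <- utils::read.csv(file.path(base, doc[["dists_csv"]]))
    for (col in c("se", "ci_low", "ci_high"))
      if (is.null(tab[[col]])) tab[[col]] <- NA_real_
    if (is.null(tab$label)) tab$label <- tab$name
    tab <- tab[, c("name", "mean", "family", "se", "ci_low", "ci_high", "label")]
    dists <- rbind(dists[!dists$name %in% tab$name, ], tab)
  }
  if (is.null(dists)) stop("distribution table required (dists or dists_csv)")

  settings <- doc[["settings"]]
  if (is.null(settings)) stop("settings block required")
  epi <- doc[["epi"]]
  if (is.null(epi)) stop("epi block required")
  if (!all(LIFETABLE_BANDS$name %in% names(values)))
    stop("life_table required: missing ",
         paste(setdiff(LIFETABLE_BANDS$name, names(values)), collapse = ", "))

  ps <- structure(list(values = values, dists = dists,
                       settings = settings, epi = epi),
                  class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' Fingerprint of a resolved parameter set
#'
#' Stable hash of the full resolved configuration (values, distributions,
#' settings, epidemiology), embedded in report files so results are traceable
#' to their inputs.
#'
#' @param ps a `parameter_set`
#' @return a short hash string
#' @export
parameter_hash <- function(ps) {
  rlang::hash(list(as.list(ps$values), ps$dists, ps$settings, ps$epi))
}
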