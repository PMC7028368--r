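#' Read a measurement table with schema validation
#'
#' All package inputs are plain CSV/TSV with unit-suffixed headers
#' (`_um`, `_s`, `_ms`, `_min`) so units travel with the data. Readers check
#' that the required columns are present (extra columns are tolerated) and
#' run row-level validity checks; in strict mode (default) an invalid row is
#' an error naming the offending line, in permissive mode invalid rows are
#' dropped with a warning.
#'
#' @param path File path (comma- or tab-delimited, sniffed from the
#'   extension: `.tsv`/`.tab` is tab).
#' @param required Character vector of required column names.
#' @param positive,non_negative Columns that must be strictly positive /
#'   non-negative in every row.
#' @param permissive Drop invalid rows instead of failing.
#' @return A tibble.
#' @export
read_table_checked <- function(path, required, positive = character(),
                               non_negative = character(),
                               permissive = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE)
  assert_columns(df, required, path)
  bad <- rep(FALSE, nrow(df))
  for (col in positive) {
    bad <- bad | !is.finite(df[[col]]) | df[[col]] <= 0
  }
  for (col in non_negative) {
    bad <- bad | !is.finite(df[[col]]) | df[[col]] < 0
  }
  if (any(bad)) {
    rows <- which(bad)
    msg <- sprintf(
      "%d invalid row(s) in %s (data line%s %s).",
      length(rows), path, if (length(rows) > 1) "s" else "",
      paste(head(rows, 10), collapse = ", ")
    )
    if (!permissive) {
      abort(msg)
    }
    warn(paste(msg, "Dropped."))
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Typed readers for the standard input schemas
#'
#' Convenience wrappers over [read_table_checked()] for each analysis
#' stage's input table.
#'
#' @inheritParams read_table_checked
#' @name table-readers
NULL

#' @rdname table-readers
#' @export
read_spine_table <- function(path, permissive = FALSE) {
  read_table_checked(path,
    required = c("neuron_id", "dendrite_id", "spine_id", "length_um",
      "head_um", "neck_um"),
    positive = c("length_um", "head_um", "neck_um"),
    permissive = permissive
  )
}

#' @rdname table-readers
#' @export
read_dendrite_table <- function(path, permissive = FALSE) {
  read_table_checked(path,
    required = c("dendrite_id", "length_um"),
    positive = "length_um", permissive = permissive
  )
}

#' @rdname table-readers
#' @export
read_trace_table <- function(path, permissive = FALSE) {
  read_table_checked(path,
    required = c("dendrite_id", "granule_id", "time_s"),
    non_negative = "time_s", permissive = permissive
  )
}

#' @rdname table-readers
#' @export
read_protrusion_table <- function(path, permissive = FALSE) {
  read_table_checked(path,
    required = c("mouse_id", "dendrite_id", "day", "protrusion_id",
      "arc_position_um", "length_um", "head_um", "neck_um",
      "shaft_diameter_um"),
    positive = c("length_um", "head_um", "neck_um", "shaft_diameter_um"),
    permissive = permissive
  )
}

#' @rdname table-readers
#' @export
read_puncta_table <- function(path, permissive = FALSE) {
  read_table_checked(path,
    required = c("dendrite_id", "position_um"),
    non_negative = "position_um", permissive = permissive
  )
}

#' Write reproducibility metadata for an analysis run
#'
#' Records the package version, R version, seed, and every threshold in
#' effect — the canonical defaults plus any overrides — as JSON, so a result
#' directory is self-describing.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed used for the run (or `NULL`).
#' @param overrides Named list of parameter overrides to record next to the
#'   defaults.
#' @param inputs Optional character vector of input file paths; their MD5
#'   digests are recorded.
#' @return The metadata list, invisibly; written to
#'   `file.path(out_dir, "run_metadata.json")`.
#' @export
write_run_metadata <- function(out_dir, seed = NULL, overrides = list(),
                               inputs = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    package = "spinedyn",
    version = as.character(utils::packageVersion("spinedyn")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    thresholds = default_thresholds(),
    overrides = overrides,
    input_md5 = if (length(inputs) > 0) {
      as.list(setNames(as.character(tools::md5sum(inputs)), inputs))
    } else {
      NULL
    }
  )
  path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(meta)
}
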