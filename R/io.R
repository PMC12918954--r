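#' Write / read a recording as CSV plus a JSON sidecar
#'
#' Recordings are stored as a long-form CSV (`trial`, `sweep`,
#' `sample_index`, `command`, `recorded`) next to a JSON sidecar
#' (`<path>.json`) holding `dt`, `mode`, `capacitance`, sweep labels,
#' `rmp_measured` and free-form metadata. The round trip is lossless:
#' numbers are written with shortest round-trippable precision, so
#' `read_recording(write_recording(rec))` reproduces `rec` bit-exactly.
#'
#' @param rec A [new_recording()] object.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  labels <- rec$data %>%
    dplyr::distinct(.data$sweep, .data$label) %>%
    arrange(.data$sweep)
  out <- rec$data %>%
    arrange(.data$trial, .data$sweep, .data$time) %>%
    group_by(.data$trial, .data$sweep) %>%
    mutate(sample_index = dplyr::row_number() - 1L) %>%
    ungroup() %>%
    select("trial", "sweep", "sample_index", "command", "recorded")
  readr::write_csv(out, path)
  sidecar <- list(dt = rec$dt, mode = rec$mode,
                  capacitance = rec$capacitance,
                  rmp_measured = rec$rmp_measured,
                  labels = as.list(setNames(labels$label,
                                            as.character(labels$sweep))),
                  metadata = rec$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    abort(paste("missing JSON sidecar:", sidecar_path))
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$dt) || side$dt <= 0) abort("sidecar dt must be positive")
  if (!side$mode %in% c("CC", "VC")) abort("sidecar mode must be CC or VC")
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trial = readr::col_integer(),
                           sweep = readr::col_integer(),
                           sample_index = readr::col_integer(),
                           command = readr::col_double(),
                           recorded = readr::col_double()))
  need <- c("trial", "sweep", "sample_index", "command", "recorded")
  if (!all(need %in% names(raw))) abort("malformed recording CSV")
  lens <- dplyr::count(raw, .data$trial, .data$sweep)
  if (any(lens$n < 2L)) abort("sweep of length < 2 in recording CSV")
  per_sweep <- dplyr::distinct(lens, .data$sweep, .data$n)
  if (anyDuplicated(per_sweep$sweep)) {
    abort("inconsistent sweep lengths across trials")
  }
  labels <- unlist(side$labels)
  data <- raw %>%
    mutate(time = .data$sample_index * side$dt,
           label = unname(labels[as.character(.data$sweep)])) %>%
    select("trial", "sweep", "label", "time", "command", "recorded")
  meta <- side$metadata
  if (is.null(meta)) meta <- list()
  new_recording(data, dt = side$dt, mode = side$mode,
                capacitance = side$capacitance,
                rmp_measured = side$rmp_measured,
                metadata = as.list(meta))
}

#' Read / write a typed TSV table against a schema
#'
#' `schema` is a named character vector mapping required column names to
#' types (`"character"`, `"double"`, `"integer"`). Unknown columns are
#' preserved (type-guessed). An empty data section yields an empty tibble.
#'
#' @param path TSV file path.
#' @param schema Named character vector of required columns and types.
#' @return A tibble with at least the schema columns, correctly typed.
#' @export
read_table <- function(path, schema) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  missing_cols <- setdiff(names(schema), names(tbl))
  if (length(missing_cols)) {
    abort(paste("missing required column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  for (nm in names(schema)) {
    col <- tbl[[nm]]
    tbl[[nm]] <- switch(schema[[nm]],
      character = as.character(col),
      integer = {
        if (!nrow(tbl)) integer(0)
        else if (is.character(col) || any(is.na(suppressWarnings(as.integer(col))) & !is.na(col))) {
          abort(paste0("column '", nm, "' contains non-integer values"))
        } else as.integer(col)
      },
      double = {
        if (!nrow(tbl)) double(0)
        else if (is.character(col)) {
          abort(paste0("column '", nm, "' contains non-numeric values"))
        } else as.double(col)
      },
      abort(paste("unknown schema type:", schema[[nm]]))
    )
  }
  tbl
}

#' @rdname read_table
#' @param tbl Tibble to write.
#' @export
write_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}
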