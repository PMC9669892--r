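#' Read and write registry exports as CSV
#'
#' Datasets are exchanged as UTF-8 CSV files with a header row. Timestamps
#' are serialized as timezone-naive ISO-8601 at minute-or-better resolution
#' (`2020-01-31T09:15:00`), dates as `2020-01-31`, ternary flags as
#' `"yes"`/`"no"` with the empty string for missing. Writing then reading a
#' dataset reproduces it field for field.
#'
#' `write_app_export()` writes `profiles.csv`, `entries.csv` and
#' `families.csv` into `dir`; `write_office_export()` writes
#' `patients.csv` and `visits.csv`.
#'
#' @param x a `fever_app_dataset` or `fever_office_dataset`.
#' @param dir directory for the CSV files (created if needed).
#' @return the input dataset, invisibly (writers); the parsed dataset
#'   (readers).
#' @name registry_io
NULL

iso_ts <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

write_plain_csv <- function(df, path) {
  readr::write_csv(df, path, na = "", progress = FALSE)
}

read_plain_csv <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, na = "", progress = FALSE)
}

#' @rdname registry_io
#' @export
write_app_export <- function(x, dir) {
  stopifnot(inherits(x, "fever_app_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- x$profiles
  p$created_at <- iso_ts(p$created_at)
  e <- x$entries
  e$occurred_at <- iso_ts(e$occurred_at)
  write_plain_csv(p, file.path(dir, "profiles.csv"))
  write_plain_csv(e, file.path(dir, "entries.csv"))
  write_plain_csv(x$families, file.path(dir, "families.csv"))
  invisible(x)
}

#' @rdname registry_io
#' @export
read_app_export <- function(dir) {
  p <- read_plain_csv(file.path(dir, "profiles.csv"), readr::cols(
    family_code = readr::col_character(),
    profile_id = readr::col_character(),
    gender = readr::col_character(),
    birth_month = readr::col_integer(),
    birth_year = readr::col_integer(),
    is_adult = readr::col_logical(),
    created_at = readr::col_character()))
  p$created_at <- parse_ts(p$created_at)
  e <- read_plain_csv(file.path(dir, "entries.csv"), readr::cols(
    profile_id = readr::col_character(),
    occurred_at = readr::col_character(),
    temperature = readr::col_double(),
    physician_visit = readr::col_character(),
    antipyretic = readr::col_character(),
    antibiotic = readr::col_character(),
    healthy_marker = readr::col_logical()))
  e$occurred_at <- parse_ts(e$occurred_at)
  fam_path <- file.path(dir, "families.csv")
  fam <- if (file.exists(fam_path)) {
    read_plain_csv(fam_path, readr::cols(family_code = readr::col_character()))
  } else NULL
  app_dataset(p, e, families = fam)
}

#' @rdname registry_io
#' @export
write_office_export <- function(x, dir) {
  stopifnot(inherits(x, "fever_office_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plain_csv(x$patients, file.path(dir, "patients.csv"))
  write_plain_csv(x$visits, file.path(dir, "visits.csv"))
  invisible(x)
}

#' @rdname registry_io
#' @export
read_office_export <- function(dir) {
  p <- read_plain_csv(file.path(dir, "patients.csv"), readr::cols(
    family_code = readr::col_character(),
    patient_id = readr::col_character(),
    gender = readr::col_character(),
    birth_date = readr::col_date(),
    registered_at = readr::col_date()))
  v <- read_plain_csv(file.path(dir, "visits.csv"), readr::cols(
    patient_id = readr::col_character(),
    visit_date = readr::col_date(),
    kind = readr::col_character(),
    max_temperature = readr::col_double(),
    physician_visit = readr::col_character(),
    antipyretic = readr::col_character(),
    antibiotic = readr::col_character()))
  office_dataset(p, v)
}
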