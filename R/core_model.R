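#' Ternary flag levels
#'
#' Diary flags (physician visit, antipyretic, antibiotic) are ternary:
#' `"yes"`, `"no"`, or missing (`NA`). Missingness is preserved in the data
#' model; the negation coercion (missing treated as "no") is applied only
#' when episodes are summarized, so that non-submission remains
#' distinguishable from an explicit negative upstream.
#'
#' @param x character vector of flag values.
#' @return `as_ternary()` returns a character vector with values in
#'   `c("yes", "no", NA)`; `ternary_to_logical()` returns a logical vector
#'   with the coercion `NA -> FALSE` applied.
#' @examples
#' as_ternary(c("yes", "no", "", NA))
#' ternary_to_logical(c("yes", NA, "no"))
#' @export
as_ternary <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- !is.na(x) & !x %in% c("yes", "no")
  if (any(bad)) {
    abort(sprintf(
      "ternary flags must be 'yes', 'no' or missing; got %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  x
}

#' @rdname as_ternary
#' @export
ternary_to_logical <- function(x) {
  x <- as_ternary(x)
  !is.na(x) & x == "yes"
}

app_gender_levels <- c("female", "male", "diverse")
office_gender_levels <- c("female", "male")

#' Construct an app-registry dataset
#'
#' Bundles the two tables of the app export -- child/adult profiles and
#' timestamped diary entries -- plus an optional family table listing every
#' registered family code (families that installed the app without creating
#' a profile appear only there).
#'
#' @param profiles tibble with columns `family_code`, `profile_id`,
#'   `gender` (`"female"`, `"male"`, `"diverse"`), `birth_month`,
#'   `birth_year` (integers, may be `NA`), `is_adult` (logical),
#'   `created_at` (POSIXct).
#' @param entries tibble with columns `profile_id`, `occurred_at`
#'   (POSIXct, the reported time of real occurrence), `temperature`
#'   (degrees Celsius, may be `NA`), `physician_visit`, `antipyretic`,
#'   `antibiotic` (ternary), `healthy_marker` (logical).
#' @param families optional tibble with column `family_code` (one row per
#'   registered family). Defaults to the family codes present in
#'   `profiles`.
#' @return an object of class `fever_app_dataset`: a list with elements
#'   `profiles`, `entries`, `families`.
#' @seealso [office_dataset()], [validate_dataset()]
#' @export
app_dataset <- function(profiles, entries, families = NULL) {
  profiles <- tibble::as_tibble(profiles)
  entries <- tibble::as_tibble(entries)
  need_p <- c("family_code", "profile_id", "gender", "birth_month",
              "birth_year", "is_adult", "created_at")
  need_e <- c("profile_id", "occurred_at", "temperature", "physician_visit",
              "antipyretic", "antibiotic", "healthy_marker")
  check_columns(profiles, need_p, "profiles")
  check_columns(entries, need_e, "entries")
  if (anyDuplicated(profiles$profile_id)) {
    abort("duplicate profile_id in app profiles table")
  }
  entries$physician_visit <- as_ternary(entries$physician_visit)
  entries$antipyretic <- as_ternary(entries$antipyretic)
  entries$antibiotic <- as_ternary(entries$antibiotic)
  if (is.null(families)) {
    families <- tibble::tibble(family_code = sort(unique(profiles$family_code)))
  } else {
    families <- tibble::as_tibble(families)
    check_columns(families, "family_code", "families")
  }
  structure(
    list(profiles = profiles, entries = entries, families = families),
    class = "fever_app_dataset"
  )
}

#' Construct an office (reference-records) dataset
#'
#' Bundles the physician's structured export: patient demographics and
#' per-visit fever reports. Each visit row describes one fever episode as
#' recorded by the office, either observed during the visit (`"acute"`) or
#' reported retrospectively when the physician asked about fever since the
#' last visit (`"past"`).
#'
#' @param patients tibble with columns `family_code`, `patient_id`,
#'   `gender` (`"female"`, `"male"`), `birth_date` (Date), `registered_at`
#'   (Date).
#' @param visits tibble with columns `patient_id`, `visit_date` (Date),
#'   `kind` (`"acute"` or `"past"`), `max_temperature`, `physician_visit`,
#'   `antipyretic`, `antibiotic` (ternary).
#' @return an object of class `fever_office_dataset`.
#' @export
office_dataset <- function(patients, visits) {
  patients <- tibble::as_tibble(patients)
  visits <- tibble::as_tibble(visits)
  check_columns(patients,
                c("family_code", "patient_id", "gender", "birth_date",
                  "registered_at"), "patients")
  check_columns(visits,
                c("patient_id", "visit_date", "kind", "max_temperature",
                  "physician_visit", "antipyretic", "antibiotic"), "visits")
  if (anyDuplicated(patients$patient_id)) {
    abort("duplicate patient_id in office patients table")
  }
  if (!all(visits$kind %in% c("acute", "past"))) {
    abort("office visit kind must be 'acute' or 'past'")
  }
  visits$physician_visit <- as_ternary(visits$physician_visit)
  visits$antipyretic <- as_ternary(visits$antipyretic)
  visits$antibiotic <- as_ternary(visits$antibiotic)
  structure(list(patients = patients, visits = visits),
            class = "fever_office_dataset")
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s table is missing column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' @export
print.fever_app_dataset <- function(x, ...) {
  cat(sprintf(
    "<fever_app_dataset> %d families, %d profiles, %d diary entries\n",
    nrow(x$families), nrow(x$profiles), nrow(x$entries)))
  invisible(x)
}

#' @export
print.fever_office_dataset <- function(x, ...) {
  cat(sprintf("<fever_office_dataset> %d patients, %d fever reports\n",
              nrow(x$patients), nrow(x$visits)))
  invisible(x)
}

#' Validate a dataset against the registry's structural rules
#'
#' Checks a dataset (app or office) for structural violations without
#' modifying it: malformed family codes (must match `^[a-z]{8}$`),
#' temperatures outside the plausible entry range, birth years outside
#' `[1900, current year]`, and entries or visits whose profile/patient
#' identifier does not occur in the demographics table. Duplicate primary
#' keys are a hard error (the tables could not have come from a consistent
#' export), everything else is reported.
#'
#' @param x a `fever_app_dataset` or `fever_office_dataset`.
#' @param temperature_range plausible temperature bounds in degrees
#'   Celsius. The app's entry bounds are not documented; the default
#'   `c(34, 43.5)` comfortably contains the observed range 36.2-42.4 and
#'   can be changed.
#' @return a tibble with columns `table`, `id`, `rule`, `message`; zero
#'   rows when the dataset is well formed.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 1, n_families = 5))
#' validate_dataset(cohort$app)
#' @export
validate_dataset <- function(x, temperature_range = c(34, 43.5)) {
  UseMethod("validate_dataset")
}

#' @export
validate_dataset.fever_app_dataset <- function(x, temperature_range = c(34, 43.5)) {
  v <- list()
  v$family <- check_family_codes(x$profiles$family_code,
                                 x$profiles$profile_id, "profiles")
  v$year <- check_birth_years(x$profiles$birth_year,
                              x$profiles$profile_id, "profiles")
  bad_t <- !is.na(x$entries$temperature) &
    (x$entries$temperature < temperature_range[1] |
       x$entries$temperature > temperature_range[2])
  v$temp <- tibble::tibble(
    table = "entries", id = as.character(x$entries$profile_id[bad_t]),
    rule = "temperature_range",
    message = sprintf("temperature %.1f outside [%.1f, %.1f]",
                      x$entries$temperature[bad_t],
                      temperature_range[1], temperature_range[2]))
  orphan <- !x$entries$profile_id %in% x$profiles$profile_id
  v$orphan <- tibble::tibble(
    table = "entries", id = as.character(x$entries$profile_id[orphan]),
    rule = "orphan_entry",
    message = "entry profile_id absent from profiles table")
  dplyr::bind_rows(v)
}

#' @export
validate_dataset.fever_office_dataset <- function(x, temperature_range = c(34, 43.5)) {
  v <- list()
  v$family <- check_family_codes(x$patients$family_code,
                                 x$patients$patient_id, "patients")
  bad_t <- !is.na(x$visits$max_temperature) &
    (x$visits$max_temperature < temperature_range[1] |
       x$visits$max_temperature > temperature_range[2])
  v$temp <- tibble::tibble(
    table = "visits", id = as.character(x$visits$patient_id[bad_t]),
    rule = "temperature_range",
    message = sprintf("temperature %.1f outside [%.1f, %.1f]",
                      x$visits$max_temperature[bad_t],
                      temperature_range[1], temperature_range[2]))
  orphan <- !x$visits$patient_id %in% x$patients$patient_id
  v$orphan <- tibble::tibble(
    table = "visits", id = as.character(x$visits$patient_id[orphan]),
    rule = "orphan_visit",
    message = "visit patient_id absent from patients table")
  dplyr::bind_rows(v)
}

check_family_codes <- function(codes, ids, table) {
  bad <- !grepl("^[a-z]{8}$", codes)
  tibble::tibble(
    table = table, id = as.character(ids[bad]), rule = "family_code",
    message = sprintf("family code '%s' is not 8 lowercase letters",
                      codes[bad]))
}

check_birth_years <- function(years, ids, table) {
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  bad <- !is.na(years) & (years < 1900 | years > this_year)
  tibble::tibble(
    table = table, id = as.character(ids[bad]), rule = "birth_year",
    message = sprintf("birth year %d outside [1900, %d]",
                      years[bad], this_year))
}
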