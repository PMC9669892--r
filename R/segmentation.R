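#' Segmentation settings
#'
#' A fever episode is a maximal run of diary entries in which no two
#' consecutive entries are separated by more than `gap_hours`. The default
#' of 48 hours encodes the registry's episode definition: if no entry was
#' made for more than two days, the next entry opens a new episode. The
#' comparison is strict, so a gap of exactly 48 hours stays within one
#' episode.
#'
#' @param gap_hours positive number of hours; gaps strictly greater than
#'   this start a new episode.
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(gap_hours = 48) {
  if (!is.numeric(gap_hours) || length(gap_hours) != 1 || gap_hours <= 0) {
    abort("gap_hours must be a single positive number")
  }
  structure(list(gap_hours = gap_hours), class = "segmentation_config")
}

#' Segment one profile's diary entries into fever episodes
#'
#' Entries are sorted by occurrence time and split wherever the gap to the
#' previous entry strictly exceeds `config$gap_hours`. Episode start and
#' end are the first and last entry timestamps. Entries with no
#' fever-related content still count for segmentation timing: the rule
#' operates on timestamps, not content. The healthy marker does not split
#' episodes; entries where a healthy marker is followed by another entry
#' within the gap window are only counted (see `attr(, "healthy_overrun")`)
#' so the report can flag them.
#'
#' @param entries diary-entry tibble for a single profile (see
#'   [app_dataset()]).
#' @param config a [segmentation_config()].
#' @return episode tibble with one row per episode: `profile_id`,
#'   `episode`, `start`, `end`, `n_entries`, plus the aggregates of
#'   [summarize_episode()]. Ordered by `start`.
#' @examples
#' e <- tibble::tibble(
#'   profile_id = "p1",
#'   occurred_at = as.POSIXct("2020-01-01", tz = "UTC") + c(0, 24, 80) * 3600,
#'   temperature = c(38.5, 39.2, 38.1),
#'   physician_visit = c(NA, "yes", NA),
#'   antipyretic = "no", antibiotic = NA, healthy_marker = FALSE
#' )
#' segment_entries(e) # two episodes: gap 56 h > 48 h
#' @export
segment_entries <- function(entries, config = segmentation_config()) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) {
    return(empty_episode_tbl())
  }
  if (length(unique(entries$profile_id)) > 1) {
    abort("segment_entries() expects entries from a single profile; use segment_profiles()")
  }
  out <- segment_all(entries, config)
  dplyr::arrange(out, .data$start)
}

# vectorized segmentation over any number of profiles
segment_all <- function(entries, config) {
  entries <- dplyr::arrange(entries, .data$profile_id, .data$occurred_at)
  same <- c(FALSE, entries$profile_id[-1] ==
              entries$profile_id[-nrow(entries)])
  gap_h <- c(Inf, diff(as.numeric(entries$occurred_at)) / 3600)
  new_ep <- !same | gap_h > config$gap_hours
  entries$episode_key <- cumsum(new_ep)
  healthy_overrun <- sum(
    entries$healthy_marker[-nrow(entries)] & same[-1] &
      gap_h[-1] <= config$gap_hours, na.rm = TRUE)
  out <- entries |>
    dplyr::group_by(.data$profile_id, .data$episode_key) |>
    dplyr::summarise(
      start = min(.data$occurred_at), end = max(.data$occurred_at),
      n_entries = dplyr::n(),
      max_temperature = if (all(is.na(.data$temperature))) NA_real_ else
        max(.data$temperature, na.rm = TRUE),
      physician_visit = any(.data$physician_visit == "yes", na.rm = TRUE),
      antipyretic = any(.data$antipyretic == "yes", na.rm = TRUE),
      antibiotic = any(.data$antibiotic == "yes", na.rm = TRUE),
      .groups = "drop") |>
    dplyr::arrange(.data$profile_id, .data$start) |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::mutate(episode = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("profile_id", "episode", "start", "end", "n_entries",
                  "max_temperature", "physician_visit", "antipyretic",
                  "antibiotic")
  attr(out, "healthy_overrun") <- healthy_overrun
  out
}

empty_episode_tbl <- function() {
  tibble::tibble(
    profile_id = character(), episode = integer(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    n_entries = integer(), max_temperature = double(),
    physician_visit = logical(), antipyretic = logical(),
    antibiotic = logical())
}

#' Aggregate one episode's entries
#'
#' `max_temperature` is the maximum of the submitted temperatures, missing
#' when none was submitted. Each ternary flag aggregates to `TRUE` when any
#' entry answers "yes"; otherwise the negation rule applies and the flag is
#' `FALSE` -- a missing answer about physician visits or medication is
#' treated as a negative.
#'
#' @param entries non-empty diary-entry tibble belonging to one episode.
#' @return a one-row tibble with `max_temperature`, `physician_visit`,
#'   `antipyretic`, `antibiotic`.
#' @export
summarize_episode <- function(entries) {
  if (nrow(entries) == 0) abort("summarize_episode() needs at least one entry")
  temps <- entries$temperature[!is.na(entries$temperature)]
  tibble::tibble(
    max_temperature = if (length(temps)) max(temps) else NA_real_,
    physician_visit = any(ternary_to_logical(entries$physician_visit)),
    antipyretic = any(ternary_to_logical(entries$antipyretic)),
    antibiotic = any(ternary_to_logical(entries$antibiotic)))
}

#' Segment every profile of an app dataset
#'
#' @param app a `fever_app_dataset`, or a raw entries tibble covering
#'   several profiles.
#' @inheritParams segment_entries
#' @return episode tibble as in [segment_entries()], one block per profile.
#'   The attribute `healthy_overrun` counts entries across all profiles
#'   where a healthy marker was followed by another entry within the gap
#'   window (possible forgotten episode closures).
#' @export
segment_profiles <- function(app, config = segmentation_config()) {
  entries <- if (inherits(app, "fever_app_dataset")) app$entries else
    tibble::as_tibble(app)
  if (nrow(entries) == 0) return(empty_episode_tbl())
  segment_all(entries, config)
}

#' Represent office visit rows as episode records
#'
#' The office export is already episode-grained: each visit row describes
#' one fever episode. This helper reshapes it to the episode schema used
#' downstream, applying the same negation coercion to the flags.
#'
#' @param office a `fever_office_dataset`.
#' @return tibble with `patient_id`, `episode`, `visit_date`, `kind`
#'   (`"acute"`/`"past"`), `max_temperature`, and coerced logical flags.
#' @export
office_episodes <- function(office) {
  stopifnot(inherits(office, "fever_office_dataset"))
  office$visits |>
    dplyr::arrange(.data$patient_id, .data$visit_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(episode = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      patient_id = .data$patient_id, episode = .data$episode,
      visit_date = .data$visit_date, kind = .data$kind,
      max_temperature = .data$max_temperature,
      physician_visit = ternary_to_logical(.data$physician_visit),
      antipyretic = ternary_to_logical(.data$antipyretic),
      antibiotic = ternary_to_logical(.data$antibiotic))
}

#' Per-unit difference in episode counts between the two sources
#'
#' Counts episodes per linked unit (profile or family) in each source and
#' returns the signed difference; positive values mean more episodes in
#' the app than in the reference records for that unit.
#'
#' @param app_episodes app episode tibble ([segment_profiles()]).
#' @param office_eps office episode tibble ([office_episodes()]).
#' @param links profile link tibble ([link_profiles()]).
#' @param by `"profile"` or `"family"`.
#' @return tibble with the unit identifier, `n_app`, `n_office`,
#'   `difference`. Only matched units are reported.
#' @export
episode_count_difference <- function(app_episodes, office_eps, links,
                                     by = c("profile", "family")) {
  by <- match.arg(by)
  matched <- dplyr::filter(links, .data$status == "matched")
  app_n <- app_episodes |>
    dplyr::count(.data$profile_id, name = "n_app")
  off_n <- office_eps |>
    dplyr::count(.data$patient_id, name = "n_office")
  per_profile <- matched |>
    dplyr::left_join(app_n, by = "profile_id") |>
    dplyr::left_join(off_n, by = "patient_id") |>
    dplyr::mutate(n_app = dplyr::coalesce(.data$n_app, 0L),
                  n_office = dplyr::coalesce(.data$n_office, 0L))
  if (by == "profile") {
    per_profile |>
      dplyr::transmute(profile_id = .data$profile_id, n_app = .data$n_app,
                       n_office = .data$n_office,
                       difference = .data$n_app - .data$n_office)
  } else {
    per_profile |>
      dplyr::group_by(family_code = .data$family_code) |>
      dplyr::summarise(n_app = sum(.data$n_app),
                       n_office = sum(.data$n_office), .groups = "drop") |>
      dplyr::mutate(difference = .data$n_app - .data$n_office)
  }
}
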