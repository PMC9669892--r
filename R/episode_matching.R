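#' Pair one child's app episodes with office-recorded episodes
#'
#' One-to-one pairing of the two sources' episodes for a single linked
#' child. An acute office episode pairs with the app episode whose
#' interval contains the visit date; acute episodes still unpaired then
#' take the nearest unpaired app episode starting within
#' `acute_window_days` of the visit. A past office episode (reported
#' retrospectively at a later visit) pairs with the most recent unpaired
#' app episode ending before the visit date, looking back at most
#' `past_window_days`. Episodes left without a partner become
#' `app_only` / `office_only` rows; no episode pairs twice.
#'
#' Conflicts are resolved by augmenting-path maximum matching over the
#' feasible (window-respecting) pairs, with acute visits claiming their
#' preferred episode before past reports: the pairing always attains the
#' maximum possible number of pairs, and on conflict a visit falls back to
#' its next-preferred feasible episode.
#'
#' The original study states no correspondence algorithm; this windowed
#' pairing is a declared convention whose windows are explicit,
#' reportable parameters.
#'
#' @param app_eps app episode tibble for one profile ([segment_entries()]).
#' @param office_eps office episode tibble for one patient
#'   ([office_episodes()]).
#' @param acute_window_days fallback window for acute visits (days).
#' @param past_window_days look-back window for past reports (days).
#' @return tibble with `app_episode`, `office_episode` (episode indices,
#'   `NA` when absent) and `match_type`
#'   (`"paired"`, `"app_only"`, `"office_only"`).
#' @export
match_episodes <- function(app_eps, office_eps, acute_window_days = 7,
                           past_window_days = 60) {
  app_eps <- tibble::as_tibble(app_eps)
  office_eps <- tibble::as_tibble(office_eps)
  n_app <- nrow(app_eps)
  n_off <- nrow(office_eps)
  if (n_app > 0) {
    app_start <- as.Date(app_eps$start)
    app_end <- as.Date(app_eps$end)
    app_order <- order(app_start)
  } else {
    app_start <- app_end <- as.Date(character())
    app_order <- integer()
  }
  off_idx <- if (n_off > 0) order(office_eps$visit_date) else integer()
  acute_idx <- off_idx[office_eps$kind[off_idx] == "acute"]
  past_idx <- off_idx[office_eps$kind[off_idx] == "past"]

  # preference-ordered feasible app episodes per office episode
  candidates <- vector("list", n_off)
  for (j in acute_idx) {
    vd <- office_eps$visit_date[j]
    contain <- which(app_start <= vd & vd <= app_end)
    near <- setdiff(which(abs(as.numeric(app_start - vd)) <=
                            acute_window_days), contain)
    d <- abs(as.numeric(app_start[near] - vd))
    candidates[[j]] <- base::c(contain[order(app_start[contain])],
                               near[order(d, app_start[near])])
  }
  for (j in past_idx) {
    vd <- office_eps$visit_date[j]
    back <- as.numeric(vd - app_end)
    cand <- which(back > 0 & back <= past_window_days)
    candidates[[j]] <- cand[order(app_end[cand], decreasing = TRUE)]
  }

  # augmenting-path maximum matching: office episodes claim candidates in
  # preference order (acute visits in date order before past reports), and
  # a later visit may displace an earlier pairing onto that visit's next
  # preference, so no feasible pairing is left unused
  owner <- rep(NA_integer_, n_app)  # office index holding each app episode
  visited <- logical(n_app)
  try_assign <- function(j) {
    for (i in candidates[[j]]) {
      if (visited[i]) next
      visited[i] <<- TRUE
      if (is.na(owner[i])) {
        owner[i] <<- j
        return(TRUE)
      }
      prev <- owner[i]
      owner[i] <<- j
      if (try_assign(prev)) return(TRUE)
      owner[i] <<- prev
    }
    FALSE
  }
  for (j in base::c(acute_idx, past_idx)) {
    visited <- logical(n_app)
    try_assign(j)
  }
  pair_of <- rep(NA_integer_, n_off)
  pair_of[owner[!is.na(owner)]] <- which(!is.na(owner))
  app_free <- is.na(owner)

  paired <- tibble::tibble(
    app_episode = if (n_off) app_eps$episode[pair_of] else integer(),
    office_episode = if (n_off) office_eps$episode else integer(),
    match_type = if (n_off) ifelse(is.na(pair_of), "office_only", "paired")
                 else character())
  app_only <- tibble::tibble(
    app_episode = app_eps$episode[app_free],
    office_episode = NA_integer_,
    match_type = rep("app_only", sum(app_free)))
  out <- dplyr::bind_rows(paired, app_only)
  dplyr::arrange(out, .data$match_type != "paired", .data$office_episode,
                 .data$app_episode)
}

#' Grade per-variable agreement of a paired episode
#'
#' Binary elements (physician visit, antipyretic, antibiotic) agree when
#' equal after the negation coercion. Maximum temperature agrees when the
#' absolute difference is below `temp_tolerance` (0.05 by default, i.e.
#' exact agreement at the sources' 0.1 degree resolution) and is
#' `not_comparable` when either side did not submit a temperature. The
#' temperature difference is reported app minus office: positive values
#' mean the app temperature was higher.
#'
#' @param app_ep one-row app episode tibble.
#' @param office_ep one-row office episode tibble.
#' @param temp_tolerance maximum absolute difference (degrees Celsius)
#'   still counted as agreement.
#' @return one-row tibble with `physician_visit`, `antipyretic`,
#'   `antibiotic`, `max_temperature` verdicts (`"agree"`, `"disagree"`,
#'   `"not_comparable"`) and `temp_difference`.
#' @export
grade_agreement <- function(app_ep, office_ep, temp_tolerance = 0.05) {
  bin <- function(a, o) ifelse(a == o, "agree", "disagree")
  ta <- app_ep$max_temperature
  to <- office_ep$max_temperature
  temp_verdict <- dplyr::case_when(
    is.na(ta) | is.na(to) ~ "not_comparable",
    abs(ta - to) < temp_tolerance ~ "agree",
    TRUE ~ "disagree")
  tibble::tibble(
    physician_visit = bin(app_ep$physician_visit, office_ep$physician_visit),
    antipyretic = bin(app_ep$antipyretic, office_ep$antipyretic),
    antibiotic = bin(app_ep$antibiotic, office_ep$antibiotic),
    max_temperature = temp_verdict,
    temp_difference = ta - to)
}

#' Match episodes for every linked child of a cohort
#'
#' Applies [match_episodes()] per matched profile/patient pair and grades
#' agreement on the paired rows.
#'
#' @param app_episodes episode tibble for all profiles
#'   ([segment_profiles()]).
#' @param office_eps office episode tibble ([office_episodes()]).
#' @param links link tibble ([link_profiles()]).
#' @inheritParams match_episodes
#' @inheritParams grade_agreement
#' @return tibble with `profile_id`, `patient_id`, `app_episode`,
#'   `office_episode`, `match_type`, `office_kind`, the agreement verdict
#'   columns of [grade_agreement()] (`NA` for unpaired rows), and
#'   `temp_difference`.
#' @export
match_cohort_episodes <- function(app_episodes, office_eps, links,
                                  acute_window_days = 7,
                                  past_window_days = 60,
                                  temp_tolerance = 0.05) {
  matched <- dplyr::filter(links, .data$status == "matched")
  app_by_profile <- split(app_episodes, app_episodes$profile_id)
  off_by_patient <- split(office_eps, office_eps$patient_id)
  empty_app <- app_episodes[0, ]
  empty_off <- office_eps[0, ]
  rows <- vector("list", nrow(matched))
  for (r in seq_len(nrow(matched))) {
    pid <- matched$profile_id[r]
    pat <- matched$patient_id[r]
    a <- app_by_profile[[pid]] %||% empty_app
    o <- off_by_patient[[pat]] %||% empty_off
    if (nrow(a) == 0 && nrow(o) == 0) next
    m <- match_episodes(a, o, acute_window_days, past_window_days)
    m$profile_id <- pid
    m$patient_id <- pat
    rows[[r]] <- m
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      profile_id = character(), patient_id = character(),
      app_episode = integer(), office_episode = integer(),
      match_type = character(), office_kind = character(),
      agree_physician_visit = character(), agree_antipyretic = character(),
      agree_antibiotic = character(), agree_max_temperature = character(),
      temp_difference = double()))
  }
  # vectorized grading (same rules as grade_agreement())
  out <- out |>
    dplyr::left_join(
      dplyr::select(office_eps, "patient_id", office_episode = "episode",
                    office_kind = "kind", o_visit = "physician_visit",
                    o_anti = "antipyretic", o_abx = "antibiotic",
                    o_temp = "max_temperature"),
      by = c("patient_id", "office_episode")) |>
    dplyr::left_join(
      dplyr::select(app_episodes, "profile_id", app_episode = "episode",
                    a_visit = "physician_visit", a_anti = "antipyretic",
                    a_abx = "antibiotic", a_temp = "max_temperature"),
      by = c("profile_id", "app_episode"))
  is_pair <- out$match_type == "paired"
  bin <- function(a, o) {
    ifelse(is_pair, ifelse(a == o, "agree", "disagree"), NA_character_)
  }
  out$agree_physician_visit <- bin(out$a_visit, out$o_visit)
  out$agree_antipyretic <- bin(out$a_anti, out$o_anti)
  out$agree_antibiotic <- bin(out$a_abx, out$o_abx)
  out$agree_max_temperature <- dplyr::case_when(
    !is_pair ~ NA_character_,
    is.na(out$a_temp) | is.na(out$o_temp) ~ "not_comparable",
    abs(out$a_temp - out$o_temp) < temp_tolerance ~ "agree",
    TRUE ~ "disagree")
  out$temp_difference <- ifelse(is_pair, out$a_temp - out$o_temp, NA_real_)
  dplyr::select(out, "profile_id", "patient_id", "app_episode",
                "office_episode", "match_type", "office_kind",
                dplyr::starts_with("agree_"), "temp_difference")
}

#' Partition both sources' episodes into the reconciliation cells
#'
#' Classifies every fever episode of the two sources into the cells of the
#' two-source Venn partition: office episodes from registered families
#' that never made an app entry, office episodes from children without an
#' app profile, and -- for children present in both sources -- paired
#' versus single-source episodes, with the office side further split into
#' acute and past. On the app side, episodes of profiles that cannot be
#' identified in the office records (siblings, adults, families absent
#' from the office export) are separated from identifiable episodes,
#' which split into paired and app-exclusive. Cells sum to the source
#' totals.
#'
#' @param matches cohort match tibble ([match_cohort_episodes()]).
#' @param links link tibble ([link_profiles()]).
#' @param app_episodes episode tibble for all profiles.
#' @param office_eps office episode tibble.
#' @param registered_families character vector of family codes registered
#'   in the app (defaults to the families seen among the app profiles).
#' @return named list of integer cell counts.
#' @export
venn_partition <- function(matches, links, app_episodes, office_eps,
                           registered_families = NULL) {
  prof_fam <- links |>
    dplyr::filter(!is.na(.data$profile_id)) |>
    dplyr::distinct(.data$profile_id, .data$family_code, .data$status,
                    .data$family_in_office)
  pat_info <- links |>
    dplyr::filter(!is.na(.data$patient_id)) |>
    dplyr::distinct(.data$patient_id, .data$family_code, .data$status)
  if (is.null(registered_families)) {
    registered_families <- unique(prof_fam$family_code)
  }

  app_e <- dplyr::left_join(app_episodes, prof_fam, by = "profile_id")
  active_fams <- unique(app_e$family_code)

  off_e <- dplyr::left_join(office_eps, pat_info, by = "patient_id")
  off_e <- dplyr::filter(off_e, .data$family_code %in% registered_families)
  off_e$cell <- dplyr::case_when(
    !off_e$family_code %in% active_fams ~ "family_without_app_entries",
    off_e$status == "office_only" ~ "child_without_profile",
    TRUE ~ "child_with_profile")

  paired_off <- matches |>
    dplyr::filter(.data$match_type == "paired") |>
    dplyr::distinct(.data$patient_id, .data$office_episode)
  with_prof <- dplyr::filter(off_e, .data$cell == "child_with_profile")
  with_prof$paired <- vapply(seq_len(nrow(with_prof)), function(i) {
    any(paired_off$patient_id == with_prof$patient_id[i] &
          paired_off$office_episode == with_prof$episode[i])
  }, logical(1))

  identifiable <- app_e$status == "matched" & app_e$family_in_office
  app_ident <- app_e[identifiable, ]
  paired_app <- matches |>
    dplyr::filter(.data$match_type == "paired") |>
    dplyr::distinct(.data$profile_id, .data$app_episode)
  app_ident$paired <- vapply(seq_len(nrow(app_ident)), function(i) {
    any(paired_app$profile_id == app_ident$profile_id[i] &
          paired_app$app_episode == app_ident$episode[i])
  }, logical(1))

  list(
    office_total = nrow(off_e),
    office_family_without_app_entries =
      sum(off_e$cell == "family_without_app_entries"),
    office_child_without_profile =
      sum(off_e$cell == "child_without_profile"),
    office_children_with_profiles = nrow(with_prof),
    office_acute = sum(with_prof$kind == "acute"),
    office_past = sum(with_prof$kind == "past"),
    office_paired = sum(with_prof$paired),
    office_paired_acute = sum(with_prof$paired & with_prof$kind == "acute"),
    office_paired_past = sum(with_prof$paired & with_prof$kind == "past"),
    office_only = sum(!with_prof$paired),
    office_only_acute = sum(!with_prof$paired & with_prof$kind == "acute"),
    office_only_past = sum(!with_prof$paired & with_prof$kind == "past"),
    app_total = nrow(app_e),
    app_unidentifiable = sum(!identifiable),
    app_identifiable = nrow(app_ident),
    app_paired = sum(app_ident$paired),
    app_only = sum(!app_ident$paired))
}
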