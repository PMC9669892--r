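#' Detect synonymous (duplicate) child profiles within one family
#'
#' Duplicate profiles arise when two caregivers register the same child on
#' two devices before the devices synchronize. Within a family, child
#' profiles with identical gender and month/year of birth form one
#' duplicate group; the earliest-created profile is canonical. Profiles
#' with a missing birth month/year never group (identity cannot be
#' confirmed).
#'
#' @param profiles app profile tibble for a single family.
#' @return tibble `profile_id`, `group`, `canonical` covering the profiles
#'   that belong to a duplicate group; zero rows when all demographics are
#'   distinct.
#' @export
detect_synonymous_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) == 0) return(empty_dup_tbl())
  if (length(unique(profiles$family_code)) > 1) {
    abort("detect_synonymous_profiles() expects profiles of one family")
  }
  keep <- !profiles$is_adult & !is.na(profiles$birth_month) &
    !is.na(profiles$birth_year)
  kids <- profiles[keep, ]
  if (nrow(kids) < 2) return(empty_dup_tbl())
  kids <- kids[order(kids$created_at, kids$profile_id), ]
  key <- paste(kids$gender, kids$birth_month, kids$birth_year)
  in_group <- key %in% key[duplicated(key)]
  kids <- kids[in_group, ]
  key <- key[in_group]
  if (nrow(kids) == 0) return(empty_dup_tbl())
  tibble::tibble(
    profile_id = kids$profile_id,
    group = match(key, unique(key)),
    canonical = !duplicated(key))
}

empty_dup_tbl <- function() {
  tibble::tibble(profile_id = character(), group = integer(),
                 canonical = logical())
}

map_gender <- function(x) {
  # app offers three options, the office two; "diverse" never auto-matches
  ifelse(x %in% office_gender_levels, x, paste0("app:", x))
}

#' Compare demographics of a matched app profile / office patient pair
#'
#' Gender is compared after mapping the app's three answer options onto
#' the office's two; `"diverse"` is always a recorded mismatch when the
#' office value differs. Date of birth is compared at month/year
#' granularity only, because the app stores only month and year of birth.
#' A missing app birth date is classified as `dob_missing` (incomplete,
#' not discordant). Which source holds the correct value is not decided;
#' mismatches are symmetric.
#'
#' @param app_profile one-row tibble from the app profiles table.
#' @param office_patient one-row tibble from the office patients table.
#' @return character vector, a subset of
#'   `c("gender", "date_of_birth", "dob_missing")`.
#' @export
compare_demographics <- function(app_profile, office_patient) {
  out <- character()
  if (map_gender(app_profile$gender) != map_gender(office_patient$gender)) {
    out <- c(out, "gender")
  }
  if (is.na(app_profile$birth_month) || is.na(app_profile$birth_year)) {
    out <- c(out, "dob_missing")
  } else {
    om <- as.integer(format(office_patient$birth_date, "%m"))
    oy <- as.integer(format(office_patient$birth_date, "%Y"))
    if (app_profile$birth_month != om || app_profile$birth_year != oy) {
      out <- c(out, "date_of_birth")
    }
  }
  out
}

#' Link app profiles to office patients
#'
#' Deterministic record linkage within each family code. Synonymous
#' duplicates are collapsed first (the canonical profile represents the
#' group). Adult profiles are set aside. Remaining child profiles are
#' matched to the family's office patients greedily, preferring full
#' (gender and date-of-birth) agreement, then date-of-birth-only, then
#' gender-only agreement; ties are broken by earlier office registration.
#' If after these passes exactly one child and one patient remain
#' unmatched in a family they are paired as sole remaining candidates
#' (this recovers genuine pairs in which both recorded demographics are
#' erroneous). Unmatched app children are classified `app_only_sibling`,
#' unmatched adults `app_only_adult`, unmatched patients `office_only`.
#'
#' @param app_profiles app profiles tibble, or a `fever_app_dataset`.
#' @param office_patients office patients tibble, or a
#'   `fever_office_dataset`.
#' @param strict error when a family code present in the app is absent
#'   from the office export (default: keep such profiles, flagged with
#'   `family_in_office = FALSE`).
#' @param sole_pair enable the sole-remaining-candidate rule.
#' @return tibble with one row per input profile and per input patient:
#'   `family_code`, `profile_id` (`NA` for `office_only`), `patient_id`
#'   (`NA` unless matched), `status`, `family_in_office`,
#'   `duplicate_of` (canonical profile for collapsed duplicates),
#'   `mismatch_gender`, `mismatch_dob`, `dob_missing`.
#' @export
link_profiles <- function(app_profiles, office_patients, strict = FALSE,
                          sole_pair = TRUE) {
  if (inherits(app_profiles, "fever_app_dataset")) {
    app_profiles <- app_profiles$profiles
  }
  if (inherits(office_patients, "fever_office_dataset")) {
    office_patients <- office_patients$patients
  }
  app_profiles <- tibble::as_tibble(app_profiles)
  office_patients <- tibble::as_tibble(office_patients)
  office_fams <- unique(office_patients$family_code)
  missing_fams <- setdiff(unique(app_profiles$family_code), office_fams)
  if (strict && length(missing_fams) > 0) {
    abort(sprintf("family code(s) absent from office export: %s",
                  paste(missing_fams, collapse = ", ")))
  }
  fams <- union(unique(app_profiles$family_code), office_fams)
  app_split <- split(app_profiles, app_profiles$family_code)
  office_split <- split(office_patients, office_patients$family_code)
  empty_app <- app_profiles[0, ]
  empty_office <- office_patients[0, ]
  rows <- lapply(fams, function(fc) {
    link_one_family(
      app_split[[fc]] %||% empty_app,
      office_split[[fc]] %||% empty_office,
      fc, family_in_office = fc %in% office_fams, sole_pair = sole_pair)
  })
  dplyr::bind_rows(rows)
}

link_one_family <- function(app, office, fc, family_in_office, sole_pair) {
  # accumulate plain vectors; one tibble per family at the end
  acc <- list(profile_id = character(), patient_id = character(),
              status = character(), duplicate_of = character(),
              mg = logical(), md = logical(), dm = logical())
  add <- function(profile_id = NA_character_, patient_id = NA_character_,
                  status, duplicate_of = NA_character_,
                  mismatches = character()) {
    acc$profile_id <<- base::c(acc$profile_id, profile_id)
    acc$patient_id <<- base::c(acc$patient_id, patient_id)
    acc$status <<- base::c(acc$status, status)
    acc$duplicate_of <<- base::c(acc$duplicate_of, duplicate_of)
    acc$mg <<- base::c(acc$mg, "gender" %in% mismatches)
    acc$md <<- base::c(acc$md, "date_of_birth" %in% mismatches)
    acc$dm <<- base::c(acc$dm, "dob_missing" %in% mismatches)
  }

  dups <- if (nrow(app) > 1) detect_synonymous_profiles(app) else
    empty_dup_tbl()
  shadowed <- dups$profile_id[!dups$canonical]
  for (pid in shadowed) {
    canon <- dups$profile_id[dups$canonical &
                               dups$group == dups$group[dups$profile_id == pid]]
    add(profile_id = pid, status = "synonymous_duplicate",
        duplicate_of = canon[1])
  }

  for (pid in app$profile_id[app$is_adult]) {
    add(profile_id = pid, status = "app_only_adult")
  }

  kids <- app[!app$is_adult & !app$profile_id %in% shadowed, ]
  kids <- kids[order(kids$created_at, kids$profile_id), ]
  office <- office[order(office$registered_at, office$patient_id), ]

  nk <- nrow(kids); no <- nrow(office)
  kid_g <- map_gender(kids$gender)
  pat_g <- map_gender(office$gender)
  pat_m <- as.integer(format(office$birth_date, "%m"))
  pat_y <- as.integer(format(office$birth_date, "%Y"))
  dob_na <- is.na(kids$birth_month) | is.na(kids$birth_year)
  g_ok <- outer(kid_g, pat_g, "==")
  d_ok <- outer(kids$birth_month, pat_m, "==") &
    outer(kids$birth_year, pat_y, "==")
  d_ok[is.na(d_ok)] <- FALSE
  ok <- list(full = g_ok & d_ok, dob = d_ok, gender = g_ok)

  kid_free <- rep(TRUE, nk)
  pat_free <- rep(TRUE, no)
  pairs <- list()
  for (pass in c("full", "dob", "gender")) {
    for (i in seq_len(nk)) {
      if (!kid_free[i]) next
      j <- which(pat_free & ok[[pass]][i, ])[1]
      if (!is.na(j)) {
        kid_free[i] <- FALSE
        pat_free[j] <- FALSE
        pairs[[length(pairs) + 1]] <- base::c(i, j)
      }
    }
  }
  if (sole_pair && sum(kid_free) == 1 && sum(pat_free) == 1) {
    i <- which(kid_free); j <- which(pat_free)
    kid_free[i] <- FALSE
    pat_free[j] <- FALSE
    pairs[[length(pairs) + 1]] <- base::c(i, j)
  }

  for (p in pairs) {
    i <- p[1]; j <- p[2]
    mm <- character()
    if (!g_ok[i, j]) mm <- base::c(mm, "gender")
    if (dob_na[i]) mm <- base::c(mm, "dob_missing")
    else if (!d_ok[i, j]) mm <- base::c(mm, "date_of_birth")
    add(profile_id = kids$profile_id[i], patient_id = office$patient_id[j],
        status = "matched", mismatches = mm)
  }
  for (i in which(kid_free)) {
    add(profile_id = kids$profile_id[i], status = "app_only_sibling")
  }
  for (j in which(pat_free)) {
    add(patient_id = office$patient_id[j], status = "office_only")
  }
  tibble::tibble(
    family_code = rep(fc, length(acc$status)),
    profile_id = acc$profile_id, patient_id = acc$patient_id,
    status = acc$status,
    family_in_office = rep(family_in_office, length(acc$status)),
    duplicate_of = acc$duplicate_of, mismatch_gender = acc$mg,
    mismatch_dob = acc$md, dob_missing = acc$dm)
}

#' Profile-level demographic data-quality indicators
#'
#' Computes completeness and concordance for gender and date of birth over
#' the matched profile pairs. Completeness is the share of matched
#' profiles whose app record carries the element; concordance is the share
#' of matched profiles without a recorded mismatch for the element. A
#' missing date of birth counts against completeness but is not a
#' discordance.
#'
#' @param links link tibble from [link_profiles()].
#' @param alpha confidence level complement for the Clopper-Pearson
#'   intervals.
#' @return tibble of [dqi_result()] rows at the profile level.
#' @export
demographic_dqi <- function(links, alpha = 0.05) {
  m <- dplyr::filter(links, .data$status == "matched")
  n <- nrow(m)
  if (n == 0) abort("demographic_dqi() needs at least one matched link")
  dplyr::bind_rows(
    dqi_result("completeness", "gender", n, n, level = "profile",
               alpha = alpha),
    dqi_result("completeness", "date_of_birth", n - sum(m$dob_missing), n,
               level = "profile", alpha = alpha),
    dqi_result("concordance", "gender", n - sum(m$mismatch_gender), n,
               level = "profile", alpha = alpha),
    dqi_result("concordance", "date_of_birth", n - sum(m$mismatch_dob), n,
               level = "profile", alpha = alpha))
}
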