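#' Published marginal counts of the registry validation cohort
#'
#' The count structure reported for the FeverApp registry validation
#' cohort (16-month enrollment window): family, profile, and episode
#' accounting plus the per-variable agreement counts among the comparable
#' episodes. [build_reference_cohort()] constructs a synthetic cohort
#' realizing these counts so the whole pipeline can be run against them.
#'
#' @return a named list of integer counts.
#' @export
reference_counts <- function() {
  list(
    families_registered = 684L,
    families_not_in_office = 5L,
    families_without_profiles = 3L,
    families_with_profiles = 676L,
    families_with_app_entries = 537L,
    families_with_comparable_entries = 534L,
    profiles_total = 1047L,
    profiles_unidentifiable_family = 6L,
    profiles_siblings = 22L,
    profiles_adults = 2L,
    profiles_duplicates = 5L,
    profiles_comparable = 1012L,
    demographic_gender_mismatch = 7L,
    demographic_dob_mismatch = 12L,
    demographic_dob_missing = 8L,
    children_with_app_episodes = 668L,
    app_episodes_total = 1481L,
    app_episodes_sibling = 29L,
    app_episodes_identifiable = 1452L,
    office_episodes_total = 1171L,
    office_episodes_family_without_entries = 133L,
    office_episodes_child_without_profile = 85L,
    office_episodes_with_profiles = 953L,
    office_acute = 681L,
    office_past = 272L,
    paired_episodes = 686L,
    paired_acute = 424L,
    paired_past = 262L,
    agree_visits = 423L,
    agree_antipyretics = 457L,
    agree_antibiotics = 619L,
    agree_temperature = 110L,
    agree_temperature_acute = 90L,
    agree_temperature_past = 20L)
}

int2code <- function(prefix, i) {
  # deterministic 8-letter lowercase family codes
  width <- 8 - nchar(prefix)
  digits <- integer(width)
  for (k in seq_len(width)) {
    digits[k] <- i %% 26L
    i <- i %/% 26L
  }
  paste0(prefix, paste(letters[rev(digits) + 1L], collapse = ""))
}

#' Deterministically reconstruct the validation cohort from its counts
#'
#' Builds an app export and an office export whose pipeline results
#' reproduce the published validation-cohort numbers: the family and
#' profile accounting (684 registered families, 1047 profiles reducing to
#' 1012 comparable), the demographic mismatch counts, the episode
#' reconciliation cells (1481/1452 app and 1171/953 office episodes, 686
#' paired), and the per-variable agreement counts. Where the published
#' marginal tables are mutually inconsistent (they do not all sum to the
#' cell totals), the agreement counts take precedence and the affected
#' single-source marginals are realized as closely as the totals allow.
#' Episode timing, temperatures, and identifiers are synthetic; the
#' construction is deterministic (no random number generation).
#'
#' @return list with `app` (a `fever_app_dataset`), `office`
#'   (a `fever_office_dataset`), and `counts` ([reference_counts()]).
#' @examples
#' \donttest{
#' cohort <- build_reference_cohort()
#' report <- run_pipeline(cohort$app, cohort$office)
#' report$concordance
#' }
#' @export
build_reference_cohort <- function() {
  d0 <- as.Date("2019-10-01")
  t0 <- as.POSIXct("2019-10-01 00:00:00", tz = "UTC")

  n_one_child_active <- 340L   # families 1..340, one child each
  n_two_child_active <- 194L   # families 341..534
  n_two_child_inactive <- 142L # families 535..676
  n_fam <- 676L
  fam_code <- vapply(seq_len(n_fam), function(i) int2code("fam", i),
                     character(1))
  uni_code <- vapply(1:5, function(i) int2code("uni", i), character(1))
  emp_code <- vapply(1:3, function(i) int2code("emp", i), character(1))

  fam_children <- function(f) if (f <= n_one_child_active) 1L else 2L

  # ---- children, app profiles, office patients -------------------------
  gender_err_fams <- 100:105
  dob_err_fams <- 106:116
  both_err_fam <- 117L
  dob_missing_fams <- 118:125
  dup_fams <- 25:29
  adult_fams <- 23:24
  sib_doc_fams <- c(1:12, 535:537)   # siblings that document episodes
  sib_nodoc_fams <- 13:19            # siblings without entries
  sib_fams <- c(sib_doc_fams, sib_nodoc_fams)

  profiles <- list(); patients <- list(); child_tbl <- list()
  np <- 0L; ci <- 0L
  for (f in seq_len(n_fam)) {
    fc <- fam_code[f]
    for (k in seq_len(fam_children(f))) {
      ci <- ci + 1L
      gender <- if (ci %% 2L == 1L) "female" else "male"
      bm <- (ci %% 12L) + 1L
      by <- 2010L + (ci %% 8L)
      np <- np + 1L
      pid <- sprintf("ap%05d", np)
      qid <- sprintf("op%05d", ci)
      app_gender <- gender
      office_gender <- gender
      app_bm <- bm; app_by <- by
      if (f %in% gender_err_fams || f == both_err_fam) {
        office_gender <- setdiff(c("female", "male"), gender)
      }
      if (f %in% dob_err_fams || f == both_err_fam) {
        app_bm <- bm %% 12L + 1L
      }
      if (f %in% dob_missing_fams) {
        app_bm <- NA_integer_; app_by <- NA_integer_
      }
      profiles[[length(profiles) + 1]] <- tibble::tibble(
        family_code = fc, profile_id = pid, gender = app_gender,
        birth_month = app_bm, birth_year = app_by, is_adult = FALSE,
        created_at = t0 + ci * 60)
      patients[[length(patients) + 1]] <- tibble::tibble(
        family_code = fc, patient_id = qid, gender = office_gender,
        birth_date = as.Date(sprintf("%d-%02d-15", by, bm)),
        registered_at = d0 + (ci %% 28L))
      child_tbl[[length(child_tbl) + 1]] <- tibble::tibble(
        family = f, child = ci, profile_id = pid, patient_id = qid)
      if (f %in% dup_fams && k == 1L) {
        np <- np + 1L
        profiles[[length(profiles) + 1]] <- tibble::tibble(
          family_code = fc, profile_id = sprintf("ap%05d", np),
          gender = app_gender, birth_month = app_bm, birth_year = app_by,
          is_adult = FALSE, created_at = t0 + ci * 60 + 3600)
      }
    }
    if (f %in% sib_fams) {
      np <- np + 1L
      profiles[[length(profiles) + 1]] <- tibble::tibble(
        family_code = fc, profile_id = sprintf("sb%05d", np),
        gender = if (f %% 2L == 0L) "female" else "male",
        birth_month = 3L, birth_year = 2002L, is_adult = FALSE,
        created_at = t0 + 40000 + f * 60)
    }
    if (f %in% adult_fams) {
      np <- np + 1L
      profiles[[length(profiles) + 1]] <- tibble::tibble(
        family_code = fc, profile_id = sprintf("ad%05d", np),
        gender = "female", birth_month = 5L, birth_year = 1985L,
        is_adult = TRUE, created_at = t0 + 50000)
    }
  }
  # profiles of the five families absent from the office export
  for (u in 1:5) {
    n_u <- if (u == 1) 2L else 1L
    for (k in seq_len(n_u)) {
      np <- np + 1L
      profiles[[length(profiles) + 1]] <- tibble::tibble(
        family_code = uni_code[u], profile_id = sprintf("ux%05d", np),
        gender = "male", birth_month = 3L + k, birth_year = 2012L,
        is_adult = FALSE, created_at = t0 + 60000)
    }
  }
  # 50 office patients without an app profile (episodes: 35 x 2 + 15 x 1)
  extra_pat <- lapply(1:50, function(s) {
    f <- 340L + s
    tibble::tibble(
      family_code = fam_code[f], patient_id = sprintf("ox%05d", s),
      gender = "female", birth_date = as.Date("2005-06-15"),
      registered_at = d0)
  })

  profiles <- dplyr::bind_rows(profiles)
  patients <- dplyr::bind_rows(c(patients, extra_pat))
  child_tbl <- dplyr::bind_rows(child_tbl)

  # ---- documenting children (668) --------------------------------------
  # all 340 one-child-family children; both children of families 341..474;
  # the first child of families 475..534
  doc <- child_tbl |>
    dplyr::mutate(first_of_family = !duplicated(.data$family)) |>
    dplyr::filter(
      .data$family <= 340L |
        (.data$family <= 474L) |
        (.data$family <= 534L & .data$first_of_family)) |>
    dplyr::arrange(.data$child)
  stopifnot(nrow(doc) == 668L)

  # ---- episode tokens ---------------------------------------------------
  counts <- reference_counts()
  tok <- tibble::tibble(
    type = rep(c("paired_acute", "paired_past", "app_only",
                 "office_only_acute", "office_only_past"),
               times = c(counts$paired_acute, counts$paired_past,
                         1452L - counts$paired_episodes,
                         counts$office_acute - counts$paired_acute,
                         counts$office_past - counts$paired_past)))
  tok$i <- seq_len(nrow(tok))
  tok$child_pos <- (tok$i - 1L) %% 668L + 1L
  tok$slot <- (tok$i - 1L) %/% 668L
  tok$profile_id <- doc$profile_id[tok$child_pos]
  tok$patient_id <- doc$patient_id[tok$child_pos]
  tok$base_day <- 10L + 25L * tok$slot
  tok$p <- ifelse(tok$type %in% c("paired_acute", "paired_past"), tok$i, NA)
  tok$ao <- ifelse(tok$type == "app_only", tok$i - 686L, NA)
  tok$oa <- ifelse(tok$type == "office_only_acute", tok$i - 1452L, NA)

  in_blocks <- function(p, ...) {
    blocks <- list(...)
    out <- rep(FALSE, length(p))
    for (b in blocks) out <- out | (!is.na(p) & p >= b[1] & p <= b[2])
    out
  }

  # ---- app entries ------------------------------------------------------
  app_tok <- dplyr::filter(tok, .data$type %in%
                             c("paired_acute", "paired_past", "app_only"))
  p <- app_tok$p; ao <- app_tok$ao
  temp_agree <- in_blocks(p, c(1, 90), c(425, 444))
  temp_app_missing <- in_blocks(p, c(676, 686))
  app_temp <- dplyr::case_when(
    !is.na(ao) & ao <= 740 ~ 38.9,
    !is.na(ao) ~ NA_real_,
    temp_app_missing ~ NA_real_,
    temp_agree ~ 39.0,
    TRUE ~ 39.5)
  yn <- function(x) ifelse(x, "yes", "no")
  app_visit <- yn(in_blocks(p, c(1, 279)) | in_blocks(ao, c(1, 121)))
  app_anti <- yn(in_blocks(p, c(1, 274)) | in_blocks(ao, c(1, 176)))
  app_abx <- yn(in_blocks(p, c(1, 32)) | in_blocks(ao, c(1, 14)))
  start_ts <- t0 + app_tok$base_day * 86400 + 9 * 3600
  app_entries <- tibble::tibble(
    profile_id = rep(app_tok$profile_id, each = 2),
    occurred_at = as.POSIXct(rep(start_ts, each = 2) +
                               rep(c(0, 86400), nrow(app_tok)), tz = "UTC"),
    temperature = interleave(app_temp, NA_real_),
    physician_visit = interleave(app_visit, NA_character_),
    antipyretic = interleave(app_anti, NA_character_),
    antibiotic = interleave(app_abx, NA_character_),
    healthy_marker = rep(c(FALSE, TRUE), nrow(app_tok)))

  # sibling episodes: 29 episodes over the 15 documenting siblings
  sib_profiles <- profiles |>
    dplyr::filter(grepl("^sb", .data$profile_id),
                  .data$family_code %in% fam_code[sib_doc_fams]) |>
    dplyr::arrange(.data$profile_id)
  sib_n_eps <- c(rep(2L, 14L), 1L)
  sib_rows <- lapply(seq_len(15L), function(s) {
    days <- c(400L, 430L)[seq_len(sib_n_eps[s])]
    tibble::tibble(
      profile_id = rep(sib_profiles$profile_id[s], 2L * length(days)),
      day = rep(days, each = 2) + rep(c(0L, 1L), length(days)))
  })
  sib_df <- dplyr::bind_rows(sib_rows)
  sib_entries <- tibble::tibble(
    profile_id = sib_df$profile_id,
    occurred_at = t0 + sib_df$day * 86400 + 9 * 3600,
    temperature = 38.7, physician_visit = "no", antipyretic = "no",
    antibiotic = "no",
    healthy_marker = rep(c(FALSE, TRUE), nrow(sib_df) / 2))

  entries <- dplyr::bind_rows(app_entries, sib_entries)

  # ---- office visits ----------------------------------------------------
  off_tok <- dplyr::filter(tok, .data$type != "app_only")
  p <- off_tok$p; oa <- off_tok$oa
  kind <- dplyr::case_when(
    off_tok$type %in% c("paired_acute", "office_only_acute") ~ "acute",
    TRUE ~ "past")
  vd <- dplyr::case_when(
    off_tok$type == "paired_acute" ~ off_tok$base_day,
    off_tok$type == "paired_past" ~ off_tok$base_day + 12L,
    off_tok$type == "office_only_acute" ~ off_tok$base_day,
    TRUE ~ 2L)
  temp_agree <- in_blocks(p, c(1, 90), c(425, 444))
  office_temp <- dplyr::case_when(
    !is.na(oa) ~ 39.0,
    off_tok$type == "office_only_past" ~ 38.5,
    in_blocks(p, c(566, 675)) ~ NA_real_,
    temp_agree | in_blocks(p, c(676, 686)) ~ 39.0,
    TRUE ~ 39.1)
  office_visit <- dplyr::case_when(
    !is.na(oa) ~ "yes",
    off_tok$type == "office_only_past" ~ "no",
    in_blocks(p, c(1, 245), c(280, 508)) ~ "yes",
    TRUE ~ "no")
  office_anti <- dplyr::case_when(
    in_blocks(oa, c(1, 129)) ~ "yes",
    !is.na(oa) ~ "no",
    off_tok$type == "office_only_past" ~ "no",
    in_blocks(p, c(1, 234), c(275, 463)) ~ "yes",
    TRUE ~ "no")
  office_abx <- dplyr::case_when(
    in_blocks(oa, c(1, 29)) ~ "yes",
    !is.na(oa) ~ "no",
    off_tok$type == "office_only_past" ~ "no",
    in_blocks(p, c(1, 13), c(33, 80)) ~ "yes",
    TRUE ~ "no")
  visits <- tibble::tibble(
    patient_id = off_tok$patient_id, visit_date = d0 + vd, kind = kind,
    max_temperature = office_temp, physician_visit = office_visit,
    antipyretic = office_anti, antibiotic = office_abx)

  # 133 office episodes from families whose app has no entries at all
  inactive_fams <- 538:670
  inactive_children <- child_tbl |>
    dplyr::filter(.data$family %in% inactive_fams) |>
    dplyr::group_by(.data$family) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  visits_inactive <- tibble::tibble(
    patient_id = inactive_children$patient_id, visit_date = d0 + 20L,
    kind = "acute", max_temperature = 39.3, physician_visit = "yes",
    antipyretic = "no", antibiotic = "no")

  # 85 office episodes from the 50 patients without app profiles
  nox <- c(rep(2L, 35L), rep(1L, 15L))
  visits_extra <- tibble::tibble(
    patient_id = rep(sprintf("ox%05d", 1:50), times = nox),
    visit_date = d0 + unlist(lapply(nox, function(n) c(450L, 475L)[seq_len(n)])),
    kind = "acute", max_temperature = 39.2, physician_visit = "yes",
    antipyretic = "no", antibiotic = "no")

  visits <- dplyr::bind_rows(visits, visits_inactive, visits_extra)

  families <- tibble::tibble(family_code = c(fam_code, uni_code, emp_code))
  list(
    app = app_dataset(profiles, entries, families = families),
    office = office_dataset(patients, visits),
    counts = counts)
}

interleave <- function(a, filler) {
  out <- rep(filler, 2 * length(a))
  out[seq(1, length(out), by = 2)] <- a
  out
}
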