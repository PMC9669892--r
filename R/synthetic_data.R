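#' Configuration of the synthetic two-source cohort generator
#'
#' The generator emulates the study conditions of the registry validation
#' cohort: families register the app through a pediatric office, children
#' experience fever episodes over a 16-month observation window, parents
#' record a subset of the episodes as diary-entry clusters, and the office
#' records a subset as acute visits or retrospective ("past") reports.
#' Defaults are calibrated analytically from the validation cohort's
#' published marginal counts (see the methods vignette): for example the
#' per-episode app recording probability equals the observed app coverage
#' of acute office episodes, and the two past-report probabilities
#' reproduce the observed asymmetry in app coverage between past and
#' acute office episodes.
#'
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @param n_families number of families that register the app.
#' @param children_per_family named numeric vector of probabilities for
#'   1, 2, ... children.
#' @param observation_days length of the observation window (days).
#' @param episode_rate true fever episodes per child-year.
#' @param p_family_active probability that a family ever uses the diary;
#'   inactive families install the app but record no entries.
#' @param p_family_not_in_office probability that a family cannot be
#'   identified in the office export (processing errors).
#' @param p_family_no_profiles probability that a family installs the app
#'   but never creates a child profile.
#' @param p_app_record probability that an active family records a given
#'   true episode in the diary (as a cluster of 2-6 entries with gaps
#'   under 48 h).
#' @param p_office_visit_acute probability of an acute office visit during
#'   a true episode.
#' @param p_office_report_past,p_office_report_past_unrecorded probability
#'   that a non-acute episode is reported retrospectively at a later
#'   visit, for app-recorded and unrecorded episodes respectively
#'   (parents who track fever in the app recall past episodes better).
#' @param p_visit_nonacute probability that a physician visit (anywhere)
#'   truly occurred during a non-acute episode.
#' @param p_true_antipyretic,p_true_antibiotic prevalence of medication
#'   use per episode.
#' @param p_submit named list per variable of `c(app = , office = )`
#'   submission probabilities given the element is truly positive (flags)
#'   or present (temperature); missing submissions are coerced to "no"
#'   downstream.
#' @param true_temp list `mean`, `sd`, `min`, `max` of the truncated
#'   normal generating the true maximum temperature (degrees Celsius,
#'   rounded to the 0.1 degree grid).
#' @param app_temp_noise_sd standard deviation of the parental measurement
#'   noise (degrees Celsius).
#' @param office_past_recall_bias downward recall bias of the office value
#'   for past episodes; positive values make the app read higher than the
#'   office for past episodes.
#' @param p_gender_error,p_dob_error,p_dob_missing per-profile demographic
#'   error/missingness probabilities in the app.
#' @param p_duplicate_profile probability that a child profile is
#'   duplicated by a second caregiver before synchronization.
#' @param p_sibling_not_patient probability that a family adds a child who
#'   is not a patient of the office.
#' @param p_adult_profile probability that a family adds an adult profile.
#' @return a validated list of class `generator_config`.
#' @seealso [generate_cohort()], [expected_dqi()]
#' @export
generator_config <- function(seed = 1,
                             n_families = 684,
                             children_per_family = c(`1` = 0.55, `2` = 0.40,
                                                     `3` = 0.05),
                             observation_days = 487,
                             episode_rate = 2.05,
                             p_family_active = 0.84,
                             p_family_not_in_office = 0.007,
                             p_family_no_profiles = 0.004,
                             p_app_record = 0.62,
                             p_office_visit_acute = 0.29,
                             p_office_report_past = 0.255,
                             p_office_report_past_unrecorded = 0.016,
                             p_visit_nonacute = 0.2,
                             p_true_antipyretic = 0.55,
                             p_true_antibiotic = 0.09,
                             p_submit = list(
                               physician_visit = c(app = 0.55, office = 0.95),
                               antipyretic = c(app = 0.73, office = 1),
                               antibiotic = c(app = 0.52, office = 1),
                               max_temperature = c(app = 0.975, office = 0.84)),
                             true_temp = list(mean = 39.2, sd = 0.6,
                                              min = 38.0, max = 42.4),
                             app_temp_noise_sd = 0.3,
                             office_past_recall_bias = 0.4,
                             p_gender_error = 0.0069,
                             p_dob_error = 0.0119,
                             p_dob_missing = 0.0079,
                             p_duplicate_profile = 0.005,
                             p_sibling_not_patient = 0.03,
                             p_adult_profile = 0.003) {
  cfg <- as.list(environment())
  probs <- cfg[grep("^p_", names(cfg))]
  flat <- unlist(probs)
  if (any(is.na(flat)) || any(flat < 0) || any(flat > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(children_per_family) - 1) > 1e-8) {
    abort("children_per_family probabilities must sum to 1")
  }
  stopifnot(n_families >= 1, observation_days > 0, episode_rate >= 0)
  structure(cfg, class = "generator_config")
}

rand_family_code <- function(n) {
  # unique 8-character lowercase pseudonyms
  out <- character(0)
  while (length(out) < n) {
    more <- replicate(n - length(out) + 8L,
                      paste(sample(letters, 8, replace = TRUE), collapse = ""))
    out <- unique(c(out, more))
  }
  out[seq_len(n)]
}

rtrunc_norm_grid <- function(n, mean, sd, min, max) {
  u <- runif(n, pnorm((min - mean) / sd), pnorm((max - mean) / sd))
  round(mean + sd * stats::qnorm(u), 1)
}

#' Generate a paired app/office cohort with known ground truth
#'
#' Draws a cohort under [generator_config()]: shared true fever episodes
#' per child, per-source recording with the configured probabilities,
#' temperature measurement and recall noise, demographic errors, duplicate
#' profiles, non-patient siblings, and adult profiles. Every app-recorded
#' episode is written as a cluster of 2-6 diary entries whose internal
#' gaps are below 48 hours, while distinct episodes are separated by more
#' than 48 hours, so segmentation recovers the generated episodes
#' exactly.
#'
#' @param config a [generator_config()].
#' @return list with elements `app` (a `fever_app_dataset`), `office`
#'   (a `fever_office_dataset`), and `truth`: a list carrying the true
#'   child-to-profile/patient links (`links`) and the per-episode record
#'   (`episodes`) with recording status, true values, and the episode
#'   indices under which each source's pipeline output will carry the
#'   episode.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 7, n_families = 20))
#' cohort$app
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  t0 <- as.POSIXct("2019-09-01 00:00:00", tz = "UTC")
  d0 <- as.Date(t0)

  fam <- tibble::tibble(
    family_code = rand_family_code(config$n_families),
    in_office = runif(config$n_families) >= config$p_family_not_in_office,
    has_profiles = runif(config$n_families) >= config$p_family_no_profiles,
    active = runif(config$n_families) < config$p_family_active)

  profiles <- list(); patients <- list(); entries <- list()
  visits <- list(); truth_eps <- list(); truth_links <- list()
  np <- 0L; nq <- 0L; nc <- 0L

  for (f in seq_len(config$n_families)) {
    fc <- fam$family_code[f]
    if (!fam$has_profiles[f]) next
    n_kids <- as.integer(sample(names(config$children_per_family), 1,
                                prob = config$children_per_family))
    n_sib <- rbinom(1, 1, config$p_sibling_not_patient)
    n_adult <- rbinom(1, 1, config$p_adult_profile)

    used_keys <- character()
    for (k in seq_len(n_kids + n_sib)) {
      is_sibling <- k > n_kids
      nc <- nc + 1L
      child_id <- sprintf("ch%05d", nc)
      # children of one family carry distinct (gender, month/year) keys:
      # the linkage key cannot distinguish same-sex twins, so the ground
      # truth keeps them identifiable
      repeat {
        true_gender <- sample(c("female", "male"), 1)
        birth_date <- d0 - round(runif(1, 90, 16 * 365.25))
        key <- paste(true_gender, format(birth_date, "%Y-%m"))
        if (!key %in% used_keys) break
      }
      used_keys <- base::c(used_keys, key)
      np <- np + 1L
      profile_id <- sprintf("ap%05d", np)

      # app demographics with error model
      app_gender <- true_gender
      if (runif(1) < config$p_gender_error) {
        app_gender <- setdiff(c("female", "male"), true_gender)
      }
      bm <- as.integer(format(birth_date, "%m"))
      by <- as.integer(format(birth_date, "%Y"))
      if (runif(1) < config$p_dob_missing) {
        bm <- by <- NA_integer_
      } else if (runif(1) < config$p_dob_error) {
        bm <- bm %% 12L + 1L
        if (bm == 1L) by <- by + 1L
      }
      created <- t0 + round(runif(1, 0, 30) * 1440) * 60
      profiles[[length(profiles) + 1]] <- tibble::tibble(
        family_code = fc, profile_id = profile_id, gender = app_gender,
        birth_month = bm, birth_year = by, is_adult = FALSE,
        created_at = created)

      patient_id <- NA_character_
      if (!is_sibling && fam$in_office[f]) {
        nq <- nq + 1L
        patient_id <- sprintf("op%05d", nq)
        patients[[length(patients) + 1]] <- tibble::tibble(
          family_code = fc, patient_id = patient_id, gender = true_gender,
          birth_date = birth_date, registered_at = d0 + nq %% 30)
      }
      truth_links[[length(truth_links) + 1]] <- tibble::tibble(
        family_code = fc, child_id = child_id, profile_id = profile_id,
        patient_id = patient_id, is_sibling = is_sibling)

      if (runif(1) < config$p_duplicate_profile) {
        np <- np + 1L
        profiles[[length(profiles) + 1]] <- tibble::tibble(
          family_code = fc, profile_id = sprintf("ap%05d", np),
          gender = app_gender, birth_month = bm, birth_year = by,
          is_adult = FALSE, created_at = created + 3600)
      }

      eps <- draw_child_episodes(config, t0, fam$active[f], is_sibling,
                                 child_id, profile_id, patient_id, fc)
      if (!is.null(eps$entries)) entries[[length(entries) + 1]] <- eps$entries
      if (!is.null(eps$visits)) visits[[length(visits) + 1]] <- eps$visits
      if (!is.null(eps$truth)) truth_eps[[length(truth_eps) + 1]] <- eps$truth
    }

    if (n_adult > 0) {
      np <- np + 1L
      profiles[[length(profiles) + 1]] <- tibble::tibble(
        family_code = fc, profile_id = sprintf("ap%05d", np),
        gender = sample(c("female", "male"), 1),
        birth_month = sample(12, 1),
        birth_year = sample(1975:1995, 1), is_adult = TRUE,
        created_at = t0 + round(runif(1, 0, 30) * 1440) * 60)
    }
  }

  profiles <- dplyr::bind_rows(profiles)
  entries <- dplyr::bind_rows(entries)
  if (nrow(entries) == 0) entries <- empty_entries_tbl()
  patients <- dplyr::bind_rows(patients)
  visits <- dplyr::bind_rows(visits)
  if (nrow(visits) == 0) visits <- empty_visits_tbl()
  truth <- dplyr::bind_rows(truth_eps)

  # episode indices as each source's pipeline will number them
  if (nrow(truth) > 0) {
    truth <- truth |>
      dplyr::group_by(.data$profile_id) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::mutate(app_episode = ifelse(.data$app_recorded,
                                         cumsum(.data$app_recorded),
                                         NA_integer_)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::arrange(.data$visit_date, .by_group = TRUE) |>
      dplyr::mutate(office_episode = ifelse(.data$office_recorded,
                                            cumsum(.data$office_recorded),
                                            NA_integer_)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$child_id, .data$start)
  }

  list(
    app = app_dataset(profiles, entries,
                      families = tibble::tibble(family_code = fam$family_code)),
    office = office_dataset(patients, visits),
    truth = list(links = dplyr::bind_rows(truth_links), episodes = truth,
                 config = config))
}

empty_entries_tbl <- function() {
  tibble::tibble(profile_id = character(),
                 occurred_at = as.POSIXct(character(), tz = "UTC"),
                 temperature = double(), physician_visit = character(),
                 antipyretic = character(), antibiotic = character(),
                 healthy_marker = logical())
}

empty_visits_tbl <- function() {
  tibble::tibble(patient_id = character(),
                 visit_date = as.Date(character()), kind = character(),
                 max_temperature = double(), physician_visit = character(),
                 antipyretic = character(), antibiotic = character())
}

draw_child_episodes <- function(config, t0, family_active, is_sibling,
                                child_id, profile_id, patient_id, fc) {
  years <- config$observation_days / 365.25
  n_ep <- rpois(1, config$episode_rate * years)
  if (n_ep == 0) return(list())
  ent <- list(); vis <- list(); tr <- list()
  # uniform starts over the window, then at least 3 days between the end of
  # one episode and the start of the next (keeps episodes > 48 h apart, so
  # the segmentation rule can recover them)
  starts <- sort(runif(n_ep, 0, config$observation_days)) * 86400
  prev_end <- -Inf
  for (e in seq_len(n_ep)) {
    cursor <- max(starts[e], prev_end + 3 * 86400)
    if (cursor > config$observation_days * 86400) break
    n_entry <- sample(2:6, 1)
    gaps <- runif(n_entry - 1, 6, 40) * 3600
    # diary timestamps at minute resolution
    times <- t0 + round((cursor + base::c(0, cumsum(gaps))) / 60) * 60
    ep_start <- times[1]; ep_end <- times[n_entry]
    prev_end <- cursor + sum(gaps)

    temp_true <- rtrunc_norm_grid(1, config$true_temp$mean,
                                  config$true_temp$sd, config$true_temp$min,
                                  config$true_temp$max)
    anti_true <- runif(1) < config$p_true_antipyretic
    abx_true <- runif(1) < config$p_true_antibiotic

    app_rec <- family_active && runif(1) < config$p_app_record
    acute <- !is_sibling && !is.na(patient_id) &&
      runif(1) < config$p_office_visit_acute
    visit_true <- acute || runif(1) < config$p_visit_nonacute
    office_rec <- acute
    kind <- NA_character_
    visit_date <- as.Date(NA)
    if (acute) {
      kind <- "acute"
      visit_date <- as.Date(ep_start) +
        sample(0:max(0, as.integer(as.Date(ep_end) - as.Date(ep_start))), 1)
    } else if (!is_sibling && !is.na(patient_id)) {
      p_past <- if (app_rec) config$p_office_report_past else
        config$p_office_report_past_unrecorded
      if (runif(1) < p_past) {
        office_rec <- TRUE
        kind <- "past"
        visit_date <- as.Date(ep_end) + round(runif(1, 3, 10))
      }
    }

    if (app_rec) {
      sub <- function(v) runif(1) < config$p_submit[[v]]["app"]
      app_temp <- if (sub("max_temperature")) {
        round(temp_true + rnorm(1, 0, config$app_temp_noise_sd), 1)
      } else NA_real_
      flag <- function(truth, v) {
        if (truth && sub(v)) "yes" else if (!truth) "no" else NA_character_
      }
      ent[[length(ent) + 1]] <- tibble::tibble(
        profile_id = profile_id, occurred_at = times,
        temperature = c(app_temp, rep(NA_real_, n_entry - 1)),
        physician_visit = c(flag(visit_true, "physician_visit"),
                            rep(NA_character_, n_entry - 1)),
        antipyretic = c(flag(anti_true, "antipyretic"),
                        rep(NA_character_, n_entry - 1)),
        antibiotic = c(flag(abx_true, "antibiotic"),
                       rep(NA_character_, n_entry - 1)),
        healthy_marker = c(rep(FALSE, n_entry - 1), TRUE))
    }
    if (office_rec) {
      sub_o <- function(v) runif(1) < config$p_submit[[v]]["office"]
      office_temp <- if (sub_o("max_temperature")) {
        if (kind == "acute") temp_true else
          round(temp_true - config$office_past_recall_bias, 1)
      } else NA_real_
      flag_o <- function(truth, v) {
        if (truth && sub_o(v)) "yes" else if (!truth) "no" else NA_character_
      }
      vis[[length(vis) + 1]] <- tibble::tibble(
        patient_id = patient_id, visit_date = visit_date, kind = kind,
        max_temperature = office_temp,
        physician_visit = flag_o(visit_true, "physician_visit"),
        antipyretic = flag_o(anti_true, "antipyretic"),
        antibiotic = flag_o(abx_true, "antibiotic"))
    }
    tr[[length(tr) + 1]] <- tibble::tibble(
      family_code = fc, child_id = child_id, profile_id = profile_id,
      patient_id = patient_id, episode_index = e, start = ep_start,
      end = ep_end, app_recorded = app_rec, office_recorded = office_rec,
      office_kind = kind, visit_date = visit_date,
      true_temperature = temp_true, true_visit = visit_true,
      true_antipyretic = anti_true, true_antibiotic = abx_true)
  }
  list(entries = if (length(ent)) dplyr::bind_rows(ent),
       visits = if (length(vis)) dplyr::bind_rows(vis),
       truth = if (length(tr)) dplyr::bind_rows(tr))
}

#' Analytic expectations for the generator's data-quality indicators
#'
#' Closed-form expected concordance implied by a [generator_config()],
#' derived from the submission/coercion algebra: for a binary element with
#' true prevalence `pi` among paired episodes and submission probabilities
#' `q_app`, `q_office` given a true positive (negatives and
#' non-submissions both read "no" after coercion), the expected
#' concordance is `pi (q_app q_office + (1 - q_app)(1 - q_office)) +
#' (1 - pi)`. Temperature agreement multiplies the joint submission
#' probability by the probability that parental measurement noise, after
#' rounding to the 0.1 degree grid, lands on the office value (shifted by
#' the recall bias for past episodes); temperature-grid truncation at the
#' range bounds is ignored.
#'
#' @param config a [generator_config()].
#' @return tibble with columns `variable` and `expected` (concordance
#'   proportion), covering the four episode elements and the two
#'   demographic elements.
#' @export
expected_dqi <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  p_acute <- config$p_office_visit_acute
  p_past <- config$p_office_report_past
  p_off_given_app <- p_acute + (1 - p_acute) * p_past
  pi_acute <- p_acute / p_off_given_app

  conc_bin <- function(pi, q) {
    qa <- q[["app"]]; qo <- q[["office"]]
    pi * (qa * qo + (1 - qa) * (1 - qo)) + (1 - pi)
  }
  pi_visit <- pi_acute + (1 - pi_acute) * config$p_visit_nonacute

  grid_hit <- function(center_shift, sd) {
    pnorm((center_shift + 0.05) / sd) - pnorm((center_shift - 0.05) / sd)
  }
  delta_past <- round(-config$office_past_recall_bias, 1)
  q_t <- config$p_submit$max_temperature
  e_temp <- q_t[["app"]] * q_t[["office"]] *
    (pi_acute * grid_hit(0, config$app_temp_noise_sd) +
       (1 - pi_acute) * grid_hit(delta_past, config$app_temp_noise_sd))

  tibble::tibble(
    variable = c("physician_visit", "antipyretic", "antibiotic",
                 "max_temperature", "gender", "date_of_birth"),
    expected = c(
      conc_bin(pi_visit, config$p_submit$physician_visit),
      conc_bin(config$p_true_antipyretic, config$p_submit$antipyretic),
      conc_bin(config$p_true_antibiotic, config$p_submit$antibiotic),
      e_temp,
      1 - config$p_gender_error,
      1 - config$p_dob_error))
}
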