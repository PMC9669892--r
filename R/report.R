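#' Run the full data-quality pipeline
#'
#' Orchestrates validation, duplicate collapsing, segmentation, profile
#' linkage, episode matching, and indicator computation for a paired
#' app/office cohort, and assembles the analysis report: observation-unit
#' accounting at the family, profile, and episode levels; demographic
#' indicators; the per-variable agreement table; completeness and
#' concordance tables with exact confidence intervals; the episode
#' reconciliation (Venn) cells; the acute-versus-past temperature
#' agreement chi-square; temperature-difference summaries with the
#' Mann-Whitney comparison; and duration-of-use statistics.
#'
#' @param app a `fever_app_dataset`.
#' @param office a `fever_office_dataset`.
#' @param gap_hours episode segmentation gap (see [segmentation_config()]).
#' @param acute_window_days,past_window_days episode pairing windows (see
#'   [match_episodes()]).
#' @param temp_tolerance temperature agreement tolerance (degrees Celsius).
#' @param threshold data-quality threshold for the pass/fail flags.
#' @param strict passed to [link_profiles()].
#' @return a list of class `fever_dqi_report`. The element `data` holds
#'   the intermediate tables (episodes, links, matches) and is excluded
#'   from JSON serialization.
#' @export
run_pipeline <- function(app, office, gap_hours = 48, acute_window_days = 7,
                         past_window_days = 60, temp_tolerance = 0.05,
                         threshold = 0.95, strict = FALSE) {
  stopifnot(inherits(app, "fever_app_dataset"),
            inherits(office, "fever_office_dataset"))
  issues <- dplyr::bind_rows(validate_dataset(app), validate_dataset(office))
  if (nrow(issues) > 0) {
    warn(sprintf("%d validation issue(s); see report$validation", nrow(issues)))
  }

  # collapse synonymous duplicates: reassign their entries to the canonical
  # profile before segmentation
  links <- link_profiles(app$profiles, office$patients, strict = strict)
  dup_map <- links |>
    dplyr::filter(.data$status == "synonymous_duplicate") |>
    dplyr::select("profile_id", "duplicate_of")
  entries <- app$entries
  if (nrow(dup_map) > 0) {
    idx <- match(entries$profile_id, dup_map$profile_id)
    entries$profile_id <- ifelse(is.na(idx), entries$profile_id,
                                 dup_map$duplicate_of[idx])
  }

  app_eps <- segment_profiles(entries, segmentation_config(gap_hours))
  office_eps <- office_episodes(office)
  matches <- match_cohort_episodes(app_eps, office_eps, links,
                                   acute_window_days, past_window_days,
                                   temp_tolerance)
  venn <- venn_partition(matches, links, app_eps, office_eps,
                         registered_families = app$families$family_code)

  prof_fam <- dplyr::distinct(app$profiles, .data$profile_id,
                              .data$family_code)
  office_fams <- unique(office$patients$family_code)
  profile_fams <- unique(app$profiles$family_code)
  active_fams <- unique(
    prof_fam$family_code[match(unique(app_eps$profile_id),
                               prof_fam$profile_id)])
  matched_links <- dplyr::filter(links, .data$status == "matched")
  comparable_eps <- dplyr::semi_join(
    app_eps, matched_links,
    by = "profile_id") |>
    dplyr::filter(.data$profile_id %in%
                    prof_fam$profile_id[prof_fam$family_code %in% office_fams])

  accounting <- list(
    families_registered = nrow(app$families),
    families_with_profiles = length(profile_fams),
    families_without_profiles = nrow(app$families) - length(profile_fams),
    families_not_in_office = sum(!profile_fams %in% office_fams),
    families_comparable = sum(unique(profile_fams) %in% office_fams),
    families_with_app_entries = length(active_fams),
    families_with_comparable_entries = length(unique(
      prof_fam$family_code[prof_fam$profile_id %in%
                             unique(comparable_eps$profile_id)])),
    profiles_total = nrow(app$profiles),
    profiles_unidentifiable_family =
      sum(!app$profiles$family_code %in% office_fams),
    profiles_siblings = sum(links$status == "app_only_sibling" &
                              links$family_in_office, na.rm = TRUE),
    profiles_adults = sum(links$status == "app_only_adult" &
                            links$family_in_office, na.rm = TRUE),
    profiles_duplicates = sum(links$status == "synonymous_duplicate"),
    profiles_comparable = nrow(matched_links),
    children_with_app_episodes = length(unique(comparable_eps$profile_id)),
    patients_office_only = sum(links$status == "office_only"))

  demo_counts <- list(
    gender_mismatch = sum(matched_links$mismatch_gender),
    dob_mismatch = sum(matched_links$mismatch_dob),
    dob_missing = sum(matched_links$dob_missing))
  demographics <- demographic_dqi(links)

  paired <- matches |>
    dplyr::filter(.data$match_type == "paired") |>
    dplyr::left_join(
      dplyr::select(app_eps, "profile_id", app_episode = "episode",
                    app_visit = "physician_visit",
                    app_antipyretic = "antipyretic",
                    app_antibiotic = "antibiotic",
                    app_temperature = "max_temperature"),
      by = c("profile_id", "app_episode")) |>
    dplyr::left_join(
      dplyr::select(office_eps, "patient_id", office_episode = "episode",
                    office_visit = "physician_visit",
                    office_antipyretic = "antipyretic",
                    office_antibiotic = "antibiotic",
                    office_temperature = "max_temperature"),
      by = c("patient_id", "office_episode"))

  agreement <- agreement_table(paired)
  n_paired <- nrow(paired)
  n_office <- venn$office_children_with_profiles
  n_app <- venn$app_identifiable

  vars <- c("physician_visit", "antipyretic", "antibiotic",
            "max_temperature")
  agree_k <- setNames(agreement$agree, agreement$variable)[vars]
  concordance <- if (n_paired > 0) {
    dplyr::bind_rows(lapply(vars, function(v) {
      concordance_rate(agree_k[[v]], n_paired, variable = v)
    }))
  } else tibble::tibble()
  completeness <- if (n_paired > 0 && n_office > 0 && n_app > 0) {
    dplyr::bind_rows(
      dplyr::bind_rows(lapply(vars, function(v) {
        completeness_rate(agree_k[[v]], n_office, variable = v)
      })) |> dplyr::mutate(denominator_source = "office"),
      dplyr::bind_rows(lapply(vars, function(v) {
        completeness_rate(agree_k[[v]], n_app, variable = v)
      })) |> dplyr::mutate(denominator_source = "app"))
  } else tibble::tibble()

  acute_past <- acute_past_chisq(paired)
  tempdiff <- temperature_difference_summary(paired)
  coverage <- list(
    acute = venn$office_paired_acute, acute_total = venn$office_acute,
    past = venn$office_paired_past, past_total = venn$office_past)

  diffs_family <- episode_count_difference(app_eps, office_eps, links,
                                           by = "family")
  diffs_profile <- episode_count_difference(app_eps, office_eps, links,
                                            by = "profile")
  duration <- duration_of_use(entries, app$profiles)

  dqis <- dplyr::bind_rows(demographics, concordance,
                           if (nrow(completeness)) {
                             dplyr::select(completeness,
                                           -"denominator_source")
                           })
  thresholds <- if (nrow(dqis)) {
    dplyr::mutate(dqis, threshold = threshold,
                  pass = .data$rate >= threshold)
  } else tibble::tibble()

  structure(list(
    parameters = list(gap_hours = gap_hours,
                      acute_window_days = acute_window_days,
                      past_window_days = past_window_days,
                      temp_tolerance = temp_tolerance,
                      threshold = threshold),
    validation = issues,
    accounting = accounting,
    demographic_counts = demo_counts,
    demographics = demographics,
    venn = venn,
    agreement = agreement,
    coverage = coverage,
    completeness = completeness,
    concordance = concordance,
    acute_past_temperature = acute_past,
    temperature_differences = tempdiff,
    episode_differences = list(
      by_family = summarize_differences(diffs_family),
      by_profile = summarize_differences(diffs_profile)),
    duration_of_use = duration,
    thresholds = thresholds,
    healthy_overrun = attr(app_eps, "healthy_overrun") %||% 0,
    data = list(links = links, app_episodes = app_eps,
                office_episodes = office_eps, matches = matches,
                paired = paired,
                episode_differences_family = diffs_family,
                episode_differences_profile = diffs_profile)),
    class = "fever_dqi_report")
}

agreement_table <- function(paired) {
  if (nrow(paired) == 0) {
    return(tibble::tibble(variable = character(), agree_yes = integer(),
                          agree_no = integer(), disagree = integer(),
                          not_comparable = integer(), agree = integer()))
  }
  bin_row <- function(v, a, o) {
    tibble::tibble(
      variable = v,
      agree_yes = sum(a & o), agree_no = sum(!a & !o),
      disagree = sum(a != o), not_comparable = 0L,
      agree = sum(a == o))
  }
  temp_row <- tibble::tibble(
    variable = "max_temperature",
    agree_yes = NA_integer_, agree_no = NA_integer_,
    disagree = sum(paired$agree_max_temperature == "disagree"),
    not_comparable = sum(paired$agree_max_temperature == "not_comparable"),
    agree = sum(paired$agree_max_temperature == "agree"))
  dplyr::bind_rows(
    bin_row("physician_visit", paired$app_visit, paired$office_visit),
    bin_row("antipyretic", paired$app_antipyretic, paired$office_antipyretic),
    bin_row("antibiotic", paired$app_antibiotic, paired$office_antibiotic),
    temp_row)
}

acute_past_chisq <- function(paired) {
  acute <- dplyr::filter(paired, .data$office_kind == "acute")
  past <- dplyr::filter(paired, .data$office_kind == "past")
  a <- sum(acute$agree_max_temperature == "agree")
  b <- nrow(acute) - a
  c_ <- sum(past$agree_max_temperature == "agree")
  d <- nrow(past) - c_
  res <- tryCatch(chi_square_yates(a, b, c_, d), error = function(e) NULL)
  list(table = c(acute_agree = a, acute_other = b,
                 past_agree = c_, past_other = d),
       statistic = res$statistic, df = res$df, p_value = res$p_value)
}

temperature_difference_summary <- function(paired) {
  both <- dplyr::filter(paired, !is.na(.data$temp_difference))
  acute <- both$temp_difference[both$office_kind == "acute"]
  past <- both$temp_difference[both$office_kind == "past"]
  mw <- if (length(acute) > 0 && length(past) > 0 &&
              (length(unique(c(acute, past))) > 1)) {
    mann_whitney(acute, past, exact = FALSE)
  } else NULL
  list(
    n_acute = length(acute), n_past = length(past),
    acute = if (length(acute)) as.list(median_iqr(acute)),
    past = if (length(past)) as.list(median_iqr(past)),
    mann_whitney = mw)
}

summarize_differences <- function(diffs) {
  if (nrow(diffs) == 0) return(list(n = 0L))
  list(n = nrow(diffs),
       equal = sum(diffs$difference == 0),
       app_higher = sum(diffs$difference > 0),
       office_higher = sum(diffs$difference < 0),
       summary = as.list(median_iqr(diffs$difference)))
}

duration_of_use <- function(entries, profiles) {
  if (nrow(entries) == 0) return(list(n_families = 0L))
  span <- entries |>
    dplyr::left_join(dplyr::distinct(profiles, .data$profile_id,
                                     .data$family_code),
                     by = "profile_id") |>
    dplyr::group_by(.data$family_code) |>
    dplyr::summarise(days = as.numeric(difftime(max(.data$occurred_at),
                                                min(.data$occurred_at),
                                                units = "days")),
                     .groups = "drop")
  list(n_families = nrow(span), summary = as.list(median_iqr(span$days)))
}

#' @export
print.fever_dqi_report <- function(x, ...) {
  a <- x$accounting
  cat("Registry data-quality report\n")
  cat(sprintf("  families: %d registered, %d with profiles, %d comparable\n",
              a$families_registered, a$families_with_profiles,
              a$families_comparable))
  cat(sprintf("  profiles: %d total, %d comparable (%d siblings, %d adults, %d duplicates excluded)\n",
              a$profiles_total, a$profiles_comparable, a$profiles_siblings,
              a$profiles_adults, a$profiles_duplicates))
  cat(sprintf("  episodes: %d app (identifiable), %d office (children with profiles), %d paired\n",
              x$venn$app_identifiable, x$venn$office_children_with_profiles,
              x$venn$office_paired))
  if (nrow(x$concordance) > 0) {
    cat("  concordance:\n")
    for (i in seq_len(nrow(x$concordance))) {
      cat(sprintf("    %-16s %s\n", x$concordance$variable[i],
                  format_dqi(x$concordance[i, ])))
    }
  }
  invisible(x)
}

#' Format and parse report cells
#'
#' `format_dqi()` renders a [dqi_result()] in the report's cell style,
#' `"423/953 (44.4; 41.2-47.6)"`: numerator/denominator, percentage, and
#' the exact 95% interval. `parse_dqi_cell()` inverts it.
#'
#' @param dqi a one-row [dqi_result()].
#' @param digits decimals for the percentages (1 by default, 2 where more
#'   precision is wanted).
#' @return `format_dqi()`: character scalar; `parse_dqi_cell()`: one-row
#'   tibble with `k`, `n`, `rate_pct`, `ci_low_pct`, `ci_high_pct`.
#' @export
format_dqi <- function(dqi, digits = 1) {
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  sprintf("%d/%d (%s; %s-%s)", dqi$k, dqi$n, fmt(100 * dqi$rate),
          fmt(100 * dqi$ci_low), fmt(100 * dqi$ci_high))
}

#' @rdname format_dqi
#' @param cell character scalar produced by `format_dqi()`.
#' @export
parse_dqi_cell <- function(cell) {
  m <- regmatches(cell, regexec(
    "^(\\d+)/(\\d+) \\(([-0-9.]+); ([-0-9.]+)-([-0-9.]+)\\)$", cell))[[1]]
  if (length(m) != 6) abort(sprintf("cannot parse cell '%s'", cell))
  tibble::tibble(k = as.integer(m[2]), n = as.integer(m[3]),
                 rate_pct = as.numeric(m[4]), ci_low_pct = as.numeric(m[5]),
                 ci_high_pct = as.numeric(m[6]))
}

#' Render the report's indicator tables
#'
#' Produces the formatted completeness, concordance, and demographic
#' tables with one `k/n (rate; low-high)` cell per indicator. An empty
#' report yields the headers (zero rows) only.
#'
#' @param report a `fever_dqi_report`.
#' @param digits decimals for the percentages.
#' @return tibble with columns `table`, `indicator`, `variable`, `level`,
#'   `cell`.
#' @export
render_tables <- function(report, digits = 1) {
  blocks <- list(
    demographics = report$demographics,
    completeness = report$completeness,
    concordance = report$concordance)
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (is.null(b) || nrow(b) == 0) return(NULL)
    tibble::tibble(
      table = nm, indicator = b$indicator, variable = b$variable,
      level = b$level,
      cell = vapply(seq_len(nrow(b)),
                    function(i) format_dqi(b[i, ], digits = digits),
                    character(1)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(table = character(), indicator = character(),
                          variable = character(), level = character(),
                          cell = character())
  }
  out
}

#' Serialize a report to JSON
#'
#' Writes every report component except the raw intermediate tables
#' (`data`) as JSON with stable element ordering and no timestamps, so
#' two runs on the same inputs are byte-identical.
#'
#' @param report a `fever_dqi_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- unclass(report)
  payload$data <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Histogram of app-office temperature differences
#'
#' Visualizes the per-episode maximum-temperature differences (app minus
#' office) for acute versus past office episodes. Requires ggplot2.
#'
#' @param report a `fever_dqi_report`.
#' @param binwidth histogram bin width in degrees Celsius.
#' @return a ggplot object.
#' @export
plot_temperature_differences <- function(report, binwidth = 0.1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_temperature_differences() requires ggplot2")
  }
  d <- report$data$paired
  d <- d[!is.na(d$temp_difference), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temp_difference)) +
    ggplot2::geom_histogram(binwidth = binwidth) +
    ggplot2::facet_wrap(~office_kind, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "max temperature difference, app - office (°C)",
                  y = "episodes")
}
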