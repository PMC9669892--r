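# shared fixtures and independent oracles

t_base <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

# diary entries at given hour offsets for one profile
entries_at <- function(hours, profile_id = "p1", temperature = NA_real_,
                       physician_visit = NA_character_,
                       antipyretic = NA_character_,
                       antibiotic = NA_character_, healthy_marker = FALSE) {
  tibble::tibble(
    profile_id = profile_id, occurred_at = t_base + hours * 3600,
    temperature = temperature, physician_visit = physician_visit,
    antipyretic = antipyretic, antibiotic = antibiotic,
    healthy_marker = healthy_marker)
}

profile_row <- function(family_code = "abcdefgh", profile_id = "p1",
                        gender = "female", birth_month = 3L,
                        birth_year = 2015L, is_adult = FALSE,
                        created_at = t_base) {
  tibble::tibble(family_code = family_code, profile_id = profile_id,
                 gender = gender, birth_month = birth_month,
                 birth_year = birth_year, is_adult = is_adult,
                 created_at = created_at)
}

patient_row <- function(family_code = "abcdefgh", patient_id = "q1",
                        gender = "female",
                        birth_date = as.Date("2015-03-15"),
                        registered_at = as.Date("2019-10-01")) {
  tibble::tibble(family_code = family_code, patient_id = patient_id,
                 gender = gender, birth_date = birth_date,
                 registered_at = registered_at)
}

app_ep_row <- function(episode, start_day, end_day, profile_id = "p1",
                       temp = 39.0, visit = FALSE, anti = FALSE,
                       abx = FALSE) {
  tibble::tibble(
    profile_id = profile_id, episode = as.integer(episode),
    start = t_base + start_day * 86400 + 9 * 3600,
    end = t_base + end_day * 86400 + 9 * 3600,
    n_entries = 2L, max_temperature = temp, physician_visit = visit,
    antipyretic = anti, antibiotic = abx)
}

office_ep_row <- function(episode, visit_day, kind = "acute",
                          patient_id = "q1", temp = 39.0, visit = TRUE,
                          anti = FALSE, abx = FALSE) {
  tibble::tibble(
    patient_id = patient_id, episode = as.integer(episode),
    visit_date = as.Date(t_base) + visit_day, kind = kind,
    max_temperature = temp, physician_visit = visit, antipyretic = anti,
    antibiotic = abx)
}

# Clopper-Pearson oracle: direct inversion of the binomial tails by
# bisection, independent of the qbeta identity used in the implementation
cp_bisect_oracle <- function(k, n, alpha = 0.05, tol = 1e-10) {
  bisect <- function(f) {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  low <- if (k == 0) 0 else
    bisect(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) < alpha / 2)
  high <- if (k == n) 1 else
    bisect(function(p) stats::pbinom(k, n, p) >= alpha / 2)
  c(low = low, high = high)
}

# exhaustive maximum one-to-one pairing oracle under the window rules
max_pairing_oracle <- function(app_eps, office_eps, acute_window_days = 7,
                               past_window_days = 60) {
  n_app <- nrow(app_eps)
  n_off <- nrow(office_eps)
  if (n_app == 0 || n_off == 0) return(0L)
  app_start <- as.Date(app_eps$start)
  app_end <- as.Date(app_eps$end)
  feasible <- matrix(FALSE, n_off, n_app)
  for (j in seq_len(n_off)) {
    vd <- office_eps$visit_date[j]
    for (i in seq_len(n_app)) {
      feasible[j, i] <- if (office_eps$kind[j] == "acute") {
        (app_start[i] <= vd && vd <= app_end[i]) ||
          abs(as.numeric(app_start[i] - vd)) <= acute_window_days
      } else {
        back <- as.numeric(vd - app_end[i])
        back > 0 && back <= past_window_days
      }
    }
  }
  best <- 0L
  recurse <- function(j, used) {
    if (j > n_off) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(j + 1, used) # leave office episode j unpaired
    for (i in which(feasible[j, ] & !used)) {
      used[i] <- TRUE
      recurse(j + 1, used)
      used[i] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, n_app))
  best
}

# exact two-sided rank-sum p-value by full permutation enumeration
mw_permutation_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- base::c(x, y)
  idx <- utils::combn(m + n, m)
  u_stat <- function(xi) {
    r <- rank(pooled)
    sum(r[xi]) - m * (m + 1) / 2
  }
  u_all <- apply(idx, 2, function(cols) {
    r <- rank(pooled)
    sum(r[cols]) - m * (m + 1) / 2
  })
  u_obs <- u_stat(seq_len(m))
  mu <- m * n / 2
  if (u_obs > mu) {
    min(1, 2 * mean(u_all >= u_obs))
  } else {
    min(1, 2 * mean(u_all <= u_obs))
  }
}

# reference cohort and its pipeline report, computed once per test run
ref_env <- new.env(parent = emptyenv())
ref_cohort <- function() {
  if (is.null(ref_env$cohort)) ref_env$cohort <- build_reference_cohort()
  ref_env$cohort
}
ref_report <- function() {
  if (is.null(ref_env$report)) {
    cohort <- ref_cohort()
    ref_env$report <- run_pipeline(cohort$app, cohort$office)
  }
  ref_env$report
}
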