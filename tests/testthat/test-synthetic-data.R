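test_that("configuration is validated", {
  expect_error(generator_config(p_app_record = 1.2), "probabilities")
  expect_error(generator_config(children_per_family = base::c(`1` = 0.7)),
               "sum to 1")
  cfg <- generator_config(seed = 3)
  expect_s3_class(cfg, "generator_config")
})

test_that("the same seed reproduces identical CSV bytes", {
  cfg <- generator_config(seed = 99, n_families = 15)
  dir <- withr::local_tempdir()
  for (run in base::c("a", "b")) {
    cohort <- generate_cohort(cfg)
    write_app_export(cohort$app, file.path(dir, run, "app"))
    write_office_export(cohort$office, file.path(dir, run, "office"))
  }
  for (f in base::c("app/profiles.csv", "app/entries.csv",
                    "app/families.csv", "office/patients.csv",
                    "office/visits.csv")) {
    expect_identical(unname(tools::md5sum(file.path(dir, "a", f))),
                     unname(tools::md5sum(file.path(dir, "b", f))),
                     label = f)
  }
})

test_that("generated entries segment back into the generated episodes", {
  for (seed in base::c(2, 17)) {
    cohort <- generate_cohort(generator_config(seed = seed,
                                               n_families = 40))
    eps <- segment_profiles(cohort$app$entries)
    tr <- cohort$truth$episodes
    expect_equal(nrow(eps), sum(tr$app_recorded))
    # per-profile counts agree too
    got <- table(eps$profile_id)
    want <- table(tr$profile_id[tr$app_recorded])
    expect_equal(as.vector(got[names(want)]), as.vector(want))
    # and recovered intervals equal the generated ones
    rec <- dplyr::arrange(eps, profile_id, start)
    gen <- tr[tr$app_recorded, ]
    gen <- dplyr::arrange(gen, profile_id, start)
    expect_equal(rec$start, gen$start)
    expect_equal(rec$end, gen$end)
  }
})

test_that("the noise-free limit recovers perfect indicators", {
  cfg <- generator_config(
    seed = 8, n_families = 40, p_family_active = 1,
    p_family_not_in_office = 0, p_family_no_profiles = 0,
    p_app_record = 1, p_office_visit_acute = 1,
    p_submit = list(physician_visit = base::c(app = 1, office = 1),
                    antipyretic = base::c(app = 1, office = 1),
                    antibiotic = base::c(app = 1, office = 1),
                    max_temperature = base::c(app = 1, office = 1)),
    app_temp_noise_sd = 0, office_past_recall_bias = 0,
    p_gender_error = 0, p_dob_error = 0, p_dob_missing = 0,
    p_duplicate_profile = 0, p_sibling_not_patient = 0,
    p_adult_profile = 0)
  cohort <- generate_cohort(cfg)
  rep <- run_pipeline(cohort$app, cohort$office)
  expect_equal(rep$venn$app_only, 0)
  expect_equal(rep$venn$office_only, 0)
  expect_equal(rep$venn$office_family_without_app_entries, 0)
  expect_true(all(rep$concordance$rate == 1))
  expect_true(all(rep$demographics$rate == 1))
  expect_equal(rep$accounting$profiles_siblings, 0)
  expect_equal(rep$accounting$profiles_duplicates, 0)
})

test_that("suppressing a variable's submission drives concordance to the coercion floor", {
  cfg <- generator_config(seed = 12, n_families = 150)
  cfg$p_submit$physician_visit[["app"]] <- 0
  cohort <- generate_cohort(cfg)
  rep <- run_pipeline(cohort$app, cohort$office)
  conc <- rep$concordance
  got <- conc$rate[conc$variable == "physician_visit"]
  # expected: agreement only where the office also reads "no"
  exp_cfg <- expected_dqi(cfg)
  want <- exp_cfg$expected[exp_cfg$variable == "physician_visit"]
  n <- conc$n[conc$variable == "physician_visit"]
  expect_lt(abs(got - want), 3 * sqrt(want * (1 - want) / n))
})

test_that("closed-form coercion algebra matches Monte-Carlo simulation", {
  set.seed(4242)
  n <- 1e6
  for (case in list(base::c(pi = 0.55, qa = 0.73, qo = 1.0),
                    base::c(pi = 0.2, qa = 0.5, qo = 0.9))) {
    truth <- runif(n) < case[["pi"]]
    app <- truth & (runif(n) < case[["qa"]])
    office <- truth & (runif(n) < case[["qo"]])
    sim <- mean(app == office)
    analytic <- case[["pi"]] * (case[["qa"]] * case[["qo"]] +
                                  (1 - case[["qa"]]) * (1 - case[["qo"]])) +
      (1 - case[["pi"]])
    expect_lt(abs(sim - analytic), 4 * sqrt(0.25 / n))
  }
  # degenerate expectations
  e <- expected_dqi(generator_config(p_gender_error = 0, p_dob_error = 0))
  expect_equal(e$expected[e$variable == "gender"], 1)
  expect_equal(e$expected[e$variable == "date_of_birth"], 1)
})

test_that("generator emulates the study's topline cohort shape", {
  # at the default (study-scale) configuration, the reconciliation cells
  # land near the published totals; stochastic, so a 10% band
  cohort <- generate_cohort(generator_config(seed = 2024))
  rep <- run_pipeline(cohort$app, cohort$office)
  v <- rep$venn
  near <- function(got, want, tol = 0.10) {
    expect_lt(abs(got - want) / want, tol,
              label = sprintf("%d vs %d", got, want))
  }
  near(v$app_identifiable, 1452)
  near(v$office_children_with_profiles, 953)
  near(v$office_paired, 686)
})
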