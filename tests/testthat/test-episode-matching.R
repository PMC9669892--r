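test_that("acute visits pair by date containment, then by window", {
  app <- app_ep_row(1, 2, 5)                     # Jan 3 - Jan 6
  office <- office_ep_row(1, 3)                  # visit Jan 4
  m <- match_episodes(app, office)
  expect_equal(m$match_type, "paired")

  # outside the episode but within the 7-day window
  m2 <- match_episodes(app_ep_row(1, 10, 11), office_ep_row(1, 5))
  expect_equal(m2$match_type[1], "paired")
  # outside the window: both exclusive
  m3 <- match_episodes(app_ep_row(1, 30, 31), office_ep_row(1, 5))
  expect_setequal(m3$match_type, c("app_only", "office_only"))
})

test_that("past reports pair with the most recent preceding episode", {
  app <- dplyr::bind_rows(app_ep_row(1, 0, 1), app_ep_row(2, 20, 21))
  office <- office_ep_row(1, 30, kind = "past")
  m <- match_episodes(app, office)
  expect_equal(m$app_episode[m$match_type == "paired"], 2L)
  # beyond the look-back window
  m2 <- match_episodes(app_ep_row(1, 0, 1),
                       office_ep_row(1, 70, kind = "past"))
  expect_false(any(m2$match_type == "paired"))
  # a past report never pairs forward in time
  m3 <- match_episodes(app_ep_row(1, 40, 41),
                       office_ep_row(1, 30, kind = "past"))
  expect_false(any(m3$match_type == "paired"))
})

test_that("degenerate inputs yield all-exclusive matches", {
  office <- dplyr::bind_rows(office_ep_row(1, 5),
                             office_ep_row(2, 40, kind = "past"))
  m <- match_episodes(app_ep_row(1, 0, 1)[0, ], office)
  expect_equal(m$match_type, c("office_only", "office_only"))
  m2 <- match_episodes(app_ep_row(1, 0, 1), office[0, ])
  expect_equal(m2$match_type, "app_only")
})

test_that("greedy pairing attains the exhaustive optimum on small cases", {
  set.seed(902)
  for (rep in 1:25) {
    n_app <- sample(0:6, 1)
    n_off <- sample(0:5, 1)
    app <- if (n_app > 0) {
      starts <- sort(sample(0:80, n_app))
      dplyr::bind_rows(lapply(seq_len(n_app), function(i) {
        app_ep_row(i, starts[i], starts[i] + sample(0:2, 1))
      }))
    } else app_ep_row(1, 0, 1)[0, ]
    office <- if (n_off > 0) {
      days <- sort(sample(0:90, n_off))
      dplyr::bind_rows(lapply(seq_len(n_off), function(j) {
        office_ep_row(j, days[j],
                      kind = sample(c("acute", "past"), 1))
      }))
    } else office_ep_row(1, 0)[0, ]
    m <- match_episodes(app, office)
    got <- sum(m$match_type == "paired")
    opt <- max_pairing_oracle(app, office)
    expect_equal(got, opt,
                 info = sprintf("rep %d: %d app, %d office", rep, n_app,
                                n_off))
    # conservation and no double pairing
    expect_equal(sum(m$match_type != "office_only"), max(n_app, 0))
    expect_equal(sum(m$match_type != "app_only"), max(n_off, 0))
    expect_false(anyDuplicated(stats::na.omit(m$app_episode)) > 0)
    # permutation stability
    if (n_app > 1 || n_off > 1) {
      m_perm <- match_episodes(app[sample(nrow(app)), ],
                               office[sample(nrow(office)), ])
      ord <- function(x) x[order(x$office_episode, x$app_episode), ]
      expect_equal(ord(m_perm), ord(m))
    }
  }
})

test_that("agreement grading applies coercion equality and 0.1 °C rule", {
  a <- app_ep_row(1, 2, 3, temp = 39.4, visit = TRUE)
  o <- office_ep_row(1, 2, temp = 39.4, visit = TRUE)
  g <- grade_agreement(a, o)
  expect_equal(g$physician_visit, "agree")
  expect_equal(g$max_temperature, "agree")
  expect_equal(g$temp_difference, 0)

  g2 <- grade_agreement(app_ep_row(1, 2, 3, temp = 39.4),
                        office_ep_row(1, 2, temp = 39.0, visit = FALSE))
  expect_equal(g2$max_temperature, "disagree")
  expect_equal(g2$temp_difference, 0.4)

  g3 <- grade_agreement(app_ep_row(1, 2, 3, temp = NA_real_),
                        office_ep_row(1, 2, visit = FALSE))
  expect_equal(g3$max_temperature, "not_comparable")
})

test_that("reconciliation cells reproduce the published partition", {
  rep <- ref_report()
  v <- rep$venn
  expect_equal(v$office_total, 1171)
  expect_equal(v$office_family_without_app_entries, 133)
  expect_equal(v$office_child_without_profile, 85)
  expect_equal(v$office_children_with_profiles, 953)
  expect_equal(v$office_acute, 681)
  expect_equal(v$office_past, 272)
  expect_equal(v$office_paired, 686)
  expect_equal(v$office_paired_acute, 424)
  expect_equal(v$office_paired_past, 262)
  expect_equal(v$app_total, 1481)
  expect_equal(v$app_unidentifiable, 29)
  expect_equal(v$app_identifiable, 1452)
  expect_equal(v$app_only, 766)
  # single child, single paired episode: all other cells zero
  links <- link_profiles(profile_row(), patient_row())
  eps <- segment_entries(entries_at(c(0, 10)))
  m <- match_cohort_episodes(eps, office_episodes(
    office_dataset(patient_row(),
                   tibble::tibble(patient_id = "q1",
                                  visit_date = as.Date(t_base),
                                  kind = "acute", max_temperature = 39,
                                  physician_visit = "yes",
                                  antipyretic = "no", antibiotic = "no"))),
    links)
  v1 <- venn_partition(m, links, eps, office_episodes(
    office_dataset(patient_row(),
                   tibble::tibble(patient_id = "q1",
                                  visit_date = as.Date(t_base),
                                  kind = "acute", max_temperature = 39,
                                  physician_visit = "yes",
                                  antipyretic = "no", antibiotic = "no"))))
  expect_equal(v1$office_paired, 1)
  expect_equal(v1$app_only, 0)
  expect_equal(v1$office_only, 0)
  expect_equal(v1$office_family_without_app_entries, 0)
})

test_that("venn cells agree with generator ground truth", {
  cohort <- generate_cohort(generator_config(seed = 31, n_families = 80))
  rep <- run_pipeline(cohort$app, cohort$office)
  tr <- cohort$truth$episodes
  expect_equal(rep$venn$app_total, sum(tr$app_recorded))
  expect_equal(rep$venn$office_total, sum(tr$office_recorded))
  expect_equal(rep$venn$office_paired,
               sum(tr$app_recorded & tr$office_recorded))
  # conservation
  expect_equal(rep$venn$app_paired + rep$venn$app_only,
               rep$venn$app_identifiable)
  expect_equal(rep$venn$office_paired + rep$venn$office_only,
               rep$venn$office_children_with_profiles)
})
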