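test_that("exact demographics give a clean match", {
  links <- link_profiles(profile_row(), patient_row())
  expect_equal(nrow(links), 1)
  expect_equal(links$status, "matched")
  expect_false(links$mismatch_gender | links$mismatch_dob |
                 links$dob_missing)
})

test_that("synonymous duplicates collapse to the earliest profile", {
  fam <- dplyr::bind_rows(
    profile_row(profile_id = "p1", created_at = t_base),
    profile_row(profile_id = "p2", created_at = t_base + 3600),
    profile_row(profile_id = "p3", gender = "male", birth_month = 7L,
                created_at = t_base))
  dups <- detect_synonymous_profiles(fam)
  expect_equal(nrow(dups), 2)
  expect_equal(dups$profile_id[dups$canonical], "p1")

  # three identical profiles form one group with one canonical
  fam3 <- dplyr::bind_rows(
    profile_row(profile_id = "a", created_at = t_base + 100),
    profile_row(profile_id = "b", created_at = t_base),
    profile_row(profile_id = "c", created_at = t_base + 200))
  d3 <- detect_synonymous_profiles(fam3)
  expect_equal(nrow(d3), 3)
  expect_equal(unique(d3$group), 1L)
  expect_equal(d3$profile_id[d3$canonical], "b")

  expect_equal(nrow(detect_synonymous_profiles(fam[3, ])), 0)

  links <- link_profiles(fam, patient_row())
  expect_equal(sum(links$status == "synonymous_duplicate"), 1)
  expect_equal(links$duplicate_of[links$status == "synonymous_duplicate"],
               "p1")
})

test_that("demographic comparison classifies mismatches symmetrically", {
  expect_equal(compare_demographics(profile_row(), patient_row()),
               character(0))
  expect_equal(
    compare_demographics(profile_row(gender = "male"), patient_row()),
    "gender")
  expect_equal(
    compare_demographics(profile_row(birth_month = 4L), patient_row()),
    "date_of_birth")
  expect_setequal(
    compare_demographics(profile_row(gender = "male", birth_year = 2014L),
                         patient_row()),
    c("gender", "date_of_birth"))
  expect_equal(
    compare_demographics(profile_row(birth_month = NA_integer_),
                         patient_row()),
    "dob_missing")
  # diverse never auto-matches the office's two options
  expect_equal(
    compare_demographics(profile_row(gender = "diverse"), patient_row()),
    "gender")
})

test_that("every profile and patient lands in exactly one link", {
  cohort <- generate_cohort(generator_config(seed = 5, n_families = 60))
  links <- link_profiles(cohort$app$profiles, cohort$office$patients)
  app_linked <- links$profile_id[!is.na(links$profile_id)]
  expect_setequal(app_linked, cohort$app$profiles$profile_id)
  expect_false(anyDuplicated(app_linked) > 0)
  pat_linked <- links$patient_id[!is.na(links$patient_id)]
  expect_setequal(pat_linked, cohort$office$patients$patient_id)
  expect_false(anyDuplicated(pat_linked) > 0)
  # matched pairs cannot exceed the smaller side of any family
  per_fam <- split(links, links$family_code)
  for (pf in per_fam) {
    n_kids <- sum(!is.na(pf$profile_id) &
                    pf$status %in% c("matched", "app_only_sibling"))
    n_pats <- sum(!is.na(pf$patient_id))
    expect_lte(sum(pf$status == "matched"), min(n_kids, n_pats))
  }
})

test_that("linkage against the true child mapping is recovered", {
  cohort <- generate_cohort(generator_config(seed = 23, n_families = 80))
  links <- link_profiles(cohort$app$profiles, cohort$office$patients)
  truth <- cohort$truth$links
  truth_pairs <- truth[!is.na(truth$patient_id), ]
  got <- links[links$status == "matched", c("profile_id", "patient_id")]
  merged <- merge(truth_pairs, got, by = "profile_id",
                  suffixes = c("_true", "_got"))
  expect_equal(nrow(merged), nrow(truth_pairs))
  expect_true(all(merged$patient_id_true == merged$patient_id_got))
})

test_that("strict mode rejects app families missing from the office", {
  app <- dplyr::bind_rows(profile_row(),
                          profile_row(family_code = "zzzzzzzz",
                                      profile_id = "p9"))
  expect_error(link_profiles(app, patient_row(), strict = TRUE),
               "absent from office")
  links <- link_profiles(app, patient_row(), strict = FALSE)
  expect_false(links$family_in_office[links$profile_id == "p9"])
})

test_that("cohort accounting reproduces the published profile arithmetic", {
  rep <- ref_report()
  a <- rep$accounting
  expect_equal(a$profiles_total, 1047)
  expect_equal(a$profiles_unidentifiable_family, 6)
  expect_equal(a$families_not_in_office, 5)
  expect_equal(a$families_without_profiles, 3)
  expect_equal(a$profiles_siblings, 22)
  expect_equal(a$profiles_adults, 2)
  expect_equal(a$profiles_duplicates, 5)
  expect_equal(a$profiles_comparable,
               1047 - 6 - (22 + 2 + 5))
  expect_equal(a$families_comparable, 676)
  expect_equal(a$families_with_app_entries, 537)
  expect_equal(a$families_with_comparable_entries, 534)
  expect_equal(a$children_with_app_episodes, 668)
})

test_that("demographic indicators follow the mismatch counts", {
  links <- dplyr::bind_rows(lapply(1:20, function(i) {
    fc <- paste0(letters[i], "familyz")
    bm <- if (i > 18) NA_integer_ else if (i == 3) 9L else 3L
    by <- if (i > 18) NA_integer_ else 2015L
    link_profiles(
      profile_row(family_code = fc, profile_id = sprintf("p%d", i),
                  gender = if (i <= 2) "male" else "female",
                  birth_month = bm, birth_year = by),
      patient_row(family_code = fc, patient_id = sprintf("q%d", i)))
  }))
  d <- demographic_dqi(links)
  conc_gender <- d[d$indicator == "concordance" & d$variable == "gender", ]
  expect_equal(conc_gender$k, 18L)
  expect_equal(conc_gender$n, 20L)
  comp_dob <- d[d$indicator == "completeness" &
                  d$variable == "date_of_birth", ]
  expect_equal(comp_dob$k, 18L)
})
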