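test_that("cohort generation is reproducible and respects edge cases", {
  cfg <- small_config(0L)
  empty <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(empty$users), 0)
  expect_equal(nrow(empty$diaries), 0)

  a <- generate_cohort(small_config(400L), seed = 99)
  b <- generate_cohort(small_config(400L), seed = 99)
  expect_identical(a$users, b$users)
  expect_identical(a$diaries, b$diaries)
  c2 <- generate_cohort(small_config(400L), seed = 100)
  expect_false(identical(a$users, c2$users))
})

test_that("config validation rejects malformed calibrations", {
  cfg <- small_config()
  cfg$p_screen <- 1.2
  expect_error(generate_cohort(cfg), "probabilities")
  cfg2 <- small_config()
  cfg2$isi_baseline$clinical$sd <- 0
  expect_error(generate_cohort(cfg2), "SDs")
  cfg3 <- small_config()
  cfg3$n_users <- -1L
  expect_error(generate_cohort(cfg3), "n_users")
})

test_that("funnel flags are monotone and ISI series consistent with them", {
  co <- generate_cohort(small_config(800L), seed = 3)
  u <- co$users
  expect_true(all(!u$step2_completed | u$step1_completed))
  expect_true(all(!u$step1_completed | u$eligible))
  expect_true(all(!u$eligible | u$screened))
  expect_true(all(is.na(u$isi_baseline) == !u$screened))
  expect_true(all(is.na(u$isi_post1) == !u$step1_completed))
  expect_true(all(is.na(u$isi_post2) == !u$step2_completed))
  # eligibility is exactly the clinical threshold on the integer baseline
  scr <- u[u$screened, ]
  expect_true(all(scr$isi_baseline[scr$eligible] > 14))
  expect_true(all(scr$isi_baseline[!scr$eligible] <= 14))
})

test_that("generated ISI totals stay in range at every occasion", {
  co <- generate_cohort(small_config(800L), seed = 4)
  for (col in c("isi_baseline", "isi_post1", "isi_post2")) {
    v <- co$users[[col]]
    v <- v[!is.na(v)]
    expect_true(all(v >= 0 & v <= 28))
    expect_true(all(v == round(v)))
  }
})

test_that("every simulated diary night passes diary validation with the TST identity", {
  co <- generate_cohort(small_config(2069L), seed = 5)
  s1 <- co$users$user_id[co$users$step1_completed]
  expect_gt(length(s1), 0)
  for (uid in s1[seq_len(min(10, length(s1)))]) {
    entries <- user_diary_entries(co, uid)
    expect_gte(length(entries), 7)
    for (e in entries) {
      ind <- derive_night(e)  # errors if the entry is inconsistent
      expect_identical(ind[["tst"]] + ind[["sol"]] + ind[["waso"]] +
                         ind[["twak"]], ind[["tib"]])
      expect_true(ind[["se"]] >= 0 && ind[["se"]] <= 100)
    }
  }
  # step-2 completers carry the 10 additional nights
  s2 <- co$users$user_id[co$users$step2_completed]
  expect_equal(sum(co$diaries$user_id == s2[1]), 17)
})

test_that("zero effect noise collapses to the closed-form mean shift", {
  cfg <- small_config(2069L)
  cfg$step1_effect$sd_delta <- 0
  cfg$step2_effect$sd_delta <- 0
  co <- generate_cohort(cfg, seed = 6)
  s1 <- co$users[co$users$step1_completed, ]
  expect_equal(s1$isi_post1, s1$isi_baseline + cfg$step1_effect$mean_delta,
               tolerance = 1e-12)
  s2 <- co$users[co$users$step2_completed, ]
  expect_equal(s2$isi_post2, s2$isi_post1 + cfg$step2_effect$mean_delta,
               tolerance = 1e-12)
  # deterministic change scores make the paired t degenerate
  expect_error(paired_t(s1$isi_post1 - s1$isi_baseline), "constant")
})

test_that("single-cohort funnel fractions sit near their configured probabilities", {
  co <- generate_cohort(seed = 7)  # default calibration, n = 2069
  u <- co$users
  expect_equal(mean(u$screened), 0.76, tolerance = 0.04)
  expect_equal(sum(u$eligible) / sum(u$screened), 0.491, tolerance = 0.06)
  expect_equal(sum(u$step1_completed) / sum(u$eligible), 0.215,
               tolerance = 0.08)
})

test_that("study tables regenerate every statistic class from the cohort", {
  co <- generate_cohort(seed = 8)
  tab <- emit_study_tables(co)
  expect_equal(tab$funnel$count[1], 2069)
  expect_true(all(diff(tab$funnel$count) <= 0))
  expect_s3_class(tab$demographics$gender_chisq, "htest")
  expect_s3_class(tab$demographics$age_t, "htest")
  expect_equal(sort(tab$severity_mixture$stratum),
               c("clinical", "subclinical"))
  # calibration recovery of the severity mixture location, one cohort
  cli <- tab$severity_mixture[tab$severity_mixture$stratum == "clinical", ]
  expect_equal(cli$isi_mean, 18.8, tolerance = 0.4)
  s1 <- tab$isi_outcomes$step1
  expect_lt(s1$post1_mean, s1$baseline_mean)
  expect_lt(unname(s1$paired$statistic), 0)
  expect_equal(nrow(tab$diary_step1), 7)
  # severity-band distributions are proper
  for (d in tab$severity_distribution) {
    if (!is.null(d)) expect_equal(sum(d), 1, tolerance = 1e-12)
  }
})

test_that("an effect-free homogeneous cohort yields zero-valued outcome statistics", {
  cfg <- small_config(2069L)
  cfg$step1_effect <- list(mean_delta = 0, sd_delta = 0)
  cfg$step2_effect <- list(mean_delta = 0, sd_delta = 0)
  tab <- emit_study_tables(generate_cohort(cfg, seed = 9))
  expect_equal(unname(tab$isi_outcomes$step1$paired$statistic), 0)
  expect_equal(unname(tab$isi_outcomes$step2$paired_post1_post2$statistic), 0)
})
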