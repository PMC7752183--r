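low_isi <- function(occ = "interview1") score_isi(rep(1, 7), occ)   # 7
mid_isi <- function(occ = "interview1") score_isi(c(3, 3, 2, 2, 2, 2, 2), occ)  # 16
high_isi <- function(occ = "interview1") score_isi(c(4, 4, 4, 3, 3, 3, 2), occ)  # 23

run_events <- function(state, events) {
  for (ev in events) state <- advance(state, ev)$state
  state
}

test_that("screening branches on the eligibility threshold", {
  low <- advance(protocol_state(), protocol_event("isi_completed",
                                                  low_isi()))
  expect_equal(low$state$stage, "screened_low")
  expect_true("generic_hygiene_bundle" %in% low$actions)

  el <- advance(protocol_state(), protocol_event("isi_completed",
                                                 mid_isi()))
  expect_equal(el$state$stage, "step1_diary")
  expect_equal(el$actions, "diary_week_instructions")
})

test_that("the interview-2 request is emitted exactly at the 7th diary night", {
  s <- advance(protocol_state(), protocol_event("isi_completed",
                                                mid_isi()))$state
  for (i in 1:6) {
    step <- advance(s, protocol_event("diary_entry_validated", make_entry()))
    s <- step$state
    expect_equal(s$stage, "step1_diary")
    expect_false("interview2_request" %in% step$actions)
    expect_true("morning_feedback" %in% step$actions)
  }
  step7 <- advance(s, protocol_event("diary_entry_validated", make_entry()))
  expect_equal(step7$state$stage, "interview2_due")
  expect_true("interview2_request" %in% step7$actions)
})

test_that("step 2 runs ten elapsed days and interview 3 routes to closure or referral", {
  to_step2 <- function() {
    run_events(protocol_state(), c(
      list(protocol_event("isi_completed", mid_isi())),
      replicate(7, protocol_event("diary_entry_validated", make_entry()),
                simplify = FALSE),
      list(protocol_event("isi_completed", mid_isi("interview2")))
    ))
  }
  s <- to_step2()
  expect_equal(s$stage, "step2_active")
  # diary entries stay legal (and optional) during Step 2
  s <- advance(s, protocol_event("diary_entry_validated", make_entry()))$state
  for (i in 1:9) {
    s <- advance(s, protocol_event("step2_day_elapsed"))$state
    expect_equal(s$stage, "step2_active")
  }
  s <- advance(s, protocol_event("step2_day_elapsed"))$state
  expect_equal(s$stage, "interview3_due")

  done <- advance(s, protocol_event("isi_completed", mid_isi("interview3")))
  expect_equal(done$state$stage, "autonomous_use")

  s2 <- run_events(to_step2(),
                   replicate(10, protocol_event("step2_day_elapsed"),
                             simplify = FALSE))
  ref <- advance(s2, protocol_event("isi_completed", high_isi("interview3")))
  expect_equal(ref$state$stage, "referred")
  expect_equal(ref$actions, "referral_notice")
})

test_that("illegal transitions raise protocol violations naming stage and event", {
  s <- advance(protocol_state(), protocol_event("isi_completed",
                                                mid_isi()))$state
  expect_error(advance(s, protocol_event("isi_completed",
                                         mid_isi("interview2"))),
               "protocol violation.*isi_completed.*step1_diary")
  expect_error(advance(s, protocol_event("step2_day_elapsed")),
               "protocol violation")
  expect_error(advance(protocol_state(),
                       protocol_event("diary_entry_validated",
                                      make_entry())),
               "protocol violation")
  expect_error(protocol_event("isi_completed", payload = NULL),
               "isi_result")
})

test_that("terminal stages absorb and dropout is legal from every non-terminal stage", {
  low <- advance(protocol_state(), protocol_event("isi_completed",
                                                  low_isi()))$state
  expect_error(advance(low, protocol_event("isi_completed",
                                           mid_isi("interview2"))),
               "protocol violation")
  expect_error(advance(low, protocol_event("user_dropout")),
               "protocol violation")

  dropped <- advance(protocol_state(), protocol_event("user_dropout"))$state
  expect_equal(dropped$stage, "dropout")
  expect_error(advance(dropped, protocol_event("user_dropout")),
               "protocol violation")

  tt <- transition_table()
  nonterminal <- c("registered", "step1_diary", "interview2_due",
                   "step2_active", "interview3_due")
  for (st in nonterminal) {
    expect_true(any(tt$stage == st & tt$event != "user_dropout"))
    expect_true(any(tt$stage == st & tt$event == "user_dropout"))
  }
  terminal <- c("screened_low", "autonomous_use", "referred", "dropout")
  expect_false(any(tt$stage %in% terminal))
})

test_that("funnel counts are monotone along the adherence chain", {
  expect_equal(funnel_counts(list()),
               c(downloaded = 0L, screened = 0L, eligible = 0L,
                 step1_completed = 0L, step2_completed = 0L))

  full <- run_events(protocol_state(), c(
    list(protocol_event("isi_completed", mid_isi())),
    replicate(7, protocol_event("diary_entry_validated", make_entry()),
              simplify = FALSE),
    list(protocol_event("isi_completed", mid_isi("interview2"))),
    replicate(10, protocol_event("step2_day_elapsed"), simplify = FALSE)
  ))
  counts <- funnel_counts(list(full, protocol_state()))
  expect_equal(unname(counts), c(2, 1, 1, 1, 1))
  expect_true(all(diff(counts) <= 0))
})

test_that("replaying a recorded event log reproduces the session, also via JSON", {
  s <- run_events(protocol_state("audit"), c(
    list(protocol_event("isi_completed", mid_isi())),
    replicate(7, protocol_event("diary_entry_validated", make_entry()),
              simplify = FALSE),
    list(protocol_event("isi_completed", mid_isi("interview2")))
  ))
  replayed <- replay_session(s)
  expect_equal(replayed$stage, s$stage)
  expect_equal(replayed$diary_days_done, s$diary_days_done)
  expect_equal(length(replayed$isi_history), length(s$isi_history))

  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  back <- read_session(path)
  expect_equal(back$stage, s$stage)
  expect_equal(back$diary_days_done, s$diary_days_done)
  expect_equal(vapply(back$isi_history, `[[`, 0L, "total"),
               vapply(s$isi_history, `[[`, 0L, "total"))
})
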