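# Protocol state machine for the two-step intervention flow:
# screening interview -> (low scorers: hygiene advice, done)
#                     -> Step 1: 7-day diary -> Interview 2
#                     -> Step 2: 10 days of personalized recommendations
#                     -> Interview 3 -> autonomous use, or referral if the
#                        complaint persists (ISI > 21).

protocol_stages <- c("registered", "screened_low", "step1_diary",
                     "interview2_due", "step2_active", "interview3_due",
                     "autonomous_use", "referred", "dropout")
protocol_terminal <- c("screened_low", "autonomous_use", "referred", "dropout")
protocol_events <- c("isi_completed", "diary_entry_validated",
                     "step2_day_elapsed", "user_dropout")

#' Create a fresh protocol session
#'
#' @param user_id identifier carried through serialization.
#' @param started_at session start time.
#' @return a \code{protocol_state}: stage \code{"registered"}, zero
#'   counters, empty ISI history and event log.
#' @export
protocol_state <- function(user_id = "user", started_at = Sys.time()) {
  structure(
    list(user_id = user_id, stage = "registered",
         diary_days_done = 0L, step2_days_done = 0L,
         isi_history = list(), event_log = list(),
         started_at = started_at),
    class = "protocol_state"
  )
}

#' Create a protocol event
#'
#' @param kind one of \code{isi_completed}, \code{diary_entry_validated},
#'   \code{step2_day_elapsed}, \code{user_dropout}.
#' @param payload an [score_isi()] result for \code{isi_completed}, a
#'   [diary_entry()] for \code{diary_entry_validated}, otherwise NULL.
#' @return a \code{protocol_event}.
#' @export
protocol_event <- function(kind, payload = NULL) {
  if (!kind %in% protocol_events) {
    stop("unknown event kind: ", kind, call. = FALSE)
  }
  if (kind == "isi_completed" && !inherits(payload, "isi_result")) {
    stop("isi_completed requires an isi_result payload", call. = FALSE)
  }
  if (kind == "diary_entry_validated" && !is.null(payload) &&
      !inherits(payload, "diary_entry")) {
    stop("diary_entry_validated payload must be a diary_entry",
         call. = FALSE)
  }
  structure(list(kind = kind, payload = payload), class = "protocol_event")
}

protocol_violation <- function(state, event) {
  stop(sprintf("protocol violation: event '%s' is illegal in stage '%s'",
               event$kind, state$stage), call. = FALSE)
}

#' Advance the protocol by one event
#'
#' Applies one event to the session, enforcing the transition guards: the
#' follow-up interview becomes due exactly when the 7th diary night is
#' validated; Interview 3 becomes due after 10 elapsed recommendation days;
#' after Interview 3 a total above 21 routes to referral, otherwise to
#' autonomous use. Terminal stages accept no further events; dropout is
#' legal from every non-terminal stage. ISI occasions must arrive in order
#' (interview1, interview2, interview3), at most once each.
#'
#' @param state a [protocol_state()].
#' @param event a [protocol_event()].
#' @return list with the new \code{state} and a character vector of
#'   \code{actions} emitted by this transition (advice bundles, feedback,
#'   interview requests, referral notice).
#' @export
advance <- function(state, event) {
  stage <- state$stage
  kind <- event$kind
  if (stage %in% protocol_terminal) protocol_violation(state, event)
  if (kind == "user_dropout") {
    state$stage <- "dropout"
    state$event_log[[length(state$event_log) + 1L]] <- event
    return(list(state = state, actions = "dropout_recorded"))
  }
  actions <- character()
  if (kind == "isi_completed") {
    occ <- event$payload$occasion
    expected <- c("registered" = "interview1",
                  "interview2_due" = "interview2",
                  "interview3_due" = "interview3")[stage]
    if (is.na(expected) || occ != expected) protocol_violation(state, event)
    state$isi_history[[length(state$isi_history) + 1L]] <- event$payload
    total <- event$payload$total
    if (stage == "registered") {
      if (total > 14) {
        state$stage <- "step1_diary"
        actions <- "diary_week_instructions"
      } else {
        state$stage <- "screened_low"
        actions <- c("generic_hygiene_bundle", "closure")
      }
    } else if (stage == "interview2_due") {
      state$stage <- "step2_active"
      actions <- c("week_summary", "personalized_recommendations")
    } else {  # interview3_due
      if (total > 21) {
        state$stage <- "referred"
        actions <- "referral_notice"
      } else {
        state$stage <- "autonomous_use"
        actions <- "closure"
      }
    }
  } else if (kind == "diary_entry_validated") {
    if (stage == "step1_diary") {
      state$diary_days_done <- state$diary_days_done + 1L
      actions <- "morning_feedback"
      if (state$diary_days_done >= 7L) {
        state$stage <- "interview2_due"
        actions <- c(actions, "interview2_request")
      }
    } else if (stage == "step2_active") {
      actions <- "morning_feedback"  # diary optional but accepted in Step 2
    } else {
      protocol_violation(state, event)
    }
  } else if (kind == "step2_day_elapsed") {
    if (stage != "step2_active") protocol_violation(state, event)
    state$step2_days_done <- state$step2_days_done + 1L
    if (state$step2_days_done >= 10L) {
      state$stage <- "interview3_due"
      actions <- "interview3_request"
    }
  } else {
    protocol_violation(state, event)
  }
  state$event_log[[length(state$event_log) + 1L]] <- event
  list(state = state, actions = actions)
}

#' @export
print.protocol_state <- function(x, ...) {
  cat(sprintf("protocol session '%s': stage %s (diary days %d, step-2 days %d, %d ISI occasion%s)\n",
              x$user_id, x$stage, x$diary_days_done, x$step2_days_done,
              length(x$isi_history),
              if (length(x$isi_history) == 1) "" else "s"))
  invisible(x)
}

#' Machine-readable transition table
#'
#' One row per legal (stage, event) pair with its guard, successor stage
#' and emitted actions. Every non-terminal stage has an outgoing edge and
#' accepts dropout.
#'
#' @return a data.frame with columns stage, event, guard, next_stage,
#'   actions.
#' @export
transition_table <- function() {
  tt <- rbind(
    data.frame(stage = "registered", event = "isi_completed",
               guard = "occasion interview1; total <= 14",
               next_stage = "screened_low",
               actions = "generic_hygiene_bundle;closure"),
    data.frame(stage = "registered", event = "isi_completed",
               guard = "occasion interview1; total > 14",
               next_stage = "step1_diary",
               actions = "diary_week_instructions"),
    data.frame(stage = "step1_diary", event = "diary_entry_validated",
               guard = "diary_days_done < 6 after increment",
               next_stage = "step1_diary", actions = "morning_feedback"),
    data.frame(stage = "step1_diary", event = "diary_entry_validated",
               guard = "diary_days_done reaches 7",
               next_stage = "interview2_due",
               actions = "morning_feedback;interview2_request"),
    data.frame(stage = "interview2_due", event = "isi_completed",
               guard = "occasion interview2",
               next_stage = "step2_active",
               actions = "week_summary;personalized_recommendations"),
    data.frame(stage = "step2_active", event = "diary_entry_validated",
               guard = "none (diary optional in Step 2)",
               next_stage = "step2_active", actions = "morning_feedback"),
    data.frame(stage = "step2_active", event = "step2_day_elapsed",
               guard = "step2_days_done < 9 after increment",
               next_stage = "step2_active", actions = ""),
    data.frame(stage = "step2_active", event = "step2_day_elapsed",
               guard = "step2_days_done reaches 10",
               next_stage = "interview3_due", actions = "interview3_request"),
    data.frame(stage = "interview3_due", event = "isi_completed",
               guard = "occasion interview3; total > 21",
               next_stage = "referred", actions = "referral_notice"),
    data.frame(stage = "interview3_due", event = "isi_completed",
               guard = "occasion interview3; total <= 21",
               next_stage = "autonomous_use", actions = "closure")
  )
  nonterminal <- setdiff(protocol_stages, protocol_terminal)
  dropout <- data.frame(stage = nonterminal, event = "user_dropout",
                        guard = "none", next_stage = "dropout",
                        actions = "dropout_recorded")
  rbind(tt, dropout)
}

#' Funnel counts over a set of protocol sessions
#'
#' Counts how many sessions reached each stage of the adherence funnel:
#' downloaded (all), screened (completed Interview 1), eligible (Interview-1
#' total above 14), Step 1 completed (7 diary nights), Step 2 completed
#' (10 recommendation days). Counts are monotone non-increasing.
#'
#' @param states list of [protocol_state()] objects.
#' @return named integer vector (downloaded, screened, eligible,
#'   step1_completed, step2_completed).
#' @export
funnel_counts <- function(states) {
  reach <- vapply(states, function(s) {
    screened <- length(s$isi_history) >= 1
    eligible <- screened && s$isi_history[[1]]$total > 14
    c(downloaded = TRUE, screened = screened, eligible = eligible,
      step1_completed = eligible && s$diary_days_done >= 7,
      step2_completed = eligible && s$step2_days_done >= 10)
  }, logical(5))
  if (length(states) == 0) {
    return(c(downloaded = 0L, screened = 0L, eligible = 0L,
             step1_completed = 0L, step2_completed = 0L))
  }
  apply(reach, 1, function(x) sum(x))
}

#' Replay a recorded event log
#'
#' Re-applies every logged event to a fresh session; used for audit: a
#' session must be exactly reproducible from its log.
#'
#' @param state a [protocol_state()] whose \code{event_log} to replay.
#' @return the reconstructed \code{protocol_state}.
#' @export
replay_session <- function(state) {
  fresh <- protocol_state(state$user_id, state$started_at)
  for (ev in state$event_log) {
    fresh <- advance(fresh, ev)$state
  }
  fresh
}

#' Serialize a protocol session to JSON
#'
#' @param state a [protocol_state()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_session <- function(state, path) {
  ser_event <- function(ev) {
    p <- ev$payload
    list(kind = ev$kind,
         payload = if (inherits(p, "isi_result")) {
           list(type = "isi_result", items = p$items, occasion = p$occasion,
                timestamp = format(p$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"))
         } else if (inherits(p, "diary_entry")) {
           c(list(type = "diary_entry"),
             lapply(unclass(p), as.character))
         } else NULL)
  }
  doc <- list(user_id = state$user_id, stage = state$stage,
              diary_days_done = state$diary_days_done,
              step2_days_done = state$step2_days_done,
              started_at = format(state$started_at, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
              event_log = lapply(state$event_log, ser_event))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a protocol session from JSON
#'
#' Rebuilds the session by replaying its event log through [advance()], so
#' a stored session is accepted only if its history is legal.
#'
#' @param path JSON path written by [write_session()].
#' @return a \code{protocol_state}.
#' @export
read_session <- function(path) {
  doc <- jsonlite::read_json(path)
  state <- protocol_state(doc$user_id,
                          as.POSIXct(doc$started_at, tz = "UTC",
                                     format = "%Y-%m-%dT%H:%M:%SZ"))
  for (ev in doc$event_log) {
    payload <- NULL
    if (!is.null(ev$payload)) {
      p <- ev$payload
      payload <- if (identical(p$type, "isi_result")) {
        score_isi(unlist(p$items), occasion = p$occasion,
                  timestamp = as.POSIXct(p$timestamp, tz = "UTC",
                                         format = "%Y-%m-%dT%H:%M:%SZ"))
      } else if (identical(p$type, "diary_entry")) {
        diary_entry(p$night_date, p$try_sleep_time,
                    as.numeric(p$reported_sol), as.numeric(p$nwak),
                    as.numeric(p$reported_waso), p$final_wake_time,
                    p$arise_time)
      }
    }
    state <- advance(state, protocol_event(ev$kind, payload))$state
  }
  state
}
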