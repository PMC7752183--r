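# Electronic sleep diary: nightly entries, midnight-safe time resolution,
# derived nocturnal indicators, window aggregation and morning feedback.
#
# The seven indicators follow the standard sleep-diary definitions:
#   SOL  sleep onset latency (reported, minutes)
#   NWAK number of awakenings (reported, count)
#   WASO wake after initial sleep onset, excluding SOL and TWAK (reported)
#   TWAK terminal wakefulness, final awakening -> out of bed (derived)
#   TIB  time in bed, intention to sleep -> final arising (derived)
#   TST  total sleep time = TIB - SOL - WASO - TWAK (derived, exact identity)
#   SE   sleep efficiency = 100 * TST / TIB (derived, percent)

indicator_names <- c("sol", "nwak", "twak", "waso", "tib", "tst", "se")

# parse "HH:MM" or "HH:MM:SS" to fractional minutes since midnight
parse_clock <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p) %in% 2:3 || anyNA(suppressWarnings(as.numeric(p)))) {
      return(NA_real_)
    }
    p <- as.numeric(p)
    if (p[1] < 0 || p[1] > 23 || p[2] < 0 || p[2] > 59) return(NA_real_)
    p[1] * 60 + p[2] + if (length(p) == 3) p[3] / 60 else 0
  }, numeric(1))
}

format_clock <- function(minutes) {
  m <- round(minutes) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Construct one night's sleep-diary entry
#'
#' An entry anchors on the evening's calendar date (\code{night_date}) and
#' records clock times plus the user-reported latencies and awakenings.
#'
#' @param night_date the calendar date of the evening (Date or "YYYY-MM-DD").
#' @param try_sleep_time clock time ("HH:MM") at which the user intended to
#'   fall asleep.
#' @param reported_sol sleep onset latency in minutes (>= 0).
#' @param nwak number of nocturnal awakenings (non-negative integer).
#' @param reported_waso minutes awake during the night, excluding sleep
#'   onset latency and terminal wakefulness (>= 0).
#' @param final_wake_time clock time of the final awakening.
#' @param arise_time clock time of getting out of bed.
#' @return a \code{diary_entry} object. Construction validates field types
#'   and signs only; temporal consistency is checked by
#'   [resolve_timeline()] / [derive_night()].
#' @export
diary_entry <- function(night_date, try_sleep_time, reported_sol, nwak,
                        reported_waso, final_wake_time, arise_time) {
  night_date <- as.Date(night_date)
  if (is.na(night_date)) stop("invalid night_date", call. = FALSE)
  for (v in c(reported_sol, reported_waso)) {
    if (!is.numeric(v) || is.na(v) || v < 0) {
      stop("reported_sol and reported_waso must be non-negative minutes",
           call. = FALSE)
    }
  }
  if (!is.numeric(nwak) || is.na(nwak) || nwak < 0 || nwak != floor(nwak)) {
    stop("nwak must be a non-negative integer count", call. = FALSE)
  }
  clocks <- parse_clock(c(try_sleep_time, final_wake_time, arise_time))
  if (anyNA(clocks)) {
    stop("clock times must be valid HH:MM (or HH:MM:SS)", call. = FALSE)
  }
  structure(
    list(night_date = night_date,
         try_sleep_time = as.character(try_sleep_time),
         reported_sol = as.numeric(reported_sol),
         nwak = as.integer(nwak),
         reported_waso = as.numeric(reported_waso),
         final_wake_time = as.character(final_wake_time),
         arise_time = as.character(arise_time)),
    class = "diary_entry"
  )
}

#' Resolve a diary entry's clock times onto an absolute timeline
#'
#' Uses a noon-anchored convention: clock times at or after 12:00 belong to
#' the evening of \code{night_date}; times before 12:00 belong to the next
#' morning (\code{night_date + 1}). This parses both early-evening bedtimes
#' and post-midnight bedtimes without extra flags, for any in-bed interval
#' shorter than 24 h.
#'
#' @param entry a [diary_entry()].
#' @return a list with POSIXct (UTC) instants \code{try_sleep},
#'   \code{final_wake}, \code{arise} satisfying
#'   \code{try_sleep <= final_wake <= arise}.
#' @export
resolve_timeline <- function(entry) {
  stopifnot(inherits(entry, "diary_entry"))
  clocks <- parse_clock(c(entry$try_sleep_time, entry$final_wake_time,
                          entry$arise_time))
  # minutes relative to midnight starting night_date; before-noon -> next day
  rel <- ifelse(clocks < 720, clocks + 1440, clocks)
  if (!(rel[1] <= rel[2] && rel[2] <= rel[3])) {
    stop("inconsistent entry: resolved times must be ordered ",
         "try_sleep <= final_wake <= arise", call. = FALSE)
  }
  if (rel[3] - rel[1] <= 0 || rel[3] - rel[1] >= 1440) {
    stop("inconsistent entry: in-bed interval must lie in (0, 24h)",
         call. = FALSE)
  }
  base <- as.POSIXct(paste(entry$night_date, "00:00:00"), tz = "UTC")
  out <- base + rel * 60
  list(try_sleep = out[1], final_wake = out[2], arise = out[3])
}

#' Derive the seven nocturnal sleep indicators for one night
#'
#' TIB and TWAK come from the resolved clock times; SOL, NWAK and WASO are
#' the user's reports; TST is the exact identity TIB - SOL - WASO - TWAK
#' and SE is 100 * TST / TIB. Entries whose reported wakefulness exceeds
#' the in-bed interval are rejected (never clamped) so the identity stays
#' exact for every accepted entry.
#'
#' @param entry a [diary_entry()].
#' @return a \code{night_indicators} object: named numeric vector with
#'   components sol, nwak, twak, waso, tib, tst, se (minutes, count, percent).
#' @export
derive_night <- function(entry) {
  tl <- resolve_timeline(entry)
  tib <- as.numeric(difftime(tl$arise, tl$try_sleep, units = "mins"))
  twak <- as.numeric(difftime(tl$arise, tl$final_wake, units = "mins"))
  sol <- entry$reported_sol
  waso <- entry$reported_waso
  tst <- tib - sol - waso - twak
  if (tst < 0) {
    stop(sprintf(paste0("entry rejected: over-reported wakefulness ",
                        "(SOL %.1f + WASO %.1f + TWAK %.1f > TIB %.1f min)"),
                 sol, waso, twak, tib), call. = FALSE)
  }
  structure(
    c(sol = sol, nwak = as.numeric(entry$nwak), twak = twak, waso = waso,
      tib = tib, tst = tst, se = 100 * tst / tib),
    class = "night_indicators"
  )
}

#' @export
print.night_indicators <- function(x, ...) {
  cat(sprintf(
    "night indicators: TIB %.0f min, TST %.0f min, SE %.1f%% (SOL %.0f, NWAK %.1f, WASO %.0f, TWAK %.0f)\n",
    x[["tib"]], x[["tst"]], x[["se"]], x[["sol"]], x[["nwak"]], x[["waso"]],
    x[["twak"]]))
  invisible(x)
}

#' Componentwise mean of a window of nights
#'
#' Aggregates a list of [derive_night()] results by arithmetic mean per
#' component. The pre/post windows used in outcome reporting are the first
#' two and last two *completed* nights in chronological order.
#'
#' @param nights list of \code{night_indicators}.
#' @param selector "all" (default), "first2", "last2", or "custom".
#' @param range integer indices into \code{nights} when
#'   \code{selector = "custom"}.
#' @return a \code{night_indicators} aggregate; \code{nwak} may be
#'   fractional.
#' @export
window_mean <- function(nights, selector = c("all", "first2", "last2", "custom"),
                        range = NULL) {
  selector <- match.arg(selector)
  n <- length(nights)
  idx <- switch(selector,
    all = seq_len(n),
    first2 = if (n >= 2) 1:2 else
      stop("first2 window needs at least 2 nights", call. = FALSE),
    last2 = if (n >= 2) (n - 1):n else
      stop("last2 window needs at least 2 nights", call. = FALSE),
    custom = {
      if (is.null(range) || !all(range %in% seq_len(n))) {
        stop("custom window range not addressable in the night list",
             call. = FALSE)
      }
      range
    }
  )
  if (length(idx) == 0) stop("empty window selection", call. = FALSE)
  m <- do.call(rbind, lapply(nights[idx], unclass))
  structure(colMeans(m)[indicator_names], class = "night_indicators")
}

#' Build the morning feedback shown after a validated night
#'
#' Mirrors the app's visual feedback: time in bed, total sleep time (both
#' as hh:mm, minutes rounded half-up) and sleep efficiency to one decimal.
#' Values are copied from the indicators, never re-derived.
#'
#' @param ind a \code{night_indicators} object.
#' @return a \code{feedback_summary} list with numeric fields and display
#'   strings.
#' @export
make_feedback <- function(ind) {
  stopifnot(inherits(ind, "night_indicators"))
  hhmm <- function(x) {
    m <- floor(x + 0.5)  # round half-up on minutes
    sprintf("%02d:%02d", m %/% 60, m %% 60)
  }
  structure(
    list(tib = ind[["tib"]], tst = ind[["tst"]], se = ind[["se"]],
         tib_display = hhmm(ind[["tib"]]),
         tst_display = hhmm(ind[["tst"]]),
         se_display = sprintf("%.1f", ind[["se"]])),
    class = "feedback_summary"
  )
}

#' Has the diary week been completed?
#'
#' @param entries list of validated [diary_entry()] objects.
#' @param required_days minimum number of completed nights (default 7, the
#'   Step-1 diary week).
#' @return TRUE iff at least \code{required_days} entries are present.
#' @export
diary_complete <- function(entries, required_days = 7) {
  stopifnot(required_days >= 1)
  length(entries) >= required_days
}

#' Read a sleep-diary CSV
#'
#' Expected columns: night_date, try_sleep_time, reported_sol_min, nwak,
#' reported_waso_min, final_wake_time, arise_time (ISO-8601 dates, HH:MM
#' clock times). Each row is validated through [diary_entry()] and
#' [derive_night()]; invalid rows are reported, not silently dropped.
#'
#' @param path CSV file path.
#' @return list with \code{entries} (validated \code{diary_entry} objects)
#'   and \code{errors} (data.frame of row numbers and messages).
#' @export
read_diary_csv <- function(path) {
  cols <- c("night_date", "try_sleep_time", "reported_sol_min", "nwak",
            "reported_waso_min", "final_wake_time", "arise_time")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(cols %in% names(df))) {
    stop("diary CSV missing columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  }
  entries <- list()
  errors <- data.frame(row = integer(), message = character())
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      e <- diary_entry(df$night_date[i], df$try_sleep_time[i],
                       as.numeric(df$reported_sol_min[i]),
                       as.numeric(df$nwak[i]),
                       as.numeric(df$reported_waso_min[i]),
                       df$final_wake_time[i], df$arise_time[i])
      derive_night(e)  # temporal validation
      e
    }, error = function(err) err)
    if (inherits(res, "error")) {
      errors <- rbind(errors,
                      data.frame(row = i, message = conditionMessage(res)))
    } else {
      entries[[length(entries) + 1]] <- res
    }
  }
  list(entries = entries, errors = errors)
}

#' Write diary entries to CSV
#'
#' Inverse of [read_diary_csv()]; writes the canonical column schema.
#'
#' @param entries list of [diary_entry()] objects.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_diary_csv <- function(entries, path) {
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(night_date = as.character(e$night_date),
               try_sleep_time = e$try_sleep_time,
               reported_sol_min = e$reported_sol,
               nwak = e$nwak,
               reported_waso_min = e$reported_waso,
               final_wake_time = e$final_wake_time,
               arise_time = e$arise_time)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
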