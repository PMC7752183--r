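# Synthetic-cohort simulator. Emulates the study population of a free
# sleep-intervention app: the adherence funnel (download -> screening ->
# eligibility -> Step-1 diary week -> Step-2 recommendations), the ISI
# severity mixture and pre/post trajectories, and nightly sleep diaries,
# so every downstream module runs with no real user data.

# truncated normal via inverse-CDF; exact truncation, vectorized
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(hi, max(lo, mean)), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# gamma draw parameterized by mean and SD; degenerate SD -> constant.
# Chosen for non-negative duration components: support [0, Inf) with the
# configured mean preserved exactly (a 0-truncated normal at these
# dispersions would inflate the mean far above its calibration value).
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Default cohort calibration
#'
#' The study conditions the simulator reproduces: 2069 downloaders; 76%
#' complete the screening interview; 49.1% of those score above the
#' clinical ISI threshold; 21.5% of eligible users complete the Step-1
#' diary week and 28.3% of those complete Step 2. Baseline ISI is a
#' two-component truncated normal (subclinical mean 10.02, SD 3.42 on
#' 0--14; clinical mean 18.2, SD 2.74 on 15--28). The Step-1 ISI change is
#' normal with mean -2.57 (the published 18.56 -> 15.99 drop) and SD 4.20
#' (inverted from the published paired t of 7.88 on 165 df); the Step-2
#' change has mean -0.96 and SD 4.63 (from t = 1.42 on 46 df). The diary
#' model drifts each indicator linearly between the published first-2-night
#' and last-2-night means of the Step-1 week, with the 10 Step-2 nights
#' around the published post-Step-2 means.
#'
#' @return a \code{cohort_config} list; every field can be overridden
#'   before passing to [generate_cohort()].
#' @export
default_config <- function() {
  minutes <- function(h, m, s = 0) h * 60 + m + s / 60
  structure(list(
    n_users = 2069L,
    p_screen = 0.76,
    p_eligible_given_screen = 0.491,
    p_step1_given_eligible = 0.215,
    p_step2_given_step1 = 0.283,
    isi_baseline = list(
      subclinical = list(mean = 10.02, sd = 3.42, lo = 0, hi = 14),
      clinical = list(mean = 18.2, sd = 2.74, lo = 15, hi = 28)
    ),
    step1_effect = list(mean_delta = -2.57, sd_delta = 4.20),
    step2_effect = list(mean_delta = -0.96, sd_delta = 4.63),
    demographics = list(
      responders = list(
        p_female = 0.67, age_mean = 43.11, age_sd = 13.8,
        education = c(middle_school = 0.202, high_school = 0.196,
                      university = 0.602),
        p_confined = 0.762, p_hcp = 0.056
      ),
      nonresponders = list(
        p_female = 0.59, age_mean = 44.83, age_sd = 14.4,
        education = c(middle_school = 0.168, high_school = 0.238,
                      university = 0.594),
        p_confined = 0.749, p_hcp = 0.057
      )
    ),
    behavior = list(
      subclinical = list(cds5 = c(4.53, 6.93), cigarettes = c(3.09, 6.40),
                         cage = c(0.65, 0.97), drinks = c(1.34, 2.09)),
      clinical = list(cds5 = c(6.45, 8.30), cigarettes = c(5.33, 8.68),
                      cage = c(0.78, 1.12), drinks = c(1.66, 3.18))
    ),
    familiarity_probs = c(no = 0.1, moderately = 0.3, yes = 0.6),
    diary_model = list(
      bedtime = list(mean = minutes(23, 0), sd = 60),  # minutes of day
      step1 = list(
        # first-2-night and last-2-night calibration means (minutes),
        # with between-user SDs; linear drift across nights 1..7
        tib = list(first2 = minutes(8, 56, 45), last2 = minutes(8, 40, 27),
                   sd = minutes(1, 34, 22)),
        sol = list(first2 = minutes(1, 31, 38), last2 = minutes(0, 58, 37),
                   sd = minutes(2, 39, 11)),
        waso = list(first2 = minutes(0, 48, 57), last2 = minutes(0, 42, 1),
                    sd = minutes(0, 55, 48)),
        twak = list(first2 = minutes(0, 58, 11), last2 = minutes(0, 39, 43),
                    sd = minutes(1, 9, 42)),
        nwak = list(first2 = 1.89, last2 = 1.67)
      ),
      step2 = list(
        tib = list(mean = minutes(8, 37, 45), sd = minutes(0, 50, 21)),
        sol = list(mean = minutes(1, 8, 50), sd = minutes(1, 25, 2)),
        waso = list(mean = minutes(0, 35, 58), sd = minutes(0, 32, 57)),
        twak = list(mean = minutes(0, 41, 17), sd = minutes(0, 32, 22)),
        nwak = list(mean = 1.35)
      )
    ),
    start_date = as.Date("2020-04-22")
  ), class = "cohort_config")
}

validate_config <- function(config) {
  probs <- c(config$p_screen, config$p_eligible_given_screen,
             config$p_step1_given_eligible, config$p_step2_given_step1)
  if (any(probs < 0 | probs > 1)) {
    stop("funnel probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (config$n_users < 0) stop("n_users must be >= 0", call. = FALSE)
  for (stratum in config$isi_baseline) {
    if (stratum$sd <= 0) stop("ISI baseline SDs must be > 0", call. = FALSE)
    if (stratum$lo >= stratum$hi) {
      stop("ISI truncation range invalid", call. = FALSE)
    }
  }
  if (config$step1_effect$sd_delta < 0 || config$step2_effect$sd_delta < 0) {
    stop("effect SDs must be >= 0", call. = FALSE)
  }
  invisible(config)
}

# integer ISI measurement of a clamped latent score. In the noiseless
# limit (sd_delta = 0) the exact mean-shifted value is returned so the
# closed-form limit post = baseline + mean_delta holds exactly.
isi_follow_up <- function(baseline, effect) {
  delta <- stats::rnorm(length(baseline), effect$mean_delta, effect$sd_delta)
  raw <- pmin(28, pmax(0, baseline + delta))
  if (effect$sd_delta > 0) round(raw) else raw
}

# distribute an integer ISI total over 7 items in 0..4
decompose_isi_items <- function(total) {
  items <- as.vector(stats::rmultinom(1, total, rep(1 / 7, 7)))
  while (any(items > 4)) {
    over <- which(items > 4)[1]
    room <- which(items < 4)
    take <- min(items[over] - 4, 4 - items[room[1]])
    items[over] <- items[over] - take
    items[room[1]] <- items[room[1]] + take
  }
  items
}

# draw one night's components for a set of users; redraws rows whose
# reported wakefulness would exceed the in-bed interval (entries must pass
# diary validation by construction)
draw_night_components <- function(n, tib_m, tib_sd, sol_m, sol_sd,
                                  waso_m, waso_sd, twak_m, twak_sd,
                                  nwak_m, bed_mean, bed_sd) {
  draw <- function(k) {
    data.frame(
      bed = round(stats::rnorm(k, bed_mean, bed_sd)),
      tib = stats::rnorm(k, tib_m, tib_sd),
      sol = round(rgamma_ms(k, sol_m, sol_sd)),
      waso = round(rgamma_ms(k, waso_m, waso_sd)),
      twak = round(rgamma_ms(k, twak_m, twak_sd))
    )
  }
  # a valid night needs reported wakefulness inside the in-bed interval
  # and the whole interval inside the noon-to-noon window of its night
  invalid <- function(z) {
    z$sol + z$waso + z$twak >= z$tib | z$tib < 60 | z$tib > 1320 |
      z$bed < 725 | z$bed + z$tib >= 2155
  }
  d <- draw(n)
  d$tib <- round(d$tib)
  bad <- which(invalid(d))
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    tries <- tries + 1
    r <- draw(length(bad))
    r$tib <- round(r$tib)
    d[bad, ] <- r
    bad <- bad[invalid(r)]
  }
  if (length(bad) > 0) {
    stop("diary model could not produce valid nights; check calibration",
         call. = FALSE)
  }
  d$nwak <- stats::rpois(n, nwak_m)
  d
}

make_diary_rows <- function(user_ids, night, night_date, comp) {
  arise <- comp$bed + comp$tib
  final <- arise - comp$twak
  data.frame(
    user_id = user_ids,
    night = night,
    night_date = as.character(night_date),
    try_sleep_time = format_clock(comp$bed),
    reported_sol_min = comp$sol,
    nwak = comp$nwak,
    reported_waso_min = comp$waso,
    final_wake_time = format_clock(final),
    arise_time = format_clock(arise),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort
#'
#' Draws the adherence funnel by stage-wise Bernoulli sampling, baseline
#' ISI from the two-component truncated-normal severity mixture (rounded
#' to integers within each stratum so eligibility is exact), follow-up ISI
#' as baseline plus a normal change clamped to [0, 28], demographics
#' conditional on responder status, and nightly diaries for Step-1/Step-2
#' completers whose components are drawn and whose TST/SE are always
#' derived, never drawn (the diary identity holds by construction). The
#' cohort is fully reproducible from (config, seed).
#'
#' @param config a [default_config()]-style \code{cohort_config}.
#' @param seed integer RNG seed; \code{NULL} uses the current RNG state.
#' @return a \code{sleep_cohort}: list with \code{users} (one row per
#'   downloader: demographics, funnel flags, ISI series, severity bands),
#'   \code{diaries} (one row per simulated night in the diary CSV schema),
#'   \code{config} and \code{seed}.
#' @export
generate_cohort <- function(config = default_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(config$n_users)
  empty_diaries <- data.frame(
    user_id = integer(), night = integer(), night_date = character(),
    try_sleep_time = character(), reported_sol_min = numeric(),
    nwak = integer(), reported_waso_min = numeric(),
    final_wake_time = character(), arise_time = character()
  )
  if (n == 0) {
    return(structure(list(users = data.frame(), diaries = empty_diaries,
                          config = config, seed = seed),
                     class = "sleep_cohort"))
  }

  screened <- stats::runif(n) < config$p_screen
  eligible <- screened & stats::runif(n) < config$p_eligible_given_screen
  step1 <- eligible & stats::runif(n) < config$p_step1_given_eligible
  step2 <- step1 & stats::runif(n) < config$p_step2_given_step1

  # demographics conditional on responder status
  dem <- config$demographics
  pick <- function(field) {
    ifelse(screened, dem$responders[[field]], dem$nonresponders[[field]])
  }
  gender <- ifelse(stats::runif(n) < pick("p_female"), "female", "male")
  age <- round(ifelse(screened,
                      rtrunc_norm(n, dem$responders$age_mean,
                                  dem$responders$age_sd, 18, 95),
                      rtrunc_norm(n, dem$nonresponders$age_mean,
                                  dem$nonresponders$age_sd, 18, 95)))
  edu_levels <- names(dem$responders$education)
  education <- character(n)
  for (grp in c(TRUE, FALSE)) {
    idx <- which(screened == grp)
    p <- if (grp) dem$responders$education else dem$nonresponders$education
    if (length(idx)) {
      education[idx] <- sample(edu_levels, length(idx), replace = TRUE,
                               prob = p)
    }
  }
  confined <- stats::runif(n) < pick("p_confined")
  hcp <- stats::runif(n) < pick("p_hcp")
  familiarity <- sample(0:2, n, replace = TRUE,
                        prob = config$familiarity_probs)

  # baseline ISI: severity stratum fixed by the eligibility draw
  isi_baseline <- rep(NA_real_, n)
  sub <- config$isi_baseline$subclinical
  cli <- config$isi_baseline$clinical
  i_sub <- which(screened & !eligible)
  i_cli <- which(eligible)
  isi_baseline[i_sub] <- round(rtrunc_norm(length(i_sub), sub$mean, sub$sd,
                                           sub$lo, sub$hi))
  isi_baseline[i_cli] <- round(rtrunc_norm(length(i_cli), cli$mean, cli$sd,
                                           cli$lo, cli$hi))

  # addiction/behavior covariates by severity stratum
  beh <- config$behavior
  draw_beh <- function(field, digits = 1) {
    out <- rep(NA_real_, n)
    out[i_sub] <- round(rgamma_ms(length(i_sub), beh$subclinical[[field]][1],
                                  beh$subclinical[[field]][2]), digits)
    out[i_cli] <- round(rgamma_ms(length(i_cli), beh$clinical[[field]][1],
                                  beh$clinical[[field]][2]), digits)
    out
  }

  isi_post1 <- rep(NA_real_, n)
  i_s1 <- which(step1)
  isi_post1[i_s1] <- isi_follow_up(isi_baseline[i_s1], config$step1_effect)
  isi_post2 <- rep(NA_real_, n)
  i_s2 <- which(step2)
  isi_post2[i_s2] <- isi_follow_up(isi_post1[i_s2], config$step2_effect)

  band_of <- function(x) {
    out <- rep(NA_character_, n)
    ok <- !is.na(x)
    out[ok] <- as.character(classify_isi(x[ok])$band)
    out
  }

  users <- data.frame(
    user_id = seq_len(n), age = age, gender = gender,
    education = education, hcp = hcp, confined = confined,
    familiarity = familiarity,
    cds5 = draw_beh("cds5"), cigarettes = draw_beh("cigarettes", 0),
    cage = draw_beh("cage"), drinks = draw_beh("drinks"),
    screened = screened, eligible = eligible,
    step1_completed = step1, step2_completed = step2,
    isi_baseline = isi_baseline, isi_post1 = isi_post1,
    isi_post2 = isi_post2,
    band_baseline = band_of(isi_baseline),
    band_post1 = band_of(isi_post1),
    band_post2 = band_of(isi_post2),
    stringsAsFactors = FALSE
  )

  # diaries: Step-1 week (nights 1..7, drifting) for Step-1 completers,
  # plus 10 Step-2 nights (8..17) for Step-2 completers
  dm <- config$diary_model
  diaries <- empty_diaries
  if (length(i_s1) > 0) {
    drift <- function(ind, t) {
      # anchors: nights 1-2 average to first2, nights 6-7 to last2
      ind$first2 + (t - 1.5) * (ind$last2 - ind$first2) / 5
    }
    rows <- vector("list", 17)
    for (t in 1:7) {
      comp <- draw_night_components(
        length(i_s1),
        drift(dm$step1$tib, t), dm$step1$tib$sd,
        drift(dm$step1$sol, t), dm$step1$sol$sd,
        drift(dm$step1$waso, t), dm$step1$waso$sd,
        drift(dm$step1$twak, t), dm$step1$twak$sd,
        drift(dm$step1$nwak, t),
        dm$bedtime$mean, dm$bedtime$sd
      )
      rows[[t]] <- make_diary_rows(i_s1, t, config$start_date + t - 1, comp)
    }
    if (length(i_s2) > 0) {
      for (t in 8:17) {
        comp <- draw_night_components(
          length(i_s2),
          dm$step2$tib$mean, dm$step2$tib$sd,
          dm$step2$sol$mean, dm$step2$sol$sd,
          dm$step2$waso$mean, dm$step2$waso$sd,
          dm$step2$twak$mean, dm$step2$twak$sd,
          dm$step2$nwak$mean,
          dm$bedtime$mean, dm$bedtime$sd
        )
        rows[[t]] <- make_diary_rows(i_s2, t, config$start_date + t - 1,
                                     comp)
      }
    }
    diaries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    diaries <- diaries[order(diaries$user_id, diaries$night), ]
    rownames(diaries) <- NULL
  }

  structure(list(users = users, diaries = diaries, config = config,
                 seed = seed),
            class = "sleep_cohort")
}

#' @export
print.sleep_cohort <- function(x, ...) {
  u <- x$users
  cat(sprintf("synthetic cohort: %d users (%d screened, %d eligible, %d Step-1, %d Step-2), %d diary nights\n",
              nrow(u), sum(u$screened), sum(u$eligible),
              sum(u$step1_completed), sum(u$step2_completed),
              nrow(x$diaries)))
  invisible(x)
}

#' Diary entries of one simulated user
#'
#' @param cohort a [generate_cohort()] result.
#' @param user_id user identifier.
#' @param nights which nights to return (default all).
#' @return list of [diary_entry()] objects in chronological order.
#' @export
user_diary_entries <- function(cohort, user_id, nights = NULL) {
  d <- cohort$diaries[cohort$diaries$user_id == user_id, ]
  if (!is.null(nights)) d <- d[d$night %in% nights, ]
  d <- d[order(d$night), ]
  lapply(seq_len(nrow(d)), function(i) {
    diary_entry(d$night_date[i], d$try_sleep_time[i], d$reported_sol_min[i],
                d$nwak[i], d$reported_waso_min[i], d$final_wake_time[i],
                d$arise_time[i])
  })
}

#' Per-user window means of derived night indicators
#'
#' Derives each night through [derive_night()] and aggregates the selected
#' window per user with [window_mean()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param user_ids users to include (default: Step-1 completers).
#' @param nights candidate nights (default the Step-1 week 1..7).
#' @param selector window passed to [window_mean()].
#' @return data.frame with one row per user: user_id plus the seven
#'   indicator means.
#' @export
diary_window_means <- function(cohort, user_ids = NULL, nights = 1:7,
                               selector = "all") {
  if (is.null(user_ids)) {
    user_ids <- cohort$users$user_id[cohort$users$step1_completed]
  }
  sub <- cohort$diaries[cohort$diaries$user_id %in% user_ids &
                          cohort$diaries$night %in% nights, ]
  sub <- sub[order(sub$user_id, sub$night), ]
  per_user <- split(sub, sub$user_id)
  rows <- lapply(per_user, function(d) {
    inds <- lapply(seq_len(nrow(d)), function(i) {
      derive_night(diary_entry(d$night_date[i], d$try_sleep_time[i],
                               d$reported_sol_min[i], d$nwak[i],
                               d$reported_waso_min[i], d$final_wake_time[i],
                               d$arise_time[i]))
    })
    w <- window_mean(inds, selector)
    c(user_id = d$user_id[1], unclass(w))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# report-layer paired t: constant differences print as a zero statistic
paired_t_or_zero <- function(d) {
  if (length(d) < 2 || stats::sd(d) == 0) {
    return(list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                p.value = 1))
  }
  paired_t(d)
}

#' Regenerate the study's summary tables from a synthetic cohort
#'
#' Recomputes every statistic class the feasibility analyses use on the
#' simulated data: responder vs non-responder demographics (chi-square and
#' pooled t), the adherence funnel with conditional percentages, severity
#' mixture by stratum, pre/post ISI outcomes with paired t tests and the
#' share of responders at or below the clinical threshold, severity-band
#' distributions along the program, and the Step-1 diary-week indicator
#' comparison (first 2 vs last 2 nights).
#'
#' @param cohort a [generate_cohort()] result.
#' @return a \code{study_tables} list with elements \code{funnel},
#'   \code{demographics}, \code{severity_mixture}, \code{isi_outcomes},
#'   \code{severity_distribution}, \code{diary_step1}.
#' @export
emit_study_tables <- function(cohort) {
  u <- cohort$users
  scr <- u[u$screened, ]
  counts <- c(downloaded = nrow(u), screened = sum(u$screened),
              eligible = sum(u$eligible),
              step1_completed = sum(u$step1_completed),
              step2_completed = sum(u$step2_completed))
  funnel <- funnel_percentages(counts)

  demographics <- NULL
  if (nrow(scr) > 0 && any(!u$screened)) {
    non <- u[!u$screened, ]
    demographics <- list(
      age_t = two_sample_t_pooled(mean(scr$age), stats::sd(scr$age),
                                  nrow(scr), mean(non$age),
                                  stats::sd(non$age), nrow(non)),
      gender_chisq = chi_square(rbind(table(factor(scr$gender,
                                                   c("female", "male"))),
                                      table(factor(non$gender,
                                                   c("female", "male"))))),
      confined_chisq = chi_square(rbind(table(factor(scr$confined,
                                                     c(TRUE, FALSE))),
                                        table(factor(non$confined,
                                                     c(TRUE, FALSE)))))
    )
  }

  severity_mixture <- NULL
  if (nrow(scr) > 0) {
    grp <- ifelse(scr$eligible, "clinical", "subclinical")
    severity_mixture <- do.call(rbind, lapply(split(scr, grp), function(g) {
      data.frame(stratum = if (g$eligible[1]) "clinical" else "subclinical",
                 n = nrow(g), isi_mean = mean(g$isi_baseline),
                 isi_sd = stats::sd(g$isi_baseline))
    }))
    rownames(severity_mixture) <- NULL
  }

  s1 <- u[u$step1_completed, ]
  s2 <- u[u$step2_completed, ]
  isi_outcomes <- list(
    step1 = if (nrow(s1) > 0) list(
      n = nrow(s1),
      baseline_mean = mean(s1$isi_baseline),
      post1_mean = mean(s1$isi_post1),
      paired = paired_t_or_zero(s1$isi_post1 - s1$isi_baseline),
      pct_at_or_below_threshold = 100 * mean(s1$isi_post1 <= 14)
    ),
    step2 = if (nrow(s2) > 0) list(
      n = nrow(s2),
      baseline_mean = mean(s2$isi_baseline),
      post1_mean = mean(s2$isi_post1),
      post2_mean = mean(s2$isi_post2),
      paired_post1_post2 = paired_t_or_zero(s2$isi_post2 - s2$isi_post1),
      paired_baseline_post2 = paired_t_or_zero(s2$isi_post2 - s2$isi_baseline),
      pct_at_or_below_threshold = 100 * mean(s2$isi_post2 <= 14),
      pct_severe = 100 * mean(s2$isi_post2 > 21)
    )
  )

  band_dist <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NULL)
    prop.table(table(factor(x, isi_band_labels)))
  }
  severity_distribution <- list(
    baseline_screened = band_dist(scr$band_baseline),
    baseline_step1 = band_dist(s1$band_baseline),
    post_step1 = band_dist(s1$band_post1),
    post_step2 = band_dist(s2$band_post2)
  )

  diary_step1 <- NULL
  if (nrow(s1) > 0 && nrow(cohort$diaries) > 0) {
    first2 <- diary_window_means(cohort, s1$user_id, 1:7, "first2")
    last2 <- diary_window_means(cohort, s1$user_id, 1:7, "last2")
    diary_step1 <- do.call(rbind, lapply(indicator_names, function(ind) {
      tt <- paired_t_or_zero(last2[[ind]] - first2[[ind]])
      data.frame(indicator = ind,
                 first2_mean = mean(first2[[ind]]),
                 first2_sd = stats::sd(first2[[ind]]),
                 last2_mean = mean(last2[[ind]]),
                 last2_sd = stats::sd(last2[[ind]]),
                 t = unname(tt$statistic), p = tt$p.value)
    }))
  }

  structure(list(funnel = funnel, demographics = demographics,
                 severity_mixture = severity_mixture,
                 isi_outcomes = isi_outcomes,
                 severity_distribution = severity_distribution,
                 diary_step1 = diary_step1),
            class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat("== adherence funnel ==\n")
  print(x$funnel)
  if (!is.null(x$severity_mixture)) {
    cat("\n== baseline severity mixture (screened users) ==\n")
    print(x$severity_mixture, digits = 4)
  }
  s1 <- x$isi_outcomes$step1
  if (!is.null(s1)) {
    cat(sprintf("\n== Step 1 (n=%d): ISI %.2f -> %.2f, paired t = %.2f, %.1f%% at or below threshold ==\n",
                s1$n, s1$baseline_mean, s1$post1_mean,
                unname(s1$paired$statistic), s1$pct_at_or_below_threshold))
  }
  s2 <- x$isi_outcomes$step2
  if (!is.null(s2)) {
    cat(sprintf("== Step 2 (n=%d): ISI %.2f -> %.2f -> %.2f ==\n",
                s2$n, s2$baseline_mean, s2$post1_mean, s2$post2_mean))
  }
  if (!is.null(x$diary_step1)) {
    cat("\n== Step-1 diary week, first 2 vs last 2 nights ==\n")
    print(x$diary_step1, digits = 4)
  }
  invisible(x)
}
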