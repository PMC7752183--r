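# shared in-code fixtures

make_entry <- function(night_date = "2020-04-23", try_sleep = "23:00",
                       sol = 0, nwak = 0, waso = 0, final_wake = "07:00",
                       arise = "07:00") {
  diary_entry(night_date, try_sleep, sol, nwak, waso, final_wake, arise)
}

# random valid entry: wakefulness drawn inside the in-bed interval
random_valid_entry <- function() {
  bed <- sample(c("21:30", "22:15", "23:00", "23:45", "00:30", "01:30"), 1)
  tib <- sample(300:600, 1)
  bed_min <- as.integer(substr(bed, 1, 2)) * 60 +
    as.integer(substr(bed, 4, 5))
  rel_bed <- if (bed_min < 720) bed_min + 1440 else bed_min
  wake_budget <- sample(0:(tib - 1), 1)
  parts <- diff(sort(c(0, sample(0:wake_budget, 2, replace = TRUE),
                       wake_budget)))
  twak <- parts[3]
  arise_rel <- rel_bed + tib
  final_rel <- arise_rel - twak
  clock <- function(m) sprintf("%02d:%02d", (m %% 1440) %/% 60, m %% 60)
  diary_entry("2020-04-23", clock(rel_bed), parts[1], sample(0:4, 1),
              parts[2], clock(final_rel), clock(arise_rel))
}

make_week <- function(n = 7, ...) {
  lapply(seq_len(n), function(i) make_entry(night_date = as.Date("2020-04-22") + i - 1, ...))
}

# aggregate indicators built directly, bypassing entry construction
make_indicators <- function(sol = 10, nwak = 1, twak = 10, waso = 10,
                            tib = 480) {
  tst <- tib - sol - waso - twak
  structure(c(sol = sol, nwak = nwak, twak = twak, waso = waso, tib = tib,
              tst = tst, se = 100 * tst / tib),
            class = "night_indicators")
}

moderate_isi <- function(occasion = "interview2") {
  score_isi(c(3, 3, 3, 2, 2, 2, 3), occasion = occasion)
}

# brute-force chi-square oracle: explicit double loop over cells
chisq_oracle <- function(x) {
  n <- sum(x)
  rs <- rowSums(x)
  cs <- colSums(x)
  stat <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (x[i, j] - e)^2 / e
    }
  }
  stat
}

random_table <- function(max_dim = 4) {
  r <- sample(2:max_dim, 1)
  c <- sample(2:max_dim, 1)
  matrix(sample(1:80, r * c, replace = TRUE), r, c)
}

small_config <- function(n = 200L) {
  cfg <- default_config()
  cfg$n_users <- n
  cfg
}
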