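#' Severity band labels for the Insomnia Severity Index
#'
#' The ISI total (0--28) partitions into four clinical bands:
#' 0--7 no clinically significant insomnia, 8--14 subthreshold insomnia,
#' 15--21 moderate insomnia, 22--28 severe insomnia.
#' @keywords internal
isi_band_labels <- c("none", "subthreshold", "moderate", "severe")

#' Classify an ISI total score
#'
#' Maps total scores to severity bands and derives the two protocol flags:
#' eligibility for the behavioral intervention (total > 14) and indication
#' for referral to a sleep specialist (total > 21, i.e. the severe band).
#'
#' @param total numeric vector of ISI totals, each in [0, 28]. Non-integer
#'   values are accepted (e.g. window means); band edges sit at 7/8, 14/15
#'   and 21/22 so the open intervals (7,8), (14,15), (21,22) classify with
#'   the lower boundary threshold (> 14 eligible, > 21 referral).
#' @return a data.frame with columns \code{total}, \code{band} (factor with
#'   levels none/subthreshold/moderate/severe), \code{eligible_for_intervention}
#'   and \code{referral_indicated}.
#' @examples
#' classify_isi(c(7, 8, 14, 15, 21, 22))
#' @export
classify_isi <- function(total) {
  if (!is.numeric(total) || anyNA(total)) {
    stop("ISI total must be numeric and non-missing", call. = FALSE)
  }
  if (any(total < 0 | total > 28)) {
    stop("ISI total out of range [0, 28]", call. = FALSE)
  }
  band <- cut(total, breaks = c(-Inf, 7, 14, 21, Inf), labels = isi_band_labels)
  data.frame(
    total = total,
    band = band,
    eligible_for_intervention = total > 14,
    referral_indicated = total > 21
  )
}

#' Score one ISI administration
#'
#' Sums the 7 items (each 0--4), classifies the total and attaches the
#' interview occasion. The total ranges 0--28.
#'
#' @param items integer vector of exactly 7 item responses, each in 0..4.
#' @param occasion which interview this response belongs to.
#' @param timestamp time of administration.
#' @return an object of class \code{isi_result} with fields \code{items},
#'   \code{occasion}, \code{timestamp}, \code{total}, \code{band},
#'   \code{eligible_for_intervention}, \code{referral_indicated}.
#' @examples
#' score_isi(c(3, 3, 3, 2, 2, 2, 3), occasion = "interview1")
#' @export
score_isi <- function(items,
                      occasion = c("interview1", "interview2", "interview3"),
                      timestamp = Sys.time()) {
  occasion <- match.arg(occasion)
  if (length(items) != 7) {
    stop("malformed interview: ISI requires exactly 7 items, got ",
         length(items), call. = FALSE)
  }
  if (!is.numeric(items) || anyNA(items) || any(items != floor(items)) ||
      any(items < 0 | items > 4)) {
    stop("malformed interview: ISI items must be integers in 0..4",
         call. = FALSE)
  }
  total <- sum(items)
  cls <- classify_isi(total)
  structure(
    list(
      items = as.integer(items),
      occasion = occasion,
      timestamp = timestamp,
      total = as.integer(total),
      band = as.character(cls$band),
      eligible_for_intervention = cls$eligible_for_intervention,
      referral_indicated = cls$referral_indicated
    ),
    class = "isi_result"
  )
}

#' @export
print.isi_result <- function(x, ...) {
  cat(sprintf("ISI (%s): total %d, band '%s'%s%s\n",
              x$occasion, x$total, x$band,
              if (x$eligible_for_intervention) ", eligible for intervention" else "",
              if (x$referral_indicated) ", referral indicated" else ""))
  invisible(x)
}

#' Default Acceptability E-scale layout
#'
#' The item list of the acceptance instrument is configurable; the default
#' assumes 6 items on a 1--5 scale, the first three forming the usability
#' subscale and the last three the satisfaction subscale. Subscores are
#' per-item means so the published "more than 3 out of 5" satisfaction
#' threshold applies on the item scale.
#'
#' @param usability_items,satisfaction_items integer indices into the item
#'   vector for each subscale.
#' @param scale_min,scale_max per-item response bounds.
#' @return a list describing the instrument layout.
#' @export
aes_config <- function(usability_items = 1:3, satisfaction_items = 4:6,
                       scale_min = 1, scale_max = 5) {
  if (length(intersect(usability_items, satisfaction_items)) > 0) {
    stop("AES subscales must not share items", call. = FALSE)
  }
  list(usability_items = usability_items,
       satisfaction_items = satisfaction_items,
       scale_min = scale_min, scale_max = scale_max,
       satisfaction_threshold = 3)
}

#' Score the Acceptability E-scale
#'
#' @param items numeric vector of item responses on the configured scale.
#' @param config instrument layout, see [aes_config()].
#' @return an \code{aes_result}: per-item mean \code{usability} and
#'   \code{satisfaction} subscores, the \code{satisfaction_positive} flag
#'   (strictly above 3 out of 5) and \code{n_items_per_subscale}.
#' @export
score_aes <- function(items, config = aes_config()) {
  need <- max(config$usability_items, config$satisfaction_items)
  if (length(items) < need) {
    stop("AES expects at least ", need, " items", call. = FALSE)
  }
  if (any(items < config$scale_min | items > config$scale_max)) {
    stop("AES item outside configured scale [", config$scale_min, ", ",
         config$scale_max, "]", call. = FALSE)
  }
  usability <- mean(items[config$usability_items])
  satisfaction <- mean(items[config$satisfaction_items])
  structure(
    list(usability = usability,
         satisfaction = satisfaction,
         satisfaction_positive = satisfaction > config$satisfaction_threshold,
         n_items_per_subscale = c(usability = length(config$usability_items),
                                  satisfaction = length(config$satisfaction_items))),
    class = "aes_result"
  )
}

#' Default trust-questionnaire layout
#'
#' Credibility items are scored 0--3 (positive attitude = subscore strictly
#' above 1); benevolence items sit on a 5-point agreement scale where the
#' top two categories (4 = somewhat agree, 5 = totally agree) count as a
#' positive attitude.
#'
#' @param credibility_items,benevolence_items item indices per subscale.
#' @param credibility_scale,benevolence_scale c(min, max) per-item bounds.
#' @return a list describing the instrument layout.
#' @export
etq_config <- function(credibility_items = 1:3, benevolence_items = 4:6,
                       credibility_scale = c(0, 3),
                       benevolence_scale = c(1, 5)) {
  if (length(intersect(credibility_items, benevolence_items)) > 0) {
    stop("ETQ subscales must not share items", call. = FALSE)
  }
  list(credibility_items = credibility_items,
       benevolence_items = benevolence_items,
       credibility_scale = credibility_scale,
       benevolence_scale = benevolence_scale,
       credibility_threshold = 1,
       benevolence_top_two = benevolence_scale[2] - 1)
}

#' Score the agent trust questionnaire
#'
#' @param items numeric vector of item responses.
#' @param config instrument layout, see [etq_config()].
#' @return an \code{etq_result} with \code{credibility} (mean on 0--3),
#'   \code{benevolence} (mean on the agreement scale), and the two
#'   positivity flags.
#' @export
score_etq <- function(items, config = etq_config()) {
  need <- max(config$credibility_items, config$benevolence_items)
  if (length(items) < need) {
    stop("ETQ expects at least ", need, " items", call. = FALSE)
  }
  cred_items <- items[config$credibility_items]
  ben_items <- items[config$benevolence_items]
  if (any(cred_items < config$credibility_scale[1] |
          cred_items > config$credibility_scale[2])) {
    stop("ETQ credibility item outside configured scale", call. = FALSE)
  }
  if (any(ben_items < config$benevolence_scale[1] |
          ben_items > config$benevolence_scale[2])) {
    stop("ETQ benevolence item outside configured scale", call. = FALSE)
  }
  credibility <- mean(cred_items)
  benevolence <- mean(ben_items)
  structure(
    list(credibility = credibility,
         benevolence = benevolence,
         credibility_positive = credibility > config$credibility_threshold,
         benevolence_positive = benevolence >= config$benevolence_top_two),
    class = "etq_result"
  )
}

#' Score the technology-familiarity item
#'
#' Single question ("Are you familiar with computer technologies?") with
#' answers No / Moderately / Yes scored 0 / 1 / 2.
#'
#' @param value integer in \{0, 1, 2\}.
#' @return a named integer (label attribute carries the answer text).
#' @export
score_familiarity <- function(value) {
  if (length(value) != 1 || !value %in% 0:2) {
    stop("familiarity must be a single value in {0, 1, 2}", call. = FALSE)
  }
  structure(as.integer(value), label = c("No", "Moderately", "Yes")[value + 1])
}
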