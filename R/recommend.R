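# Rule-based recommendation engine. Screened-low users get the fixed
# generic sleep-hygiene bundle; Step-2 users get personalized advice from a
# declarative, config-loaded rule table evaluated on the week's aggregated
# diary indicators and the latest ISI answers.
#
# The shipped default rule set is a reconstruction from standard behavioral
# sleep-medicine heuristics (time-in-bed restriction, stimulus control,
# fixed rise time, wind-down, specialist note); it lives entirely in a
# config file so a different rule table can replace it without code change.

#' Advice text catalog
#'
#' Maps every advice id the engine can emit to its display template.
#'
#' @return named character vector (id -> template text).
#' @export
advice_catalog <- function() {
  c(
    regular_wake_time = "Keep your usual wake-up time, including weekends.",
    morning_light = "Get exposed to sunlight in the morning.",
    quiet_dark_room = "Sleep in a quiet and dark room.",
    restrict_tib = "Reduce your time in bed by about {reduce_minutes} minutes: go to bed later or get up earlier.",
    stimulus_control = "If you are not asleep after about 20 minutes, leave the bed and return only when sleepy.",
    fixed_rise_time = "Get out of bed promptly at your planned rise time instead of lingering awake.",
    wind_down = "Adopt a calm wind-down routine before bed and keep the bedroom for sleep only.",
    limit_stimulants = "Avoid caffeine, alcohol and screens in the hours before bedtime.",
    see_specialist = "Your insomnia complaints remain severe; a consultation with a sleep specialist is advised."
  )
}

# names a rule condition may reference
rule_variables <- c("sol", "nwak", "twak", "waso", "tib", "tst", "se",
                    "isi_total", paste0("isi_item", 1:7))

# whitelist walk over the parsed condition: only comparisons, boolean
# algebra, arithmetic, parentheses, numeric/logical literals and known
# indicator names -- no function calls, no general code execution
check_condition_ast <- function(e) {
  allowed_ops <- c("<", "<=", ">", ">=", "==", "!=", "&", "|", "&&", "||",
                   "!", "(", "+", "-", "*", "/")
  if (is.numeric(e) || is.logical(e)) return(invisible(TRUE))
  if (is.name(e)) {
    if (!as.character(e) %in% rule_variables) {
      stop("condition references unknown name '", as.character(e), "'",
           call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% allowed_ops) {
      stop("condition uses disallowed operator or call '", op, "'",
           call. = FALSE)
    }
    for (i in seq_along(e)[-1]) check_condition_ast(e[[i]])
    return(invisible(TRUE))
  }
  stop("unevaluable condition element", call. = FALSE)
}

parse_condition <- function(txt, id) {
  expr <- tryCatch(str2lang(txt), error = function(e) {
    stop("rule '", id, "': condition does not parse: ", txt, call. = FALSE)
  })
  tryCatch(check_condition_ast(expr), error = function(e) {
    stop("rule '", id, "': ", conditionMessage(e), call. = FALSE)
  })
  expr
}

#' Load a recommendation rule set
#'
#' Accepts a YAML/JSON file path or an already-parsed list with a
#' \code{rules} element. Each rule needs a unique \code{id}, a
#' \code{condition} written in a restricted expression grammar (indicator
#' names, numbers, comparisons, and/or/not, arithmetic -- no function
#' calls), an \code{advice} id resolving to the text catalog, and an
#' integer \code{priority} (lower = more important). Optional
#' \code{params} are carried into the emitted advice.
#'
#' @param config file path or list.
#' @param catalog advice text catalog used to validate advice ids.
#' @return a \code{rule_set}: data.frame (id, condition, advice, priority)
#'   with parsed condition expressions and params attached as attributes.
#' @export
load_rules <- function(config, catalog = advice_catalog()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$rules)) {
    stop("rule config must contain a 'rules' list", call. = FALSE)
  }
  rules <- config$rules
  if (length(rules) == 0) {
    out <- data.frame(id = character(), condition = character(),
                      advice = character(), priority = integer())
    attr(out, "exprs") <- list()
    attr(out, "params") <- list()
    class(out) <- c("rule_set", "data.frame")
    return(out)
  }
  get_field <- function(r, f) {
    if (is.null(r[[f]])) {
      stop("rule missing required field '", f, "'", call. = FALSE)
    }
    r[[f]]
  }
  ids <- vapply(rules, get_field, "", f = "id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  conditions <- vapply(rules, get_field, "", f = "condition")
  advice <- vapply(rules, get_field, "", f = "advice")
  bad <- setdiff(advice, names(catalog))
  if (length(bad)) {
    stop("rule advice id not in catalog: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  priority <- vapply(rules, function(r) as.integer(get_field(r, "priority")),
                     integer(1))
  exprs <- Map(parse_condition, conditions, ids)
  params <- lapply(rules, function(r) r$params)
  out <- data.frame(id = ids, condition = conditions, advice = advice,
                    priority = priority, stringsAsFactors = FALSE)
  attr(out, "exprs") <- exprs
  attr(out, "params") <- params
  class(out) <- c("rule_set", "data.frame")
  out
}

#' The shipped default rule set
#'
#' @return a \code{rule_set} loaded from the package's default config.
#' @export
default_rules <- function() {
  load_rules(system.file("extdata", "default_rules.yaml", package = "somnus",
                         mustWork = TRUE))
}

new_advice_bundle <- function(items, source) {
  structure(list(items = items, source = source), class = "advice_bundle")
}

#' Generic sleep-hygiene advice for screened-low users
#'
#' The fixed three-item bundle handed to users whose screening ISI is at or
#' below the clinical threshold: keep a regular wake time, get morning
#' light, sleep in a quiet dark room.
#'
#' @return an \code{advice_bundle} with \code{source = "generic_hygiene"}.
#' @export
generic_hygiene <- function() {
  ids <- c("regular_wake_time", "morning_light", "quiet_dark_room")
  items <- data.frame(rule_id = NA_character_, advice = ids,
                      priority = seq_along(ids),
                      stringsAsFactors = FALSE)
  attr(items, "params") <- vector("list", length(ids))
  new_advice_bundle(items, "generic_hygiene")
}

#' Personalized recommendations from the diary week and latest ISI
#'
#' Evaluates every rule's condition on the weekly indicator aggregate and
#' the ISI answers; each firing rule contributes one advice item. Items are
#' ordered by priority, then rule id, so the output is independent of the
#' rule-file order. If no rule fires, the generic hygiene items are
#' returned, marked as the personalized bundle's fallback.
#'
#' @param week a \code{night_indicators} aggregate over the diary week
#'   (see [window_mean()]); at least 7 nights are expected upstream.
#' @param isi the latest [score_isi()] result (Interview 2).
#' @param rules a [load_rules()] rule set (default: the shipped config).
#' @return an \code{advice_bundle} with \code{source = "personalized"}.
#' @export
personalize <- function(week, isi, rules = default_rules()) {
  stopifnot(inherits(week, "night_indicators"), inherits(isi, "isi_result"))
  data <- as.list(unclass(week))
  data$isi_total <- isi$total
  items7 <- as.list(isi$items)
  names(items7) <- paste0("isi_item", 1:7)
  data <- c(data, items7)
  exprs <- attr(rules, "exprs")
  params <- attr(rules, "params")
  fired <- vapply(seq_along(exprs), function(i) {
    isTRUE(eval(exprs[[i]], envir = data, enclos = baseenv()))
  }, logical(1))
  if (!any(fired)) {
    bundle <- generic_hygiene()
    bundle$source <- "personalized"
    return(bundle)
  }
  items <- rules[fired, c("id", "advice", "priority"), drop = FALSE]
  names(items)[1] <- "rule_id"
  ord <- order(items$priority, items$rule_id)
  items <- items[ord, , drop = FALSE]
  rownames(items) <- NULL
  attr(items, "params") <- params[fired][ord]
  new_advice_bundle(items, "personalized")
}

#' Render an advice bundle to display text
#'
#' @param bundle an \code{advice_bundle}.
#' @param catalog advice text catalog.
#' @return character vector of rendered advice lines, in bundle order.
#' @export
render_advice <- function(bundle, catalog = advice_catalog()) {
  params <- attr(bundle$items, "params")
  vapply(seq_len(nrow(bundle$items)), function(i) {
    txt <- catalog[[bundle$items$advice[i]]]
    p <- if (is.null(params)) NULL else params[[i]]
    for (nm in names(p)) {
      txt <- gsub(paste0("{", nm, "}"), p[[nm]], txt, fixed = TRUE)
    }
    txt
  }, character(1))
}

#' @export
print.advice_bundle <- function(x, ...) {
  cat(sprintf("advice bundle (%s), %d item%s:\n", x$source, nrow(x$items),
              if (nrow(x$items) == 1) "" else "s"))
  for (line in render_advice(x)) cat("  -", line, "\n")
  invisible(x)
}
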