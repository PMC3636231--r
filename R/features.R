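# Website-usage coding: eight engagement variables coded two ways.
#  * binary (ever/never) for the features a member can plausibly never use
#    (food days, exercise days, exercise minutes, forum posts, friends);
#  * categorical per-30-day rates, normalized by the member's weight-entry
#    span, with thresholds at 4 events (roughly weekly), 120 exercise
#    minutes, and 20 points per 30 days; friends stay on raw counts.

#' Assemble per-member usage totals
#'
#' Combines the dated logs (log-in days, weight-entry days as distinct
#' calendar days) with the undated totals table.
#'
#' @param cohort cohort table from [compute_outcomes()]
#' @param entries cleaned weight entries
#' @param logins log-in events
#' @param usage undated totals (`member_id`, `food_entry_days`,
#'   `exercise_entry_days`, `exercise_minutes`, `sparkpoints`,
#'   `forum_posts`, `friends`)
#' @return a `data.frame` of totals, one row per cohort member
#' @export
usage_totals <- function(cohort, entries, logins, usage) {
  ids <- cohort$member_id
  e <- collapse_daily(entries[entries$member_id %in% ids, ])
  login_days <- tapply(logins$day[logins$member_id %in% ids],
                       logins$member_id[logins$member_id %in% ids],
                       function(d) length(unique(d)))
  weigh_days <- tapply(e$day, e$member_id, length)
  out <- data.frame(member_id = ids,
                    login_days = as.integer(login_days[ids]),
                    weight_entry_days = as.integer(weigh_days[ids]),
                    stringsAsFactors = FALSE)
  out <- merge(out, usage, by = "member_id", all.x = TRUE, sort = TRUE)
  if (any(is.na(out$login_days)))
    stop("cohort members missing from log-ins", call. = FALSE)
  if (any(out$login_days < out$weight_entry_days))
    stop("log-in days below weight-entry days (weigh-ins must generate ",
         "log-ins)", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Binary (ever/never) usage flags
#'
#' Log-in days, weight-entry days, and points are excluded from the
#' binary analysis: every cohort member has two or more log-ins and
#' weigh-ins, and nearly all have at least one point.
#'
#' @param totals output of [usage_totals()]
#' @return a `data.frame` of logical flags `any_food_day`,
#'   `any_exercise_day`, `any_exercise_minute`, `any_forum_post`,
#'   `any_friend`
#' @export
code_binary <- function(totals) {
  data.frame(member_id = totals$member_id,
             any_food_day = totals$food_entry_days >= 1,
             any_exercise_day = totals$exercise_entry_days >= 1,
             any_exercise_minute = totals$exercise_minutes >= 1,
             any_forum_post = totals$forum_posts >= 1,
             any_friend = totals$friends >= 1,
             stringsAsFactors = FALSE)
}

# rate category with a zero level: "0" only for an exact zero count;
# (0, cut) -> mid label; >= cut -> top label (inclusive boundary)
rate_cat3 <- function(count, rate, cut, labels) {
  if (any(count < 0)) stop("negative counts", call. = FALSE)
  lab <- ifelse(count == 0, labels[1],
                ifelse(rate < cut, labels[2], labels[3]))
  factor(lab, levels = labels)
}

#' Per-30-day usage rates and categories
#'
#' Rates are `count / (span / 30)` with the member's weight-entry span as
#' the exposure denominator (the same window that normalizes the
#' outcome). Categories: log-in and weight-entry days have no zero level
#' (every member has both) and split at 4 per 30 days; food days,
#' exercise days, and forum posts use 0 / 1-<4 / >=4; exercise minutes
#' 0 / 1-<120 / >=120; points 0 / 1-<20 / >=20. Friends are categorized
#' on raw counts (0 / 1 / >=2), not per 30 days. All ">=" boundaries are
#' inclusive; the zero level means an exactly zero count.
#'
#' @param totals output of [usage_totals()]
#' @param span_days weight-entry span (days) per member, aligned with
#'   `totals`
#' @return a `data.frame` with per-30-day rates (`rate_*`) and factor
#'   categories (`cat_*`)
#' @export
code_rates <- function(totals, span_days) {
  if (length(span_days) != nrow(totals))
    stop("span_days must align with totals", call. = FALSE)
  if (any(span_days < 1)) stop("span must be >= 1 day", call. = FALSE)
  s30 <- span_days / 30
  r <- function(count) count / s30

  rate_login <- r(totals$login_days)
  rate_weigh <- r(totals$weight_entry_days)
  rate_food <- r(totals$food_entry_days)
  rate_ex <- r(totals$exercise_entry_days)
  rate_exmin <- r(totals$exercise_minutes)
  rate_spark <- r(totals$sparkpoints)
  rate_forum <- r(totals$forum_posts)

  two_lab <- c("0 to <4", ">=4")
  data.frame(
    member_id = totals$member_id,
    rate_login_days = rate_login,
    rate_weight_entry_days = rate_weigh,
    rate_food_days = rate_food,
    rate_exercise_days = rate_ex,
    rate_exercise_minutes = rate_exmin,
    rate_sparkpoints = rate_spark,
    rate_forum_posts = rate_forum,
    cat_login_days = factor(ifelse(rate_login < 4, two_lab[1], two_lab[2]),
                            levels = two_lab),
    cat_weight_entry_days = factor(ifelse(rate_weigh < 4, two_lab[1],
                                          two_lab[2]), levels = two_lab),
    cat_food_days = rate_cat3(totals$food_entry_days, rate_food, 4,
                              c("0", "1 to <4", ">=4")),
    cat_exercise_days = rate_cat3(totals$exercise_entry_days, rate_ex, 4,
                                  c("0", "1 to <4", ">=4")),
    cat_exercise_minutes = rate_cat3(totals$exercise_minutes, rate_exmin,
                                     120, c("0", "1 to <120", ">=120")),
    cat_sparkpoints = rate_cat3(totals$sparkpoints, rate_spark, 20,
                                c("0", "1 to <20", ">=20")),
    cat_forum_posts = rate_cat3(totals$forum_posts, rate_forum, 4,
                                c("0", "1 to <4", ">=4")),
    cat_friends = factor(ifelse(totals$friends == 0, "0",
                                ifelse(totals$friends == 1, "1", ">=2")),
                         levels = c("0", "1", ">=2")),
    stringsAsFactors = FALSE)
}

#' Code all usage features for a cohort
#'
#' @param cohort cohort table from [compute_outcomes()]
#' @param entries cleaned weight entries
#' @param logins log-in events
#' @param usage undated totals
#' @return cohort joined with binary flags and rate categories
#' @export
code_usage <- function(cohort, entries, logins, usage) {
  totals <- usage_totals(cohort, entries, logins, usage)
  totals <- totals[match(cohort$member_id, totals$member_id), ]
  bin <- code_binary(totals)
  rates <- code_rates(totals, cohort$span_days)
  out <- merge(cohort, totals, by = "member_id", sort = TRUE)
  out <- merge(out, bin, by = "member_id", sort = TRUE)
  out <- merge(out, rates, by = "member_id", sort = TRUE)
  rownames(out) <- NULL
  out
}
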