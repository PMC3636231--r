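# Cohort construction: from cleaned weight entries to one analysis row per
# member, under the two-weigh-day requirement and the temporality rule
# (website use must not extend past the last weigh-in, so that usage
# precedes the measured outcome).

#' Retain members with at least two weight-entry days
#'
#' @param members roster (post baseline exclusions)
#' @param entries cleaned weight entries (day-collapsed internally)
#' @return list with `members` (retained), `excluded`, and `ledger`
#' @export
require_two_weigh_days <- function(members, entries) {
  e <- collapse_daily(entries)
  days <- table(e$member_id)
  keep_ids <- names(days)[days >= 2]
  keep <- members$member_id %in% keep_ids
  list(members = members[keep, , drop = FALSE],
       excluded = members[!keep, , drop = FALSE],
       ledger = data.frame(stage = "two_weigh_days",
                           entering = nrow(members),
                           excluded = sum(!keep),
                           retained = sum(keep)))
}

#' Apply the temporality rule
#'
#' Retains members whose last log-in falls on or before their last weight
#' entry. Because every website activity generates a date-stamped log-in,
#' this guarantees that all feature use happened between the first and
#' last weigh-in, so usage precedes the measured weight change.
#'
#' @param members roster (post two-weigh-day rule)
#' @param entries cleaned weight entries
#' @param logins log-in events (`member_id`, `day`)
#' @return list with `members`, `excluded`, and `ledger`
#' @export
apply_temporality_rule <- function(members, entries, logins) {
  e <- entries[entries$member_id %in% members$member_id, ]
  l <- logins[logins$member_id %in% members$member_id, ]
  no_login <- setdiff(unique(e$member_id), unique(l$member_id))
  if (length(no_login))
    stop("members have weight entries but no log-ins (violates the ",
         "every-activity-logs-in premise): ",
         paste(utils::head(no_login, 10), collapse = ", "), call. = FALSE)
  last_w <- tapply(e$day, e$member_id, max)
  last_l <- tapply(l$day, l$member_id, max)
  ids <- members$member_id
  keep <- as.numeric(last_l[ids]) <= as.numeric(last_w[ids])
  keep[is.na(keep)] <- FALSE
  list(members = members[keep, , drop = FALSE],
       excluded = members[!keep, , drop = FALSE],
       ledger = data.frame(stage = "temporality",
                           entering = nrow(members),
                           excluded = sum(!keep),
                           retained = sum(keep)))
}

#' Compute per-member outcomes
#'
#' For each cohort member: baseline weight is the first cleaned weight
#' entry, last weight the final one; the weight-entry span is the number
#' of days between them; net weight change (kg) is last minus baseline;
#' the per-30-day change is net change divided by span in 30-day units
#' (e.g., last 100 kg, baseline 108 kg, span 60 days gives -8 / 2 = -4 kg
#' per 30 days). Baseline BMI uses the imperial formula on the first
#' entry's weight.
#'
#' @param members cohort roster (post temporality rule); must carry
#'   `height_in` and the demographic columns
#' @param entries cleaned weight entries
#' @return a `data.frame` with one row per member: demographics,
#'   `first_day`, `last_day`, `span_days`, `baseline_lb`, `last_lb`,
#'   `baseline_bmi`, `net_kg`, `per30_kg`, `weight_entry_days`
#' @export
compute_outcomes <- function(members, entries) {
  e <- collapse_daily(entries[entries$member_id %in% members$member_id, ])
  parts <- split(e, e$member_id)
  rows <- lapply(parts, function(p) {
    data.frame(member_id = p$member_id[1],
               first_day = p$day[1], last_day = p$day[nrow(p)],
               baseline_lb = p$weight_lb[1], last_lb = p$weight_lb[nrow(p)],
               weight_entry_days = nrow(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$span_days <- out$last_day - out$first_day
  if (any(out$span_days < 1 & out$weight_entry_days >= 2))
    stop("zero span with two entry days should be impossible after ",
         "day-collapsing", call. = FALSE)
  out$net_kg <- lb_to_kg(out$last_lb - out$baseline_lb)
  out$per30_kg <- out$net_kg / (out$span_days / 30)
  cohort <- merge(members, out, by = "member_id", sort = TRUE)
  cohort$baseline_bmi <- bmi_imperial(cohort$baseline_lb, cohort$height_in)
  rownames(cohort) <- NULL
  cohort
}

SPAN_BREAKS <- c(0, 30, 60, 90, 183, 365, 548, 829, Inf)
SPAN_LABELS <- c("Up to 30 days", "31-60 days", "61-90 days", "91-183 days",
                 "184-365 days", "366-548 days", "549-829 days", ">829 days")

#' Stratify total weight change by weight-entry span
#'
#' Bins are inclusive of their printed upper bounds (a 30-day span falls
#' in "Up to 30 days"); an overflow bin catches spans beyond 829 days.
#'
#' @param cohort output of [compute_outcomes()]
#' @return a `data.frame`: span bin, n, percent, mean and SD of net
#'   weight change (kg); empty bins are retained with n = 0
#' @export
stratify_by_span <- function(cohort) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  bin <- cut(cohort$span_days, SPAN_BREAKS, labels = SPAN_LABELS,
             include.lowest = TRUE, right = TRUE)
  n <- as.integer(table(bin))
  mean_kg <- as.numeric(tapply(cohort$net_kg, bin, mean))
  sd_kg <- as.numeric(tapply(cohort$net_kg, bin, stats::sd))
  data.frame(span_bin = SPAN_LABELS, n = n,
             pct = round(100 * n / nrow(cohort), 1),
             mean_net_kg = mean_kg, sd_net_kg = sd_kg,
             stringsAsFactors = FALSE)
}

#' Fraction of members documenting weight regain
#'
#' A member counts (once) if the day-collapsed weight series contains any
#' later entry above any earlier one, i.e. the member posted at least one
#' weight reflecting regain.
#'
#' @param cohort cohort table (for the member set)
#' @param entries cleaned weight entries
#' @return proportion of cohort members with a documented up-tick
#' @export
fraction_documenting_regain <- function(cohort, entries) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  e <- collapse_daily(entries[entries$member_id %in% cohort$member_id, ])
  up <- vapply(split(e$weight_lb, e$member_id), function(w) {
    n <- length(w)
    if (n < 2) return(FALSE)
    any(w[-1] > cummin(w)[-n])
  }, logical(1))
  mean(cohort$member_id %in% names(up)[up])
}

#' Combine stage ledgers into a flow ledger
#'
#' @param ... stage ledgers (data frames with `stage`, `entering`,
#'   `excluded`, `retained`) in pipeline order
#' @return a single `data.frame`; an error is raised if counts do not
#'   chain (each stage must enter with the previous stage's retained)
#' @export
flow_ledger <- function(...) {
  led <- do.call(rbind, list(...))
  if (nrow(led) > 1) {
    chain <- led$entering[-1] == led$retained[-nrow(led)]
    if (!all(chain))
      stop("flow ledger does not chain at stage(s): ",
           paste(led$stage[-1][!chain], collapse = ", "), call. = FALSE)
  }
  if (!all(led$entering == led$excluded + led$retained))
    stop("flow ledger stage counts do not conserve", call. = FALSE)
  led
}
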