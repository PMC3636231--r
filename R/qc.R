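# Automated screening of self-reported weight entries.
#
# Four trajectory filters flag weight entries that look like data-entry
# errors (digit omissions, additions, transpositions, unexplained jumps):
#   F1  quadratic-trend residual screen (entry-level, >= 3 entry days)
#   F2  per-day percent-change screen   (entry-level, >= 3 entry days)
#   F3  pairwise absolute-jump screen   (entry-level, >= 3 entry days)
#   F4  whole-record range screen       (member-level, >= 2 entry days)
# Entries flagged here go to manual review; nothing is dropped until two
# reviewers (plus consensus) confirm an entry as erroneous.

#' Collapse weight entries to one per member-day
#'
#' Multiple same-day weights collapse to the last entry of the day (by
#' entry order), since the analysis unit is the weight-entry day. All
#' filters and cohort rules operate on day-collapsed entries.
#'
#' @param entries weight entries (`member_id`, `day`, `weight_lb`,
#'   `entry_id`)
#' @return the entries, one row per (member, day), sorted by member and day
#' @export
collapse_daily <- function(entries) {
  ord <- order(entries$member_id, entries$day, seq_len(nrow(entries)))
  e <- entries[ord, , drop = FALSE]
  keep <- !duplicated(e[c("member_id", "day")], fromLast = TRUE)
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply baseline outlier exclusions
#'
#' Drops members with implausible baseline attributes: age above 100
#' years, height above 120 inches (10 ft), or a baseline weight below
#' 100 lb or above 800 lb when the member has no follow-up weight entries.
#' The weight rule deliberately spares members with follow-up entries,
#' whose baseline can be adjudicated by the trajectory filters instead.
#'
#' @param members roster
#' @param entries weight entries (used to count follow-up entries)
#' @param thresholds a [qc_thresholds()]
#' @return list with `members` (retained rows), `excluded` (dropped rows
#'   plus a `reason` column), and `ledger` (stage counts)
#' @export
apply_baseline_exclusions <- function(members, entries,
                                      thresholds = qc_thresholds()) {
  orphans <- setdiff(unique(entries$member_id), members$member_id)
  if (length(orphans))
    stop("entries reference members absent from the roster: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)

  e <- collapse_daily(entries)
  n_days <- table(e$member_id)
  follow_up <- members$member_id %in% names(n_days)[n_days >= 2]

  bad_age <- members$age > thresholds$max_age
  bad_height <- members$height_in > thresholds$max_height_in
  bad_weight <- (members$weight_lb < thresholds$min_weight_lb |
                   members$weight_lb > thresholds$max_weight_lb) & !follow_up

  reason <- character(nrow(members))
  reason[bad_weight] <- "baseline_weight"
  reason[bad_height] <- "height"
  reason[bad_age] <- "age"
  multi <- bad_age + bad_height + bad_weight > 1
  reason[multi] <- apply(
    cbind(age = bad_age, height = bad_height,
          baseline_weight = bad_weight)[multi, , drop = FALSE], 1,
    function(r) paste(names(r)[r], collapse = "+"))
  drop <- bad_age | bad_height | bad_weight

  excluded <- members[drop, , drop = FALSE]
  excluded$reason <- reason[drop]
  list(members = members[!drop, , drop = FALSE],
       excluded = excluded,
       ledger = data.frame(stage = "baseline_exclusions",
                           entering = nrow(members),
                           excluded = sum(drop),
                           retained = sum(!drop)))
}

# per-member worker: entries must be day-collapsed and date-sorted
f1_member <- function(day, w, entry_id, th) {
  if (length(day) < 3) return(character(0))
  t <- day - mean(day)
  fit <- stats::lm.fit(cbind(1, t, t^2), w)
  r <- fit$residuals
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) return(character(0))
  entry_id[abs(r) > th$f1_sd_mult * s & abs(r) > th$f1_abs_lb]
}

f2_member <- function(day, w, entry_id, th) {
  n <- length(day)
  if (n < 3) return(character(0))
  rate <- abs(diff(w)) / (w[-n] * diff(day))
  hit <- rate > th$f2_rate
  unique(c(entry_id[-n][hit], entry_id[-1][hit]))
}

f3_member <- function(day, w, entry_id, th) {
  if (length(day) < 3) return(character(0))
  # entry i participates in a >= f3_jump_lb pair iff its distance to the
  # series max or min reaches the threshold (equivalent to the all-pairs
  # scan)
  hit <- (max(w) - w >= th$f3_jump_lb) | (w - min(w) >= th$f3_jump_lb)
  entry_id[hit]
}

f4_member <- function(day, w, entry_id, th) {
  if (length(day) < 2) return(NULL)
  if (max(w) - min(w) < th$f4_range_lb) return(NULL)
  list(max_entry = entry_id[which.max(w)], min_entry = entry_id[which.min(w)],
       range_lb = max(w) - min(w))
}

empty_flags <- function() {
  data.frame(entry_id = character(0), member_id = character(0),
             filter_id = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

# Run a set of per-member filter workers over day-collapsed entries in one
# pass; splitting row indices (not data frames) keeps this fast on large
# rosters.
filters_core <- function(entries, funs, th) {
  e <- collapse_daily(entries)
  sp <- split(seq_len(nrow(e)), e$member_id)
  acc_id <- vector("list", length(funs) * length(sp))
  acc_member <- acc_filter <- acc_detail <- acc_id
  k <- 0L
  members <- names(sp)
  for (j in seq_along(sp)) {
    ix <- sp[[j]]
    day <- e$day[ix]; w <- e$weight_lb[ix]; eid <- e$entry_id[ix]
    for (f in names(funs)) {
      if (f == "F4") {
        res <- funs[[f]](day, w, eid, th)
        if (is.null(res)) next
        k <- k + 1L
        acc_id[[k]] <- c(res$max_entry, res$min_entry)
        acc_member[[k]] <- rep(members[j], 2L)
        acc_filter[[k]] <- rep("F4", 2L)
        acc_detail[[k]] <- rep(sprintf("range=%.1flb", res$range_lb), 2L)
      } else {
        res <- funs[[f]](day, w, eid, th)
        if (!length(res)) next
        k <- k + 1L
        acc_id[[k]] <- res
        acc_member[[k]] <- rep(members[j], length(res))
        acc_filter[[k]] <- rep(f, length(res))
        acc_detail[[k]] <- rep("", length(res))
      }
    }
  }
  if (k == 0L) return(empty_flags())
  data.frame(entry_id = unlist(acc_id[seq_len(k)]),
             member_id = unlist(acc_member[seq_len(k)]),
             filter_id = unlist(acc_filter[seq_len(k)]),
             detail = unlist(acc_detail[seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' F1: quadratic-trend residual filter
#'
#' Fits `weight ~ day + day^2` by ordinary least squares per member and
#' flags entries whose residual exceeds both `f1_sd_mult` times the
#' residual SD (sample SD, n-1 denominator) and `f1_abs_lb` pounds.
#' Members with fewer than three entry days yield no flags; exactly three
#' entry days are interpolated exactly, so they also yield none.
#'
#' @param entries weight entries (any number of members)
#' @param thresholds a [qc_thresholds()]
#' @return flags: `entry_id`, `member_id`, `filter_id`, `detail`
#' @export
filter_f1_polynomial <- function(entries, thresholds = qc_thresholds()) {
  filters_core(entries, list(F1 = f1_member), thresholds)
}

#' F2: percent-per-day change filter
#'
#' Flags both members of every consecutive (date-sorted) entry pair whose
#' absolute change exceeds `f2_rate` of the earlier weight per day,
#' whether over a short or long interval (strict inequality).
#'
#' @inheritParams filter_f1_polynomial
#' @return flags as in [filter_f1_polynomial()]
#' @export
filter_f2_rate <- function(entries, thresholds = qc_thresholds()) {
  filters_core(entries, list(F2 = f2_member), thresholds)
}

#' F3: pairwise absolute-jump filter
#'
#' Flags both members of every entry pair (all pairs, not only
#' consecutive) differing by `f3_jump_lb` pounds or more (inclusive).
#'
#' @inheritParams filter_f1_polynomial
#' @return flags as in [filter_f1_polynomial()]
#' @export
filter_f3_jump <- function(entries, thresholds = qc_thresholds()) {
  filters_core(entries, list(F3 = f3_member), thresholds)
}

#' F4: whole-record range filter
#'
#' Member-level flag for a recorded range (max minus min) of
#' `f4_range_lb` pounds or more (inclusive) over the complete record, for
#' members with at least two entry days. The flag carries the extreme
#' (argmax/argmin) entries so they can be routed to review.
#'
#' @inheritParams filter_f1_polynomial
#' @return flags as in [filter_f1_polynomial()]; two rows per flagged
#'   member (the extreme entries), `detail` records the range
#' @export
filter_f4_range <- function(entries, thresholds = qc_thresholds()) {
  filters_core(entries, list(F4 = f4_member), thresholds)
}

#' Run all four automated filters
#'
#' Applies F1-F4 after day-collapsing, unions the flags with per-filter
#' provenance, and summarizes counts. When ground-truth error labels are
#' supplied, filter sensitivity is computed both overall and over the
#' filters' applicable domain (members with at least two entry days --
#' single-day members cannot be screened by any filter).
#'
#' @param members roster (baseline exclusions already applied)
#' @param entries weight entries
#' @param thresholds a [qc_thresholds()]
#' @param truth_entries optional ground-truth error table
#'   (`entry_id` column) from the generator
#' @return list with `flags` (all flag rows), `flagged_entries` (unique
#'   entry ids routed to review), and `summary` (counts, per-filter flag
#'   counts, and sensitivity/precision when truth is given)
#' @export
run_all_filters <- function(members, entries, thresholds = qc_thresholds(),
                            truth_entries = NULL) {
  entries <- entries[entries$member_id %in% members$member_id, , drop = FALSE]
  flags <- filters_core(entries, list(F1 = f1_member, F2 = f2_member,
                                      F3 = f3_member, F4 = f4_member),
                        thresholds)
  flagged <- unique(flags$entry_id)
  summary <- list(
    n_entries = nrow(entries),
    n_flagged_entries = length(flagged),
    n_flagged_members = length(unique(flags$member_id)),
    flags_per_filter = as.list(table(factor(flags$filter_id,
                                            c("F1", "F2", "F3", "F4")))))
  if (!is.null(truth_entries)) {
    e <- collapse_daily(entries)
    days <- table(e$member_id)
    multi <- names(days)[days >= 2]
    truth_ids <- intersect(truth_entries$entry_id, entries$entry_id)
    truth_multi <- truth_entries$entry_id[
      truth_entries$entry_id %in% e$entry_id[e$member_id %in% multi]]
    summary$sensitivity_overall <-
      if (length(truth_ids)) mean(truth_ids %in% flagged) else NA_real_
    summary$sensitivity_domain <-
      if (length(truth_multi)) mean(truth_multi %in% flagged) else NA_real_
    summary$precision <-
      if (length(flagged)) mean(flagged %in% truth_ids) else NA_real_
  }
  list(flags = flags, flagged_entries = flagged, summary = summary)
}
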