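# Manual-review workflow: two independent reviewers label each flagged
# entry as erroneous or valid; disagreements are settled by a consensus
# verdict. Inter-rater reliability is summarized by raw agreement and
# Cohen's kappa.

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement and `p_e` the expected agreement under independent
#' raters with the observed marginal verdict frequencies. Returns 1 when
#' both raters agree everywhere (including the degenerate one-category
#' case, where the formula is 0/0 but agreement is perfect).
#'
#' @param v1,v2 verdict vectors of equal length (any atomic type)
#' @return kappa in [-1, 1]
#' @export
#' @examples
#' cohen_kappa(rep(c("e", "v"), c(45, 55)),
#'             rep(c("e", "v", "e", "v"), c(40, 5, 5, 50)))
cohen_kappa <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("verdict vectors differ in length")
  if (!length(v1)) stop("no verdicts supplied")
  lev <- union(unique(v1), unique(v2))
  t1 <- table(factor(v1, lev)) / length(v1)
  t2 <- table(factor(v2, lev)) / length(v2)
  p_o <- mean(v1 == v2)
  p_e <- sum(t1 * t2)
  if (1 - p_e < .Machine$double.eps) {
    if (p_o == 1) return(1)
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Simulate two reviewers from ground truth
#'
#' Emulates the manual review of flagged entries: each reviewer reports
#' the ground-truth verdict, flipped independently with probability
#' `flip_prob`; the consensus verdict is the ground truth. Produces the
#' label tables [resolve_reviews()] consumes.
#'
#' @param flagged_entries entry ids routed to review
#' @param truth_entry_ids entry ids that are truly erroneous
#' @param flip_prob per-reviewer verdict flip probability
#' @param seed RNG seed
#' @return list with `labels` (entry_id, reviewer_id, verdict) and
#'   `consensus` (entry_id, verdict for all entries; used where reviewers
#'   disagree)
#' @export
simulate_reviews <- function(flagged_entries, truth_entry_ids,
                             flip_prob = 0.025, seed = 1L) {
  truth <- flagged_entries %in% truth_entry_ids
  with_seed(sub_seed(seed, 53L), {
    flip <- function() xor(truth, stats::runif(length(truth)) < flip_prob)
    verd <- function(x) ifelse(x, "erroneous", "valid")
    labels <- rbind(
      data.frame(entry_id = flagged_entries, reviewer_id = "R1",
                 verdict = verd(flip()), stringsAsFactors = FALSE),
      data.frame(entry_id = flagged_entries, reviewer_id = "R2",
                 verdict = verd(flip()), stringsAsFactors = FALSE))
    consensus <- data.frame(entry_id = flagged_entries,
                            verdict = verd(truth), stringsAsFactors = FALSE)
    list(labels = labels, consensus = consensus)
  })
}

#' Resolve reviewer labels into a confirmed-erroneous set
#'
#' Every flagged entry must carry a label from each of the two reviewers;
#' entries on which the reviewers disagree additionally need a consensus
#' verdict. The confirmed-erroneous set is the union of concordant
#' "erroneous" verdicts and consensus "erroneous" resolutions.
#'
#' @param flagged_entries entry ids that were flagged
#' @param labels data frame `entry_id`, `reviewer_id`, `verdict`
#'   (`"erroneous"` or `"valid"`), exactly two reviewers
#' @param consensus optional data frame `entry_id`, `verdict` used for
#'   disagreements
#' @return list with `confirmed` (entry ids), `agreement`, `kappa`,
#'   `n_reviewed`, and `verdict_table` (2x2 reviewer cross-table)
#' @export
resolve_reviews <- function(flagged_entries, labels, consensus = NULL) {
  bad <- setdiff(unique(labels$verdict), c("erroneous", "valid"))
  if (length(bad))
    stop("unknown verdicts: ", paste(bad, collapse = ", "), call. = FALSE)
  reviewers <- sort(unique(labels$reviewer_id))
  if (length(reviewers) != 2)
    stop("exactly two reviewers are required, got ",
         length(reviewers), call. = FALSE)
  if (anyDuplicated(labels[c("entry_id", "reviewer_id")]))
    stop("at most one label per (entry, reviewer)", call. = FALSE)

  get_verdicts <- function(r) {
    l <- labels[labels$reviewer_id == r, ]
    v <- l$verdict[match(flagged_entries, l$entry_id)]
    missing <- flagged_entries[is.na(v)]
    if (length(missing))
      stop(sprintf("reviewer %s is missing labels for: %s", r,
                   paste(utils::head(missing, 10), collapse = ", ")),
           call. = FALSE)
    v
  }
  v1 <- get_verdicts(reviewers[1])
  v2 <- get_verdicts(reviewers[2])

  agree <- v1 == v2
  disagreed <- flagged_entries[!agree]
  cons_v <- rep(NA_character_, length(flagged_entries))
  if (!is.null(consensus))
    cons_v <- consensus$verdict[match(flagged_entries, consensus$entry_id)]
  unresolved <- disagreed[is.na(cons_v[!agree])]
  if (length(unresolved))
    stop("entries lack a consensus verdict: ",
         paste(utils::head(unresolved, 10), collapse = ", "), call. = FALSE)

  final_err <- (agree & v1 == "erroneous") |
    (!agree & cons_v == "erroneous")

  list(confirmed = flagged_entries[final_err],
       agreement = mean(agree),
       kappa = cohen_kappa(v1, v2),
       n_reviewed = length(flagged_entries),
       verdict_table = table(reviewer1 = factor(v1, c("erroneous", "valid")),
                             reviewer2 = factor(v2, c("erroneous", "valid"))))
}

#' Drop confirmed-erroneous entries
#'
#' Removes the confirmed set from the entry table and reports the ledger:
#' counts, the percentage of all entries removed, and the percentage of
#' flagged entries confirmed (nearest integer).
#'
#' @param entries weight entries
#' @param confirmed entry ids confirmed erroneous (must all be present)
#' @param n_flagged number of entries that had been flagged (for the
#'   confirmed-fraction denominator); defaults to `length(confirmed)`
#' @return list with `entries` (cleaned) and `ledger` (named list of
#'   counts and percentages; `pct_removed` is rounded to 2 decimals)
#' @export
drop_confirmed_errors <- function(entries, confirmed,
                                  n_flagged = length(confirmed)) {
  absent <- setdiff(confirmed, entries$entry_id)
  if (length(absent))
    stop("confirmed entries absent from input: ",
         paste(utils::head(absent, 10), collapse = ", "), call. = FALSE)
  cleaned <- entries[!entries$entry_id %in% confirmed, , drop = FALSE]
  ledger <- list(
    n_entries = nrow(entries),
    n_confirmed = length(confirmed),
    n_flagged = n_flagged,
    n_retained = nrow(cleaned),
    pct_removed = round(100 * length(confirmed) / nrow(entries), 2),
    pct_confirmed = if (n_flagged > 0)
      round(100 * length(confirmed) / n_flagged) else NA_real_)
  list(entries = cleaned, ledger = ledger)
}
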