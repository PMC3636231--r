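# End-to-end orchestration: simulate (or load) -> QC -> cohort -> features
# -> regression, with a flow ledger accumulated across stages and a
# summary report. Each stage logs one structured line with row counts, so
# the flow diagram falls out of the logs.

stage_msg <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: data acquisition (simulation by default,
#' or a directory of CSVs), baseline exclusions, the four automated weight
#' filters, review resolution (simulated two-reviewer labels when ground
#' truth is available, otherwise user-supplied labels), removal of
#' confirmed errors, the two-weigh-day and temporality rules, outcome
#' computation, span stratification, usage coding, confounder screening,
#' BMI-adjusted univariable models, and backward stepwise selection. When
#' ground truth exists, filter sensitivity/precision and effect-recovery
#' summaries are added.
#'
#' @param config a [pipeline_config()]
#' @param input optional directory containing `members.csv`,
#'   `weights.csv`, `logins.csv`, `usage.csv` (plus optional ground-truth
#'   files), or a dataset list as returned by [simulate_dataset()];
#'   `NULL` simulates from `config$sim`
#' @param out_dir optional output directory; when given, ledgers
#'   (`flow_ledger.json`, `qc_ledger.json`), tables (`cohort.csv`,
#'   `features.csv`, `span_table.csv`, `flags.csv`), model results
#'   (`models.json`), and a plain-text `report.txt` are written
#' @param review_labels,review_consensus reviewer labels for real data
#'   (see [resolve_reviews()]); ignored when ground truth is present
#' @param dry_run print the stage plan and return without computing
#' @param verbose emit one structured message per stage
#' @return an object of class `wp_report`
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         out_dir = NULL, review_labels = NULL,
                         review_consensus = NULL, dry_run = FALSE,
                         verbose = FALSE) {
  if (!inherits(config, "wp_pipeline_config"))
    stop_config("config", "must be a wp_pipeline_config")
  stages <- c("data", "baseline_exclusions", "filters", "review",
              "two_weigh_days", "temporality", "outcomes", "features",
              "models")
  if (dry_run) {
    cat("pipeline stages:\n", paste(" -", stages, collapse = "\n"), "\n")
    return(invisible(stages))
  }

  data <- if (is.null(input)) {
    simulate_dataset(config$sim)
  } else if (is.character(input)) {
    read_dataset(input)
  } else input
  has_truth <- !is.null(data$truth_entries)
  stage_msg(verbose, "data", "members=%d weights=%d logins=%d",
            nrow(data$members), nrow(data$weights), nrow(data$logins))

  th <- config$thresholds
  base <- apply_baseline_exclusions(data$members, data$weights, th)
  stage_msg(verbose, "baseline_exclusions", "in=%d out=%d excluded=%d",
            base$ledger$entering, base$ledger$retained, base$ledger$excluded)

  entries <- data$weights[data$weights$member_id %in%
                            base$members$member_id, , drop = FALSE]
  fl <- run_all_filters(base$members, entries, th,
                        truth_entries = data$truth_entries)
  stage_msg(verbose, "filters", "flagged_entries=%d flagged_members=%d",
            fl$summary$n_flagged_entries, fl$summary$n_flagged_members)

  if (length(fl$flagged_entries)) {
    if (has_truth) {
      rv <- simulate_reviews(fl$flagged_entries,
                             data$truth_entries$entry_id,
                             flip_prob = config$review_flip_prob,
                             seed = config$sim$seed)
      review_labels <- rv$labels
      review_consensus <- rv$consensus
    }
    if (is.null(review_labels))
      stop("pipeline stage 'review' failed: flagged entries but no ",
           "reviewer labels supplied", call. = FALSE)
    res <- resolve_reviews(fl$flagged_entries, review_labels,
                           review_consensus)
  } else {
    res <- list(confirmed = character(0), agreement = NA_real_,
                kappa = NA_real_, n_reviewed = 0L)
  }
  dropped <- drop_confirmed_errors(entries, res$confirmed,
                                   n_flagged = length(fl$flagged_entries))
  stage_msg(verbose, "review", "reviewed=%d confirmed=%d agreement=%.3f",
            res$n_reviewed, length(res$confirmed), res$agreement)

  qc_ledger <- c(fl$summary, dropped$ledger,
                 list(agreement = res$agreement, kappa = res$kappa))
  cleaned <- dropped$entries

  two <- require_two_weigh_days(base$members, cleaned)
  stage_msg(verbose, "two_weigh_days", "in=%d out=%d",
            two$ledger$entering, two$ledger$retained)
  tmp <- apply_temporality_rule(two$members, cleaned, data$logins)
  stage_msg(verbose, "temporality", "in=%d out=%d",
            tmp$ledger$entering, tmp$ledger$retained)
  flow <- flow_ledger(base$ledger, two$ledger, tmp$ledger)

  cohort <- compute_outcomes(tmp$members, cleaned)
  span_table <- stratify_by_span(cohort)
  regain <- fraction_documenting_regain(cohort, cleaned)
  stage_msg(verbose, "outcomes", "cohort=%d regain_frac=%.3f",
            nrow(cohort), regain)

  features <- code_usage(cohort, cleaned, data$logins, data$usage)
  stage_msg(verbose, "features", "rows=%d", nrow(features))

  screen <- screen_confounders(cohort, alpha = config$screen_p)
  binary_vars <- c("any_food_day", "any_exercise_day",
                   "any_exercise_minute", "any_forum_post", "any_friend")
  cat_vars <- c("cat_login_days", "cat_weight_entry_days", "cat_food_days",
                "cat_exercise_days", "cat_exercise_minutes",
                "cat_sparkpoints", "cat_forum_posts", "cat_friends")
  binary_fits <- lapply(binary_vars, function(v) fit_usage_model(features, v))
  names(binary_fits) <- binary_vars
  cat_fits <- lapply(cat_vars, function(v) fit_usage_model(features, v))
  names(cat_fits) <- cat_vars
  stepwise <- fit_stepwise(features, retain_p = config$retain_p)
  stage_msg(verbose, "models", "stepwise_final=%s",
            paste(stepwise$final_terms, collapse = "+"))

  recovery <- if (has_truth) recovery_summary(config$sim, screen,
                                              binary_fits, cat_fits,
                                              stepwise) else NULL

  report <- list(config = config, flow = flow, qc = qc_ledger,
                 cohort = cohort, features = features,
                 span_table = span_table, regain_fraction = regain,
                 screen = screen, binary_fits = binary_fits,
                 cat_fits = cat_fits, stepwise = stepwise,
                 recovery = recovery)
  class(report) <- "wp_report"
  if (!is.null(out_dir)) write_report(report, out_dir, flags = fl$flags)
  report
}

# Compare fitted CIs with the generator's configured truths.
recovery_summary <- function(sim, screen, binary_fits, cat_fits, stepwise) {
  bmi_row <- screen$table[screen$table$candidate == "baseline_bmi", ]
  forum <- binary_fits$any_forum_post
  weigh <- cat_fits$cat_weight_entry_days
  w_term <- weigh$terms[grepl(">=4", weigh$terms$term), ]
  f_term <- forum$terms[1, ]
  list(
    beta_weigh = list(truth = sim$true_beta_weigh_freq,
                      estimate = w_term$estimate,
                      ci = c(w_term$ci_lo, w_term$ci_hi),
                      covered = w_term$ci_lo <= sim$true_beta_weigh_freq &
                        sim$true_beta_weigh_freq <= w_term$ci_hi),
    beta_forum = list(truth = sim$true_beta_forum,
                      estimate = f_term$estimate,
                      ci = c(f_term$ci_lo, f_term$ci_hi),
                      covered = f_term$ci_lo <= sim$true_beta_forum &
                        sim$true_beta_forum <= f_term$ci_hi),
    beta_bmi = list(truth = sim$true_beta_bmi,
                    estimate = bmi_row$estimate,
                    ci = c(bmi_row$ci_lo, bmi_row$ci_hi),
                    covered = isTRUE(bmi_row$ci_lo <= sim$true_beta_bmi &
                                       sim$true_beta_bmi <= bmi_row$ci_hi)),
    bmi_retained = isTRUE(bmi_row$retained),
    stepwise_keeps_weigh =
      "cat_weight_entry_days" %in% stepwise$final_terms)
}

#' @export
print.wp_report <- function(x, ...) {
  cat("== weightpipe report ==\n\nFlow ledger:\n")
  print(x$flow, row.names = FALSE)
  cat(sprintf("\nQC: %d/%d entries flagged; %d confirmed erroneous (%.2f%% of all)\n",
              x$qc$n_flagged_entries, x$qc$n_entries, x$qc$n_confirmed,
              x$qc$pct_removed))
  if (!is.na(x$qc$agreement))
    cat(sprintf("review agreement %.3f, kappa %.3f\n",
                x$qc$agreement, x$qc$kappa))
  if (!is.null(x$qc$sensitivity_domain))
    cat(sprintf("filter sensitivity %.3f (applicable domain), %.3f overall\n",
                x$qc$sensitivity_domain, x$qc$sensitivity_overall))
  cat(sprintf("\nCohort n = %d; regain documented by %.1f%% of members\n",
              nrow(x$cohort), 100 * x$regain_fraction))
  cat("\nWeight change by span:\n")
  print(x$span_table, row.names = FALSE, digits = 3)
  cat("\n"); print(x$screen)
  cat("\n"); print(x$stepwise)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' @param report a `wp_report`
#' @param dir output directory (created if needed)
#' @param flags optional flag table to write as `flags.csv`
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir, flags = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report$flow, file.path(dir, "flow_ledger.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$qc, file.path(dir, "qc_ledger.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(report$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(report$span_table, file.path(dir, "span_table.csv"),
                   row.names = FALSE)
  if (!is.null(flags))
    utils::write.csv(flags, file.path(dir, "flags.csv"), row.names = FALSE)

  fit_json <- function(f) list(variable = f$variable, outcome = f$outcome,
                               n = f$n, overall_p = f$overall_p,
                               terms = f$terms)
  models <- list(
    screen = report$screen$table,
    binary = lapply(report$binary_fits, fit_json),
    categorical = lapply(report$cat_fits, fit_json),
    stepwise = list(final_terms = report$stepwise$final_terms,
                    terms = report$stepwise$terms,
                    trace = report$stepwise$trace))
  if (!is.null(report$recovery)) models$recovery <- report$recovery
  jsonlite::write_json(models, file.path(dir, "models.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Plot a member's weight trajectory with flags
#'
#' Base-graphics view of one member's day-collapsed weight series, the
#' fitted quadratic trend used by filter F1, and any flagged entries.
#'
#' @param entries weight entries
#' @param member_id the member to plot
#' @param flags optional flag table (rows for this member are marked)
#' @param thresholds a [qc_thresholds()]
#' @return invisibly, the member's day-collapsed entries
#' @export
plot_member_trajectory <- function(entries, member_id, flags = NULL,
                                   thresholds = qc_thresholds()) {
  e <- collapse_daily(entries[entries$member_id == member_id, ])
  if (!nrow(e)) stop("no entries for member ", member_id, call. = FALSE)
  graphics::plot(e$day, e$weight_lb, type = "b", pch = 16,
                 xlab = "study day", ylab = "weight (lb)",
                 main = sprintf("member %s", member_id))
  if (nrow(e) >= 3) {
    t <- e$day - mean(e$day)
    fit <- stats::lm.fit(cbind(1, t, t^2), e$weight_lb)
    grid_day <- seq(min(e$day), max(e$day), length.out = 100)
    tg <- grid_day - mean(e$day)
    graphics::lines(grid_day,
                    cbind(1, tg, tg^2) %*% fit$coefficients,
                    lty = 2, col = "grey40")
  }
  if (!is.null(flags)) {
    hit <- e$entry_id %in% flags$entry_id[flags$member_id == member_id]
    if (any(hit))
      graphics::points(e$day[hit], e$weight_lb[hit], col = "red",
                       pch = 1, cex = 2, lwd = 2)
  }
  invisible(e)
}
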