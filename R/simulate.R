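# Synthetic event-log generator.
#
# Emulates a free online weight-loss program's data: a member roster with
# demographics, date-stamped weigh-ins and log-ins, undated per-member usage
# totals, and ground-truth labels for injected weight data-entry errors and
# true weight-change slopes. A latent engagement score couples log-in
# frequency, attrition, and weigh-in propensity, which reproduces the
# characteristic shape of such cohorts: many members with a single weigh-in,
# heavily right-skewed usage with a point mass at zero, and frequent
# weighers concentrated among engaged members.

STUDY_EPOCH <- as.Date("2008-02-01")

#' Simulate a member roster
#'
#' Draws demographics from truncated normals (age in [18, 100], BMI in
#' [17, 65], heights in [49, 78] inches), derives baseline weight from BMI
#' and height, and assigns registration dates, sources, and regions. A
#' small fraction of members (`outlier_rate`) receive an implausible
#' baseline attribute so that baseline exclusion logic has work to do.
#'
#' @param config a [sim_config()]
#' @return a `data.frame` with columns `member_id`, `age`, `sex`,
#'   `height_in`, `weight_lb` (recorded baseline, possibly a typo),
#'   `true_weight_lb` (the latent true weight used for trajectories; not
#'   written to CSV), `reg_day`, `reg_source`, `region`
#' @export
simulate_members <- function(config) {
  if (!inherits(config, "wp_sim_config"))
    stop_config("config", "must be a wp_sim_config")
  with_seed(sub_seed(config$seed, 11L), {
    n <- as.integer(config$n_members)
    sex <- ifelse(stats::runif(n) < config$frac_female, "female", "male")
    age <- round(rtruncnorm(n, config$age_mean, config$age_sd, 18, 100), 1)
    height <- ifelse(
      sex == "female",
      rtruncnorm(n, config$height_female_mean, config$height_female_sd, 49, 78),
      rtruncnorm(n, config$height_male_mean, config$height_male_sd, 49, 78))
    height <- round(height, 1)
    bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd, 17, 65)
    weight <- round(bmi * height^2 / BMI_FACTOR, 1)
    reg_day <- sample.int(config$reg_window_days, n, replace = TRUE) - 1L
    reg_source <- sample(c("friend", "search_ad", "other"), n,
                         replace = TRUE, prob = c(0.25, 0.35, 0.40))
    region <- sample(c("US-Midwest", "US-Northeast", "US-South", "US-West",
                       "other-country"), n, replace = TRUE,
                     prob = c(0.231, 0.149, 0.318, 0.167, 0.135))

    # implausible baseline attributes: data-entry slips in the recorded
    # age, height, or baseline weight; a weight typo corrupts only the
    # *recorded* first entry, the member's true trajectory stays sane
    true_weight <- weight
    is_out <- stats::runif(n) < config$outlier_rate
    out_type <- sample(c("age", "height", "weight"), n, replace = TRUE)
    k <- is_out & out_type == "age"
    age[k] <- round(stats::runif(sum(k), 101, 115))
    k <- is_out & out_type == "height"
    height[k] <- round(stats::runif(sum(k), 121, 170), 1)
    k <- which(is_out & out_type == "weight")
    for (i in k) {
      v <- NA_real_
      guard <- 0
      while ((is.na(v) || v == weight[i]) && guard < 10) {
        v <- corrupt_weight(weight[i],
                            sample(c("omit", "add", "transpose"), 1),
                            c(50, 150))
        guard <- guard + 1
      }
      if (!is.na(v)) weight[i] <- v
    }

    data.frame(member_id = sprintf("M%05d", seq_len(n)),
               age = age, sex = sex, height_in = height,
               weight_lb = weight, true_weight_lb = true_weight,
               reg_day = reg_day,
               reg_source = reg_source, region = region,
               stringsAsFactors = FALSE)
  })
}

#' Simulate event logs, usage totals, and ground truth
#'
#' For each member a log-in-day process runs forward from registration:
#' the number of log-in days is `1 + Geometric(p_i)` (a per-log-in stopping
#' process), gaps between log-in days are overdispersed counts, and each
#' log-in day after the first carries a weigh-in with member-specific
#' probability. The first log-in always records the baseline weight. True
#' weight follows a linear trajectory between first and last weigh-in whose
#' per-30-day slope depends on whether the member's realized weigh-in
#' frequency is at least `weigh_rate_threshold` per 30 days (coefficient
#' `true_beta_weigh_freq`), plus forum-use and BMI effects accruing per 30
#' days, slope heterogeneity, accrual noise, and per-entry measurement
#' noise. Data-entry errors are then injected via [inject_errors()].
#'
#' @param members roster from [simulate_members()]
#' @param config the same [sim_config()]
#' @return a list with `weights` (member_id, day, weight_lb, entry_id),
#'   `logins` (member_id, day), `usage` (one row per member with the six
#'   undated totals), `truth_entries` (per-entry error labels from
#'   [inject_errors()]), and `truth_members` (per-member true slope in kg
#'   per 30 days and the frequent-weigher indicator)
#' @export
simulate_activity <- function(members, config) {
  if (!inherits(config, "wp_sim_config"))
    stop_config("config", "must be a wp_sim_config")
  if (nrow(members) == 0) stop("members roster is empty", call. = FALSE)
  n <- nrow(members)
  ur <- config$usage_rates

  res <- with_seed(sub_seed(config$seed, 23L), {
    z <- stats::rnorm(n) # latent engagement

    p_stop <- stats::plogis(stats::qlogis(config$attrition_geometric_p) -
                              config$engagement_stop_slope * z)
    p_stop <- pmin(pmax(p_stop, 0.02), 0.95)
    n_login <- pmin(1L + stats::rgeom(n, p_stop), 400L)

    gap_mu <- exp(log(config$gap_median_days) -
                    config$engagement_gap_slope * z +
                    stats::rnorm(n, 0, config$gap_log_sd))
    gap_mu <- pmin(pmax(gap_mu, 2), 90)
    # engaged members return on a regular rhythm; casual members have
    # erratic, heavy-tailed gaps
    gap_sdlog_i <- pmin(pmax(config$gap_sdlog -
                               config$gap_regularity_slope * z, 0.5), 1.8)

    p_weigh <- stats::plogis(config$weigh_logit_intercept +
                               config$engagement_weigh_slope * z +
                               stats::rnorm(n, 0, config$weigh_logit_sd))

    # expand to one row per log-in day
    idx <- rep.int(seq_len(n), n_login)
    first <- !duplicated(idx)
    m_total <- length(idx)
    gap <- numeric(m_total)
    # heavy-tailed return gaps with a minimum turnaround: many members
    # resurface only after months
    gap[!first] <- pmax(1 + round(stats::rlnorm(sum(!first),
                                                log(gap_mu[idx[!first]]),
                                                gap_sdlog_i[idx[!first]])),
                        config$gap_min_days)
    day <- members$reg_day[idx] + unlist(lapply(
      split(gap, idx), cumsum), use.names = FALSE)
    keep <- day <= config$study_days
    idx <- idx[keep]; day <- day[keep]; first <- first[keep]

    # self-monitoring attrition: after a geometric number of log-ins a
    # member permanently stops entering weight while possibly continuing
    # to log in (these members fail the temporality rule later)
    q_stop_weigh <- stats::plogis(stats::qlogis(config$weigh_stop_p) -
                                    config$engagement_weigh_stop_slope * z)
    weigh_horizon <- 1L + stats::rgeom(n, pmin(pmax(q_stop_weigh, 0.02), 0.95))
    k <- stats::ave(seq_along(idx), idx, FUN = seq_along)
    eligible <- k <= weigh_horizon[idx]
    weigh <- eligible & (first | stats::runif(length(idx)) < p_weigh[idx])

    # forum usage (undated totals) -- drawn here because the forum effect
    # enters the weight trajectory; forum use follows its own social
    # latent, separate from the engagement score that drives weighing
    z_soc <- stats::rnorm(n)
    forum_any <- stats::runif(n) < stats::plogis(ur$forum_any_logit[1] +
                                                   ur$forum_any_logit[2] * z_soc)
    forum_posts <- ifelse(
      forum_any,
      1L + stats::rnbinom(n, size = ur$forum_size,
                          mu = ur$forum_mu * exp(0.5 * z_soc)),
      0L)

    bmi0 <- bmi_imperial(members$weight_lb, members$height_in)
    eta <- stats::rnorm(n, 0, config$slope_sd)

    # per-30-day slope given the realized frequent-weigher indicator;
    # forum/BMI net effects accrue per 30 days via the reference span so
    # the marginal net-kg regression slopes match the configured values
    slope_for <- function(fw) {
      config$baseline_drift + config$true_beta_weigh_freq * fw + eta +
        (config$true_beta_forum * forum_any +
           config$true_beta_bmi * (bmi0 - config$bmi_mean)) /
        config$span30_ref
    }
    weigh_summary <- function(idx, day, weigh) {
      widx <- idx[weigh]; wday <- day[weigh]
      wd_first <- rep(NA_real_, n); wd_last <- rep(NA_real_, n)
      wd_n <- rep(0L, n)
      agg_min <- tapply(wday, widx, min)
      mid <- as.integer(names(agg_min))
      wd_first[mid] <- as.numeric(agg_min)
      wd_last[mid] <- as.numeric(tapply(wday, widx, max))
      wd_n[mid] <- as.integer(tapply(wday, widx, length))
      span30 <- (wd_last - wd_first) / 30
      fw <- !is.na(span30) & span30 > 0 & wd_n >= 2 &
        (wd_n / span30) >= config$weigh_rate_threshold
      list(first = wd_first, span30 = span30, fw = fw)
    }

    ws <- weigh_summary(idx, day, weigh)
    slope30 <- slope_for(ws$fw)
    base_kg <- lb_to_kg(if (is.null(members$true_weight_lb))
      members$weight_lb else members$true_weight_lb)
    floor_kg <- pmax(-config$max_loss_kg, 38 - base_kg)

    # members whose trajectory would cross the physical floor leave the
    # program once the floor is reached (goal reached / drop-out), so the
    # linear slope holds exactly over every observed span
    intended <- slope30 * ws$span30
    binder <- !is.na(intended) & intended < floor_kg
    if (any(binder)) {
      cutoff <- rep(Inf, n)
      cutoff[binder] <- ws$first[binder] +
        floor(30 * floor_kg[binder] / slope30[binder])
      drop_row <- day > cutoff[idx]
      idx <- idx[!drop_row]; day <- day[!drop_row]
      weigh <- weigh[!drop_row]
      ws <- weigh_summary(idx, day, weigh)
      slope30 <- slope_for(ws$fw)
    }

    logins <- data.frame(member_id = members$member_id[idx], day = day,
                         stringsAsFactors = FALSE)
    widx <- idx[weigh]
    wday <- day[weigh]
    freq_weigher <- ifelse(is.na(ws$span30), NA, ws$fw)
    slope30[is.na(ws$span30)] <- NA_real_

    accr_sd <- config$accrual_sd * sqrt(pmax(ws$span30, 0))
    net_kg <- slope30 * ws$span30 +
      stats::rnorm(n, 0, ifelse(is.na(accr_sd), 0, accr_sd))
    net_kg <- pmax(net_kg, floor_kg) # accrual noise may still graze the floor

    # render weight entries along the linear trajectory + measurement noise
    true_base <- if (is.null(members$true_weight_lb)) members$weight_lb else
      members$true_weight_lb
    base_lb <- true_base[widx]
    first_day <- ws$first[widx]
    span_m <- ws$span30[widx] * 30
    frac <- ifelse(span_m > 0, (wday - first_day) / span_m, 0)
    net_lb <- kg_to_lb(ifelse(is.na(net_kg[widx]), 0, net_kg[widx]))
    w <- base_lb + net_lb * frac +
      stats::rnorm(length(widx), 0, config$meas_sd_lb)
    w <- pmax(round(w, 1), 75)
    # recorded baseline typos overwrite the first entry
    typo <- members$weight_lb != true_base
    first_entry <- !duplicated(widx)
    typo_row <- first_entry & typo[widx]
    w[typo_row] <- members$weight_lb[widx][typo_row]

    weights <- data.frame(member_id = members$member_id[widx], day = wday,
                          weight_lb = w,
                          entry_id = sprintf("W%06d", seq_along(widx)),
                          stringsAsFactors = FALSE)
    typo_truth <- data.frame(
      entry_id = weights$entry_id[typo_row],
      member_id = weights$member_id[typo_row],
      type = rep("baseline_typo", sum(typo_row)),
      original_lb = round(base_lb[typo_row], 1),
      corrupted_lb = w[typo_row], stringsAsFactors = FALSE)

    # remaining undated usage totals, tied to engagement and log-in volume
    n_login_real <- tabulate(idx, nbins = n)
    p_food <- stats::plogis(ur$food_logit[1] + ur$food_logit[2] * z)
    food_days <- stats::rbinom(n, n_login_real, p_food)
    p_ex <- stats::plogis(ur$exercise_logit[1] + ur$exercise_logit[2] * z)
    ex_days <- stats::rbinom(n, n_login_real, p_ex)
    ex_min <- round(ex_days * exp(stats::rnorm(
      n, ur$exercise_minutes_meanlog, ur$exercise_minutes_sdlog)))
    ex_min[ex_days == 0] <- 0L
    # some members log exercise minutes without a diary-day entry, so the
    # any-minute and any-day indicators are related but not identical
    extra <- stats::runif(n) < ur$exercise_extra_prob
    ex_min[extra] <- ex_min[extra] + round(exp(stats::rnorm(
      sum(extra), ur$exercise_minutes_meanlog, ur$exercise_minutes_sdlog)))
    spark <- ifelse(
      stats::runif(n) < ur$spark_zero, 0,
      round(n_login_real * stats::rgamma(n, shape = ur$spark_shape,
                                         scale = ur$spark_scale *
                                           exp(0.3 * z))))
    friends <- ifelse(
      stats::runif(n) < ur$friends_zero, 0L,
      stats::rnbinom(n, size = ur$friends_size,
                     mu = ur$friends_mu * exp(0.4 * z_soc)))

    usage <- data.frame(member_id = members$member_id,
                        food_entry_days = food_days,
                        exercise_entry_days = ex_days,
                        exercise_minutes = as.integer(ex_min),
                        sparkpoints = as.integer(spark),
                        forum_posts = as.integer(forum_posts),
                        friends = as.integer(friends),
                        stringsAsFactors = FALSE)

    truth_members <- data.frame(
      member_id = members$member_id,
      true_slope_kg_30d = slope30,
      freq_weigher = freq_weigher,
      forum_any = forum_any,
      stringsAsFactors = FALSE)

    list(weights = weights, logins = logins, usage = usage,
         truth_members = truth_members, typo_truth = typo_truth)
  })

  err <- inject_errors(res$weights, config, exclude = res$typo_truth$entry_id)
  res$weights <- err$entries
  res$truth_entries <- rbind(res$typo_truth, err$truth)
  res$typo_truth <- NULL
  res
}

# Corrupt one positive integer-ish weight with a digit-level operation.
# Returns a positive numeric or NA when the operation cannot apply (caller
# resamples the type).
corrupt_weight <- function(w, type, jump_range) {
  s <- as.character(round(w))
  switch(type,
    omit = {
      if (nchar(s) < 2) return(NA_real_)
      as.numeric(substr(s, 1, nchar(s) - 1))
    },
    add = as.numeric(paste0(s, sample(0:9, 1))),
    transpose = {
      if (nchar(s) < 2 || substr(s, 1, 1) == substr(s, 2, 2))
        return(NA_real_)
      d <- strsplit(s, "")[[1]]
      d[1:2] <- d[2:1]
      as.numeric(paste(d, collapse = ""))
    },
    jump = {
      delta <- stats::runif(1, jump_range[1], jump_range[2]) *
        sample(c(-1, 1), 1)
      if (w + delta <= 0) delta <- abs(delta)
      round(w + delta, 1)
    },
    stop("unknown corruption type: ", type))
}

#' Inject data-entry errors into weight entries
#'
#' Corrupts exactly `round(error_rate * n)` entries, mimicking the
#' data-entry slips seen in self-reported weights: omitting the last digit
#' (185 -> 18), appending a digit (185 -> 1850-1859), transposing the first
#' two digits (185 -> 815), or an unexplained jump of
#' `jump_range_lb` pounds. A corruption that cannot produce a positive,
#' changed value (e.g., transposing equal digits) is resampled to another
#' type. Every corrupted entry is recorded in the returned ground truth.
#'
#' @param entries weight entries (`member_id`, `day`, `weight_lb`,
#'   `entry_id`)
#' @param config a [sim_config()]; `error_rate` and `error_mix` are used
#' @param type optional single corruption type applied to all selected
#'   entries (for deterministic demonstrations); default samples from
#'   `error_mix`
#' @param exclude entry ids never selected for corruption
#' @return list with `entries` (corrupted copy) and `truth` (one row per
#'   corrupted entry: `entry_id`, `member_id`, `type`, `original_lb`,
#'   `corrupted_lb`)
#' @export
inject_errors <- function(entries, config, type = NULL,
                          exclude = character(0)) {
  if (!inherits(config, "wp_sim_config"))
    stop_config("config", "must be a wp_sim_config")
  if (any(entries$weight_lb <= 0))
    stop("entries must carry positive weights", call. = FALSE)
  n <- nrow(entries)
  n_err <- round(config$error_rate * n)
  truth <- data.frame(entry_id = character(0), member_id = character(0),
                      type = character(0), original_lb = numeric(0),
                      corrupted_lb = numeric(0), stringsAsFactors = FALSE)
  if (n_err == 0) return(list(entries = entries, truth = truth))

  eligible <- which(!entries$entry_id %in% exclude)
  with_seed(sub_seed(config$seed, 37L), {
    pick <- sample(eligible, n_err)
    types <- if (is.null(type)) {
      sample(names(config$error_mix), n_err, replace = TRUE,
             prob = config$error_mix)
    } else rep(type, n_err)
    orig <- entries$weight_lb[pick]
    corr <- numeric(n_err)
    for (i in seq_len(n_err)) {
      ti <- types[i]
      v <- corrupt_weight(orig[i], ti, config$jump_range_lb)
      guard <- 0
      while ((is.na(v) || v <= 0 || v == orig[i]) && guard < 20) {
        ti <- sample(names(config$error_mix), 1, prob = config$error_mix)
        v <- corrupt_weight(orig[i], ti, config$jump_range_lb)
        guard <- guard + 1
      }
      if (is.na(v) || v <= 0) { ti <- "jump"; v <- orig[i] + 100 }
      types[i] <- ti
      corr[i] <- v
    }
    entries$weight_lb[pick] <- corr
    truth <- data.frame(entry_id = entries$entry_id[pick],
                        member_id = entries$member_id[pick],
                        type = types, original_lb = orig,
                        corrupted_lb = corr, stringsAsFactors = FALSE)
    list(entries = entries, truth = truth)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: roster plus event logs, optionally written to CSV
#' (`members.csv`, `weights.csv`, `logins.csv`, `usage.csv`, and ground
#' truth files when requested). Dates are rendered ISO-8601 from the study
#' epoch (2008-02-01) at I/O only; in memory all dates are integer day
#' offsets.
#'
#' @param config a [sim_config()]
#' @param dir optional output directory for the CSV files
#' @param ground_truth write `ground_truth_entries.csv` /
#'   `ground_truth_members.csv` as well
#' @return (invisibly when writing) a list with `members`, `weights`,
#'   `logins`, `usage`, `truth_entries`, `truth_members`
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL,
                             ground_truth = FALSE) {
  members <- simulate_members(config)
  act <- simulate_activity(members, config)
  out <- c(list(members = members), act)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_dataset(out, dir, ground_truth = ground_truth)
    return(invisible(out))
  }
  out
}

day_to_date <- function(day) format(STUDY_EPOCH + day, "%Y-%m-%d")
date_to_day <- function(date) as.integer(as.Date(date) - STUDY_EPOCH)

#' Write a simulated dataset to headered CSV files
#'
#' @param data list as returned by [simulate_dataset()]
#' @param dir output directory
#' @param ground_truth also write the ground-truth tables
#' @return `dir`, invisibly
#' @export
write_dataset <- function(data, dir, ground_truth = FALSE) {
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  m <- data$members
  m$reg_date <- day_to_date(m$reg_day)
  wcsv(m[c("member_id", "age", "sex", "height_in", "weight_lb",
           "reg_date", "reg_source", "region")], "members.csv")
  w <- data$weights
  w$date <- day_to_date(w$day)
  wcsv(w[c("member_id", "date", "weight_lb", "entry_id")], "weights.csv")
  l <- data$logins
  l$date <- day_to_date(l$day)
  wcsv(l[c("member_id", "date")], "logins.csv")
  wcsv(data$usage, "usage.csv")
  if (ground_truth) {
    wcsv(data$truth_entries, "ground_truth_entries.csv")
    wcsv(data$truth_members, "ground_truth_members.csv")
  }
  invisible(dir)
}

#' Read a dataset from CSV files
#'
#' Inverse of [write_dataset()]; ISO dates become integer day offsets.
#'
#' @param dir directory holding `members.csv`, `weights.csv`, `logins.csv`,
#'   `usage.csv` (ground-truth files are read when present)
#' @return list with the same shape as [simulate_dataset()] output
#' @export
read_dataset <- function(dir) {
  need <- c("members.csv", "weights.csv", "logins.csv", "usage.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("input directory is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rcsv <- function(name) utils::read.csv(file.path(dir, name),
                                         stringsAsFactors = FALSE)
  m <- rcsv("members.csv")
  m$reg_day <- date_to_day(m$reg_date)
  m$reg_date <- NULL
  w <- rcsv("weights.csv")
  w$day <- date_to_day(w$date)
  w$date <- NULL
  l <- rcsv("logins.csv")
  l$day <- date_to_day(l$date)
  l$date <- NULL
  out <- list(members = m, weights = w, logins = l, usage = rcsv("usage.csv"))
  for (nm in c("entries", "members")) {
    f <- file.path(dir, sprintf("ground_truth_%s.csv", nm))
    if (file.exists(f))
      out[[paste0("truth_", nm)]] <- utils::read.csv(f,
                                                     stringsAsFactors = FALSE)
  }
  out
}
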