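#' @keywords internal
"_PACKAGE"

# Unit conversions and shared constants. Weights are stored in pounds
# everywhere; kilograms appear only in outcomes and reports.
LB_PER_KG <- 1 / 0.45359237
KG_PER_LB <- 0.45359237
BMI_FACTOR <- 703 # imperial BMI: 703 * lb / in^2

#' Convert pounds to kilograms
#' @param lb weight in pounds
#' @return weight in kilograms
#' @export
lb_to_kg <- function(lb) lb * KG_PER_LB

#' Convert kilograms to pounds
#' @param kg weight in kilograms
#' @return weight in pounds
#' @export
kg_to_lb <- function(kg) kg * LB_PER_KG

#' Body mass index from imperial measurements
#'
#' Uses the standard imperial formula `703 * weight / height^2`.
#'
#' @param weight_lb weight in pounds
#' @param height_in height in inches
#' @return BMI in kg/m^2
#' @export
#' @examples
#' bmi_imperial(150, 65) # 24.96
bmi_imperial <- function(weight_lb, height_in) {
  BMI_FACTOR * weight_lb / height_in^2
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_prop <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a proportion in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop_config(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate the membership of a large free online weight-loss program:
#' roughly 90% female, age around 34 (SD 11), BMI around 32 (SD 8), heavy
#' right-skew in feature usage with many zero users, and rapid attrition so
#' that most members record only a handful of weigh-ins. Engagement effects
#' on weight change are injected with known coefficients so downstream
#' models can be checked for parameter recovery.
#'
#' Weight-change structure: each member's true trajectory is linear between
#' first and last weigh-in with a per-30-day slope
#' `baseline_drift + true_beta_weigh_freq * I(weigh rate >= weigh_rate_threshold/30d) + N(0, slope_sd)`,
#' plus per-30-day accrual of the forum and BMI effects (see
#' `true_beta_forum`, `true_beta_bmi`, `span30_ref`), an accrual noise term
#' with SD `accrual_sd * sqrt(span/30)` kg, and i.i.d. measurement noise of
#' `meas_sd_lb` pounds on every rendered entry.
#'
#' @param n_members number of members to simulate (>= 1)
#' @param seed integer seed; identical configs give byte-identical output
#' @param frac_female proportion of female members
#' @param age_mean,age_sd age distribution (years), truncated to [18, 100]
#' @param bmi_mean,bmi_sd baseline BMI distribution (kg/m^2), truncated to
#'   [17, 65]
#' @param height_female_mean,height_female_sd,height_male_mean,height_male_sd
#'   height distributions (inches), truncated to [49, 78]
#' @param study_days last day of the study window (day 0 = first possible
#'   registration date); dates are integer day offsets from the study epoch
#' @param reg_window_days registrations fall uniformly on days
#'   `0 .. reg_window_days - 1`
#' @param outlier_rate proportion of members given an implausible baseline
#'   attribute (age > 100, height > 120 in, or weight < 100 / > 800 lb) to
#'   exercise the baseline exclusions
#' @param attrition_geometric_p per-log-in stop probability for a member of
#'   average engagement; each member's log-in count is
#'   `1 + Geometric(p_i)` with `p_i` shrunk for engaged members
#' @param gap_median_days median gap between successive log-in days for a
#'   member of average engagement
#' @param gap_min_days minimum return gap (days) between log-in days
#' @param gap_log_sd lognormal spread of per-member mean gaps
#' @param engagement_gap_slope,engagement_stop_slope,engagement_weigh_slope
#'   loadings of the latent engagement score on gap length, stop
#'   probability, and weigh-in propensity
#' @param weigh_logit_intercept log-odds that a log-in day (after the first)
#'   includes a weigh-in, for average engagement
#' @param weigh_logit_sd member-level noise on the weigh-in log-odds
#' @param usage_rates list of per-feature intensity parameters; see
#'   defaults for fields
#' @param true_beta_weigh_freq kg per 30 days added to the weight-change
#'   slope when weigh-in frequency is at least `weigh_rate_threshold` days
#'   per 30 days of span (negative = extra loss)
#' @param true_beta_forum net-kg effect (over a reference span) of having
#'   at least one forum post
#' @param true_beta_bmi net-kg effect per baseline BMI unit
#' @param span30_ref reference span in 30-day units used to convert the
#'   net-kg effects to per-30-day accrual rates; calibrated to the mean
#'   weigh-in span of the default final cohort
#' @param baseline_drift kg per 30 days of weight change common to all
#'   members
#' @param slope_sd SD (kg per 30 days) of member-level slope heterogeneity
#' @param accrual_sd SD scale (kg per sqrt(30 days)) of trajectory noise
#'   accruing with span
#' @param meas_sd_lb SD (pounds) of per-entry measurement noise
#' @param weigh_rate_threshold weigh-in days per 30 days defining the
#'   frequent-weigher indicator used by the injected effect
#' @param error_rate proportion of weight entries corrupted with a
#'   data-entry error
#' @param error_mix named proportions over the four corruption types
#'   `omit` (drop last digit), `add` (append a digit), `transpose` (swap the
#'   first two digits), `jump` (+/- uniform jump); must sum to 1
#' @param jump_range_lb magnitude range (pounds) of the `jump` corruption
#' @param max_loss_kg cap (kg) on true weight loss; true weight also never
#'   drops below about 38 kg (keeps trajectories physical)
#' @return an object of class `wp_sim_config` (a validated list)
#' @export
sim_config <- function(n_members = 26582,
                       seed = 1L,
                       frac_female = 0.907,
                       age_mean = 33.6, age_sd = 11,
                       bmi_mean = 31.6, bmi_sd = 7.7,
                       height_female_mean = 64.3, height_female_sd = 2.6,
                       height_male_mean = 69.7, height_male_sd = 2.8,
                       study_days = 829L,
                       reg_window_days = 89L,
                       outlier_rate = 0.018,
                       attrition_geometric_p = 0.14,
                       gap_median_days = 42,
                       gap_min_days = 4,
                       gap_sdlog = 0.7,
                       gap_regularity_slope = 0.1,
                       gap_log_sd = 1.0,
                       engagement_gap_slope = 1.3,
                       engagement_stop_slope = 1.0,
                       engagement_weigh_slope = 0.5,
                       weigh_logit_intercept = -0.3,
                       weigh_logit_sd = 0.6,
                       weigh_stop_p = 0.50,
                       engagement_weigh_stop_slope = 1.6,
                       usage_rates = list(
                         food_logit = c(-1.0, 0.8),
                         exercise_logit = c(-1.4, 0.8),
                         exercise_minutes_meanlog = log(35),
                         exercise_minutes_sdlog = 0.7,
                         exercise_extra_prob = 0.08,
                         forum_any_logit = c(-1.7, 0.55),
                         forum_size = 0.4,
                         forum_mu = 8,
                         friends_zero = 0.42,
                         friends_size = 0.5,
                         friends_mu = 2,
                         spark_zero = 0.06,
                         spark_shape = 0.8,
                         spark_scale = 20
                       ),
                       true_beta_weigh_freq = -5.09,
                       true_beta_forum = -1.55,
                       true_beta_bmi = -0.28,
                       span30_ref = 4.19,
                       baseline_drift = -0.1,
                       slope_sd = 0.9,
                       accrual_sd = 0.8,
                       meas_sd_lb = 1,
                       weigh_rate_threshold = 4,
                       error_rate = 0.002,
                       error_mix = c(omit = 0.3, add = 0.3,
                                     transpose = 0.3, jump = 0.1),
                       jump_range_lb = c(50, 150),
                       max_loss_kg = 60) {
  if (!is.numeric(n_members) || length(n_members) != 1 ||
      is.na(n_members) || n_members < 1 || n_members != floor(n_members))
    stop_config("n_members", "must be an integer >= 1")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_config("seed", "must be a single integer")
  check_prop(frac_female, "frac_female")
  check_prop(outlier_rate, "outlier_rate")
  check_prop(error_rate, "error_rate")
  if (!(attrition_geometric_p > 0 && attrition_geometric_p < 1))
    stop_config("attrition_geometric_p", "must be in (0, 1)")
  for (f in c("age_sd", "bmi_sd", "height_female_sd", "height_male_sd",
              "gap_median_days", "slope_sd", "accrual_sd", "meas_sd_lb",
              "span30_ref", "weigh_rate_threshold"))
    check_pos(get(f), f)
  check_pos(age_mean, "age_mean"); check_pos(bmi_mean, "bmi_mean")
  if (study_days < reg_window_days)
    stop_config("study_days", "must be >= reg_window_days")
  if (!is.numeric(error_mix) || is.null(names(error_mix)) ||
      !setequal(names(error_mix), c("omit", "add", "transpose", "jump")))
    stop_config("error_mix",
                "must be named proportions over omit/add/transpose/jump")
  if (any(error_mix < 0) || abs(sum(error_mix) - 1) > 1e-8)
    stop_config("error_mix", "must be non-negative and sum to 1")
  if (length(jump_range_lb) != 2 || any(jump_range_lb <= 0) ||
      jump_range_lb[1] > jump_range_lb[2])
    stop_config("jump_range_lb", "must be an increasing positive pair")
  check_pos(max_loss_kg, "max_loss_kg")

  cfg <- as.list(environment())
  class(cfg) <- "wp_sim_config"
  cfg
}

#' @export
print.wp_sim_config <- function(x, ...) {
  cat("<wp_sim_config>\n")
  cat(sprintf("  members: %d  seed: %s  study window: 0..%d days\n",
              x$n_members, format(x$seed), x$study_days))
  cat(sprintf("  injected effects (kg): weigh freq %.2f/30d, forum %.2f, BMI %.2f/unit\n",
              x$true_beta_weigh_freq, x$true_beta_forum, x$true_beta_bmi))
  cat(sprintf("  error rate: %.4f  mix: %s\n", x$error_rate,
              paste(sprintf("%s %.2f", names(x$error_mix), x$error_mix),
                    collapse = ", ")))
  invisible(x)
}

#' Quality-control filter thresholds
#'
#' The defaults are the standard screening rules for self-reported weight
#' series: F1 flags points whose quadratic-trend residual exceeds both
#' `f1_sd_mult` residual SDs and `f1_abs_lb` pounds; F2 flags consecutive
#' entries implying more than `f2_rate` body-weight change per day; F3 flags
#' any entry pair differing by at least `f3_jump_lb` pounds; F4 flags
#' members whose recorded range (max - min) is at least `f4_range_lb`
#' pounds. Baseline exclusions drop members with age above `max_age`,
#' height above `max_height_in`, or a baseline weight outside
#' [`min_weight_lb`, `max_weight_lb`] with no follow-up entries.
#'
#' @param f1_sd_mult residual SD multiplier for F1
#' @param f1_abs_lb absolute residual floor (lb) for F1
#' @param f2_rate fractional body-weight change per day for F2 (strict >)
#' @param f3_jump_lb pairwise absolute change (lb) for F3 (inclusive >=)
#' @param f4_range_lb whole-record range (lb) for F4 (inclusive >=)
#' @param max_age,max_height_in,min_weight_lb,max_weight_lb baseline
#'   exclusion bounds
#' @return an object of class `wp_qc_thresholds`
#' @export
qc_thresholds <- function(f1_sd_mult = 3, f1_abs_lb = 10,
                          f2_rate = 0.02, f3_jump_lb = 50,
                          f4_range_lb = 100,
                          max_age = 100, max_height_in = 120,
                          min_weight_lb = 100, max_weight_lb = 800) {
  for (f in c("f1_sd_mult", "f1_abs_lb", "f2_rate", "f3_jump_lb",
              "f4_range_lb", "max_age", "max_height_in", "min_weight_lb",
              "max_weight_lb"))
    check_pos(get(f), f)
  if (min_weight_lb >= max_weight_lb)
    stop_config("min_weight_lb", "must be < max_weight_lb")
  th <- as.list(environment())
  th$f <- NULL
  class(th) <- "wp_qc_thresholds"
  th
}

#' Pipeline configuration
#'
#' @param sim a [sim_config()] (used when the pipeline simulates its input)
#' @param thresholds a [qc_thresholds()]
#' @param screen_p significance level for the confounder screen
#' @param retain_p retention p-value for backward stepwise selection
#' @param review_flip_prob per-reviewer probability that a simulated
#'   reviewer verdict contradicts ground truth
#' @return an object of class `wp_pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = qc_thresholds(),
                            screen_p = 0.05,
                            retain_p = 0.20,
                            review_flip_prob = 0.025) {
  if (!inherits(sim, "wp_sim_config"))
    stop_config("sim", "must be a wp_sim_config")
  if (!inherits(thresholds, "wp_qc_thresholds"))
    stop_config("thresholds", "must be a wp_qc_thresholds")
  if (!(screen_p > 0 && screen_p < 1)) stop_config("screen_p", "must be in (0,1)")
  if (!(retain_p > 0 && retain_p < 1)) stop_config("retain_p", "must be in (0,1)")
  check_prop(review_flip_prob, "review_flip_prob")
  cfg <- list(sim = sim, thresholds = thresholds, screen_p = screen_p,
              retain_p = retain_p, review_flip_prob = review_flip_prob)
  class(cfg) <- "wp_pipeline_config"
  cfg
}

# Run `expr` under a deterministic sub-seed without disturbing the caller's
# RNG stream. Sub-streams per pipeline stage are derived from one base seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% 2147483647L)
}

# Truncated normal draws via inverse-CDF so draws stay deterministic and
# vectorized under a fixed seed.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}
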