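test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_members = 0), "n_members")
  expect_error(sim_config(frac_female = 1.2), "frac_female")
  expect_error(sim_config(age_sd = -1), "age_sd")
  expect_error(sim_config(error_mix = c(omit = 0.5, add = 0.5,
                                        transpose = 0.2, jump = 0)),
               "error_mix")
  expect_error(sim_config(error_mix = c(omit = 1, bad = 0)), "error_mix")
  expect_s3_class(sim_config(n_members = 10), "wp_sim_config")
})

test_that("identical configs give byte-identical datasets", {
  cfg <- sim_config(n_members = 400, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(cfg, dir = d1, ground_truth = TRUE)
  simulate_dataset(cfg, dir = d2, ground_truth = TRUE)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  d3 <- tempfile()
  simulate_dataset(sim_config(n_members = 400, seed = 8), dir = d3)
  expect_false(identical(readLines(file.path(d1, "weights.csv")),
                         readLines(file.path(d3, "weights.csv"))))
})

test_that("roster distributions match the configured targets", {
  m <- simulate_members(sim_config(n_members = 1000, seed = 1,
                                   outlier_rate = 0))
  p <- 0.907
  expect_lt(abs(mean(m$sex == "female") - p), 3 * sqrt(p * (1 - p) / 1000))
  expect_true(all(m$age >= 18 & m$age <= 100))
  expect_true(all(m$height_in >= 49 & m$height_in <= 78))
  expect_true(all(m$weight_lb > 0))
  bmi <- bmi_imperial(m$weight_lb, m$height_in)
  expect_lt(abs(mean(bmi) - 31.6), 1)
})

test_that("events respect registration dates and the log-in premise", {
  cfg <- sim_config(n_members = 500, seed = 3)
  d <- simulate_dataset(cfg)
  reg <- d$members$reg_day[match(d$logins$member_id, d$members$member_id)]
  expect_true(all(d$logins$day >= reg))
  # every weight-entry date is also a log-in date for that member
  wkey <- paste(d$weights$member_id, d$weights$day)
  lkey <- paste(d$logins$member_id, d$logins$day)
  expect_true(all(wkey %in% lkey))
  expect_true(all(d$weights$weight_lb > 0))
})

test_that("usage totals are right-skewed with point masses at zero", {
  d <- simulate_dataset(sim_config(n_members = 2000, seed = 5))
  u <- d$usage
  expect_gte(mean(u$forum_posts == 0), 0.5)
  for (v in c("forum_posts", "friends", "sparkpoints")) {
    expect_lte(median(u[[v]]), mean(u[[v]]))
  }
  expect_true(all(u$food_entry_days >= 0))
})

test_that("no corruption is recorded when error sources are off", {
  d <- simulate_dataset(sim_config(n_members = 300, seed = 2,
                                   error_rate = 0, outlier_rate = 0))
  expect_identical(nrow(d$truth_entries), 0L)
})

test_that("inject_errors corrupts exactly the requested count", {
  cfg <- sim_config(n_members = 10, seed = 4, error_rate = 0.01)
  entries <- tiny_entries(sprintf("M%04d", rep(1:1000, each = 10)),
                          day = rep(seq(0, 90, 10), 1000),
                          weight_lb = round(runif(10000, 120, 300), 1))
  entries$entry_id <- sprintf("W%05d", seq_len(10000))
  out <- inject_errors(entries, cfg)
  expect_identical(nrow(out$truth), 100L)
  expect_true(all(out$entries$weight_lb > 0))
  changed <- out$entries$weight_lb != entries$weight_lb
  expect_identical(sort(entries$entry_id[changed]), sort(out$truth$entry_id))
})

test_that("digit corruption follows the slip taxonomy", {
  cfg <- sim_config(n_members = 10, seed = 1, error_rate = 1)
  one <- tiny_entries("M1", day = 0, weight_lb = 185)
  expect_equal(inject_errors(one, cfg, type = "omit")$entries$weight_lb, 18)
  expect_equal(inject_errors(one, cfg, type = "transpose")$entries$weight_lb,
               815)
  add <- inject_errors(one, cfg, type = "add")$entries$weight_lb
  expect_true(add >= 1850 && add <= 1859)
  jump <- inject_errors(one, cfg, type = "jump")$entries$weight_lb
  expect_true(abs(jump - 185) >= 50 && abs(jump - 185) <= 150)
})

test_that("member-level ground truth tracks the frequent-weigher rule", {
  cfg <- sim_config(n_members = 2000, seed = 11, error_rate = 0,
                    outlier_rate = 0)
  d <- simulate_dataset(cfg)
  e <- collapse_daily(d$weights)
  sp <- split(e$day, e$member_id)
  for (m in sample(names(sp)[lengths(sp) >= 2], 50)) {
    days <- sp[[m]]
    rate <- length(days) / ((max(days) - min(days)) / 30)
    expect_identical(
      unname(rate >= 4),
      d$truth_members$freq_weigher[d$truth_members$member_id == m],
      label = m)
  }
})
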