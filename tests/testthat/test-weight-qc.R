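test_that("baseline exclusions follow the outlier rules", {
  m <- tiny_members(sprintf("M%d", 1:5))
  m$age <- c(101, 35, 35, 35, 35)
  m$height_in <- c(65, 121, 65, 65, 65)
  m$weight_lb <- c(180, 180, 99, 99, 180)
  # M3: 99 lb with follow-up entries (spared); M4: 99 lb, single entry day
  e <- rbind(tiny_entries("M3", c(0, 10, 20), c(99, 100, 101)),
             tiny_entries("M4", 0, 99),
             tiny_entries("M5", c(0, 5), c(180, 179)))
  out <- apply_baseline_exclusions(m, e)
  expect_setequal(out$members$member_id, c("M3", "M5"))
  expect_setequal(out$excluded$member_id, c("M1", "M2", "M4"))
  expect_identical(out$excluded$reason[out$excluded$member_id == "M1"], "age")
  expect_identical(out$excluded$reason[out$excluded$member_id == "M2"],
                   "height")
  expect_identical(out$excluded$reason[out$excluded$member_id == "M4"],
                   "baseline_weight")
  expect_identical(out$ledger$entering, 5L)
  expect_identical(out$ledger$excluded + out$ledger$retained, 5L)
})

test_that("entries without a roster row raise a data-integrity error", {
  m <- tiny_members("M1")
  e <- tiny_entries("M9", c(0, 5), c(180, 181))
  expect_error(apply_baseline_exclusions(m, e), "M9")
})

test_that("same-day entries collapse to the last of the day", {
  e <- data.frame(member_id = "M1", day = c(3, 3, 10),
                  weight_lb = c(180, 185, 170),
                  entry_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  out <- collapse_daily(e)
  expect_identical(out$entry_id, c("b", "c"))
  expect_identical(out$weight_lb, c(185, 170))
})

test_that("F1 interpolates three entry days exactly and flags gross spikes", {
  expect_identical(nrow(filter_f1_polynomial(
    tiny_entries("M1", c(0, 10, 20), c(180, 240, 160)))), 0L)
  # on an otherwise noise-free quadratic, a lone spike inflates the
  # residual SD itself: with only 7 points |r|/SD(r) is about 2 whatever
  # the spike size, so the 3-SD rule cannot fire (the oracle agrees);
  # with enough points the spike's leverage dilutes and F1 flags it
  day7 <- seq(0, 60, 10)
  quad7 <- 200 - 0.5 * day7 + 0.005 * day7^2
  w7 <- quad7; w7[4] <- w7[4] + 80
  expect_identical(nrow(filter_f1_polynomial(tiny_entries("M1", day7, w7))),
                   0L)
  expect_identical(length(oracle_f1(day7, w7)), 0L)
  day <- seq(0, 140, 10)
  quad <- 200 - 0.5 * day + 0.005 * day^2
  w <- quad; w[8] <- w[8] + 80
  fl <- filter_f1_polynomial(tiny_entries("M1", day, w))
  expect_identical(fl$entry_id, "M1-008")
  expect_identical(oracle_f1(day, w), 8L)
  # +8 lb fails the 10-lb conjunct even where the 3-SD rule would fire
  w8 <- quad; w8[8] <- w8[8] + 8
  expect_identical(nrow(filter_f1_polynomial(tiny_entries("M1", day, w8))),
                   0L)
  expect_identical(length(oracle_f1(day, w8)), 0L)
})

test_that("F2 flags strictly more than 2% body weight per day", {
  e <- tiny_entries("M1", c(0, 2, 30), c(200, 190, 190))
  fl <- filter_f2_rate(e) # 10/(200*2) = 2.5%/day
  expect_setequal(fl$entry_id, c("M1-001", "M1-002"))
  # exactly 2.0%/day is not flagged
  e2 <- tiny_entries("M1", c(0, 1, 30), c(200, 196, 196))
  expect_identical(nrow(filter_f2_rate(e2)), 0L)
  e3 <- tiny_entries("M1", c(0, 5, 10), c(200, 200, 200))
  expect_identical(nrow(filter_f2_rate(e3)), 0L)
})

test_that("F3 scans all pairs with an inclusive 50 lb threshold", {
  e <- tiny_entries("M1", c(0, 40, 80), c(200, 175, 149))
  fl <- filter_f3_jump(e) # 200 vs 149 = 51, non-consecutive
  expect_setequal(fl$entry_id, c("M1-001", "M1-003"))
  expect_identical(nrow(filter_f3_jump(
    tiny_entries("M1", c(0, 40, 80), c(200, 175, 151)))), 0L)
  fl50 <- filter_f3_jump(tiny_entries("M1", c(0, 40, 80), c(200, 175, 150)))
  expect_setequal(fl50$entry_id, c("M1-001", "M1-003"))
})

test_that("F4 flags a member whose record spans 100 lb or more", {
  fl <- filter_f4_range(tiny_entries("M1", c(0, 100, 300), c(199, 250, 300)))
  expect_identical(unique(fl$member_id), "M1")
  expect_setequal(fl$entry_id, c("M1-003", "M1-001")) # argmax/argmin
  expect_identical(nrow(filter_f4_range(
    tiny_entries("M1", c(0, 100, 300), c(280, 230, 181)))), 0L)
  # exactly 100 on a two-entry member is inclusive
  fl2 <- filter_f4_range(tiny_entries("M1", c(0, 30), c(250, 150)))
  expect_identical(unique(fl2$filter_id), "F4")
})

test_that("filters agree with brute-force oracles on random series", {
  th <- qc_thresholds()
  set.seed(421)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    s <- random_series(n)
    expect_identical(sort(filter_f1_polynomial(s, th)$entry_id),
                     sort(s$entry_id[oracle_f1(s$day, s$weight_lb)]))
    expect_identical(sort(filter_f2_rate(s, th)$entry_id),
                     sort(s$entry_id[oracle_f2(s$day, s$weight_lb)]))
    expect_identical(sort(unique(filter_f3_jump(s, th)$entry_id)),
                     sort(s$entry_id[oracle_f3(s$day, s$weight_lb)]))
    expect_identical(nrow(filter_f4_range(s, th)) > 0,
                     oracle_f4(s$day, s$weight_lb))
  }
})

test_that("filters are deterministic and idempotent on clean data", {
  m <- tiny_members(c("M1", "M2"))
  e <- rbind(tiny_entries("M1", seq(0, 120, 20), 200 - seq(0, 12, 2)),
             tiny_entries("M2", seq(0, 60, 15), 180 + c(0, 1, -1, 0, 1)))
  r1 <- run_all_filters(m, e)
  r2 <- run_all_filters(m, e)
  expect_identical(r1$flags, r2$flags)
  expect_identical(nrow(r1$flags), 0L)
  # F2-F4 produce nothing new on already-cleaned error-free output
  expect_identical(nrow(filter_f2_rate(e)), 0L)
  expect_identical(nrow(filter_f3_jump(e)), 0L)
  expect_identical(nrow(filter_f4_range(e)), 0L)
})

test_that("flag report counts flags per filter with provenance", {
  m <- tiny_members("M1")
  day <- seq(0, 140, 10)
  w <- 200 - 0.5 * day + 0.005 * day^2
  w[8] <- w[8] + 120 # gross spike trips every filter
  out <- run_all_filters(m, tiny_entries("M1", day, w))
  expect_true(all(c("F1", "F2", "F3", "F4") %in% out$flags$filter_id))
  expect_identical(out$summary$n_flagged_members, 1L)
  expect_true("M1-008" %in% out$flagged_entries)
})

test_that("sensitivity is reported against ground truth", {
  m <- tiny_members(c("M1", "M2"))
  e <- rbind(tiny_entries("M1", c(0, 10, 20, 30), c(200, 199, 19, 198)),
             tiny_entries("M2", 0, 180)) # single-day member: out of domain
  truth <- data.frame(entry_id = c("M1-003", "M2-001"))
  out <- run_all_filters(m, e, truth_entries = truth)
  expect_equal(out$summary$sensitivity_domain, 1)
  expect_equal(out$summary$sensitivity_overall, 0.5)
})
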