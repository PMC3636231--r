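test_that("the two-weigh-day rule counts distinct days after collapsing", {
  m <- tiny_members(c("M1", "M2", "M3"))
  e <- rbind(tiny_entries("M1", c(3, 10), c(180, 179)),
             tiny_entries("M2", c(3, 3), c(180, 181)), # one day after collapse
             tiny_entries("M3", 5, 175))
  out <- require_two_weigh_days(m, e)
  expect_identical(out$members$member_id, "M1")
  expect_identical(out$ledger$excluded, 2L)
})

test_that("the temporality rule keeps members whose usage precedes the last weigh-in", {
  m <- tiny_members(c("A", "B", "C"))
  e <- rbind(tiny_entries("A", c(0, 90), c(180, 178)),
             tiny_entries("B", c(0, 90), c(180, 178)),
             tiny_entries("C", c(0, 90), c(180, 178)))
  logins <- data.frame(
    member_id = c("A", "A", "B", "B", "C", "C"),
    day = c(0, 100, 0, 90, 0, 80), stringsAsFactors = FALSE)
  out <- apply_temporality_rule(m, e, logins)
  expect_setequal(out$members$member_id, c("B", "C")) # same day or before
  expect_identical(out$excluded$member_id, "A")
})

test_that("weight entries without any log-in violate the premise", {
  m <- tiny_members("A")
  e <- tiny_entries("A", c(0, 9), c(180, 179))
  logins <- data.frame(member_id = character(0), day = numeric(0))
  expect_error(apply_temporality_rule(m, e, logins), "log-ins")
})

test_that("outcomes reproduce the worked per-30-day example", {
  m <- tiny_members("A")
  base_lb <- kg_to_lb(108)
  last_lb <- kg_to_lb(100)
  e <- tiny_entries("A", c(10, 70), c(base_lb, last_lb)) # span 60 days
  out <- compute_outcomes(m, e)
  expect_equal(out$net_kg, -8, tolerance = 1e-9)
  expect_equal(out$per30_kg, -4, tolerance = 1e-9)
  expect_identical(out$span_days, 60)
})

test_that("BMI uses the imperial 703 formula on the first entry", {
  m <- tiny_members("A", height = 65)
  e <- tiny_entries("A", c(0, 30), c(150, 149))
  out <- compute_outcomes(m, e)
  expect_equal(round(out$baseline_bmi, 2), 24.96)
  expect_equal(out$baseline_bmi, 703 * 150 / 65^2)
})

test_that("per-30-day change scales inversely with span", {
  m <- tiny_members(c("A", "B"))
  e <- rbind(tiny_entries("A", c(0, 60), c(200, 190)),
             tiny_entries("B", c(0, 120), c(200, 190)))
  out <- compute_outcomes(m, e)
  expect_equal(out$per30_kg[out$member_id == "A"],
               2 * out$per30_kg[out$member_id == "B"])
  # identity when last equals baseline
  e0 <- tiny_entries("A", c(0, 45), c(200, 200))
  z <- compute_outcomes(tiny_members("A"), e0)
  expect_identical(z$net_kg, 0); expect_identical(z$per30_kg, 0)
})

test_that("span strata use inclusive printed upper bounds and partition the cohort", {
  m <- tiny_members(c("A", "B", "C", "D"))
  e <- rbind(tiny_entries("A", c(0, 30), c(180, 178)),   # 30 -> first bin
             tiny_entries("B", c(0, 31), c(180, 178)),   # 31 -> second bin
             tiny_entries("C", c(0, 45), c(180, 176)),
             tiny_entries("D", c(0, 900), c(180, 178)))  # overflow bin
  tab <- stratify_by_span(compute_outcomes(m, e))
  expect_identical(tab$n[tab$span_bin == "Up to 30 days"], 1L)
  expect_identical(tab$n[tab$span_bin == "31-60 days"], 2L)
  expect_identical(tab$n[tab$span_bin == ">829 days"], 1L)
  expect_identical(sum(tab$n), 4L)
  # singleton bins report NA SD
  expect_true(is.na(tab$sd_net_kg[tab$span_bin == "Up to 30 days"]))
})

test_that("documented regain counts members with any up-tick once", {
  m <- tiny_members(c("A", "B", "C"))
  e <- rbind(tiny_entries("A", c(0, 10, 20), c(180, 179, 178)),
             tiny_entries("B", c(0, 10, 20), c(180, 179, 181)),
             tiny_entries("C", c(0, 10, 20, 30), c(180, 181, 182, 183)))
  cohort <- compute_outcomes(m, e)
  expect_equal(fraction_documenting_regain(cohort, e), 2 / 3)
  # strictly decreasing everywhere -> 0
  e2 <- rbind(tiny_entries("A", c(0, 10), c(180, 179)),
              tiny_entries("B", c(0, 10), c(200, 150)))
  c2 <- compute_outcomes(tiny_members(c("A", "B")), e2)
  expect_equal(fraction_documenting_regain(c2, e2), 0)
})

test_that("the flow ledger conserves and chains counts", {
  s1 <- data.frame(stage = "baseline_exclusions", entering = 100L,
                   excluded = 10L, retained = 90L)
  s2 <- data.frame(stage = "two_weigh_days", entering = 90L,
                   excluded = 50L, retained = 40L)
  led <- flow_ledger(s1, s2)
  expect_identical(led$entering, c(100L, 90L))
  bad <- data.frame(stage = "x", entering = 80L, excluded = 1L,
                    retained = 79L)
  expect_error(flow_ledger(s1, bad), "chain")
  bad2 <- data.frame(stage = "x", entering = 90L, excluded = 2L,
                     retained = 79L)
  expect_error(flow_ledger(s1, bad2), "conserve")
})
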