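sim_cohort_frame <- function(n = 200, seed = 1) {
  set.seed(seed)
  data.frame(
    member_id = sprintf("M%03d", 1:n),
    baseline_bmi = rnorm(n, 31.6, 7),
    age = rnorm(n, 34, 11),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.9, 0.1)),
    reg_source = sample(c("friend", "search_ad", "other"), n, TRUE),
    region = sample(c("US-South", "US-West", "other-country"), n, TRUE),
    span_days = sample(10:700, n, TRUE),
    net_kg = rnorm(n, -1.5, 5),
    stringsAsFactors = FALSE)
}

test_that("OLS fits equal the brute-force normal-equations solution", {
  d <- sim_cohort_frame(20, seed = 3)
  d$flag <- d$age > 34
  d$net_kg <- -1 - 2 * d$flag + 0.1 * d$baseline_bmi + rnorm(20, 0, 0.5)
  fit <- fit_usage_model(d, "flag", outcome = "net_kg")
  X <- cbind(1, d$flag, d$baseline_bmi)
  beta <- solve(t(X) %*% X, t(X) %*% d$net_kg)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)
})

test_that("confounder screening retains strong predictors and skips constants", {
  d <- sim_cohort_frame(300, seed = 5)
  d$net_kg <- d$net_kg + 0.4 * d$baseline_bmi
  sc <- screen_confounders(d)
  expect_true("baseline_bmi" %in% sc$retained)
  expect_lt(sc$table$p[sc$table$candidate == "baseline_bmi"], 1e-6)
  d$sex <- "female"
  expect_warning(sc2 <- screen_confounders(d), "constant")
  expect_false("sex" %in% sc2$retained)
  # outcome equal to a candidate is retained with p ~ 0
  d3 <- sim_cohort_frame(50, seed = 6)
  d3$net_kg <- d3$span_days
  # perfect association: R warns that the fit is essentially perfect
  sc3 <- suppressWarnings(screen_confounders(d3))
  expect_true("span_days" %in% sc3$retained)
})

test_that("a null candidate is retained at about the nominal 5% rate", {
  hits <- vapply(1:200, function(s) {
    d <- sim_cohort_frame(100, seed = 1000 + s)
    "age" %in% screen_confounders(d, candidates = "age")$retained
  }, logical(1))
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.11)
})

test_that("categorical fits report contrasts, overall p, and empty levels", {
  d <- sim_cohort_frame(150, seed = 9)
  d$per30_kg <- rnorm(150)
  d$cat <- factor(sample(c("0", "1 to <4", ">=4"), 150, TRUE),
                  levels = c("0", "1 to <4", ">=4"))
  fit <- fit_usage_model(d, "cat")
  expect_identical(fit$outcome, "per30_kg")
  expect_identical(nrow(fit$terms), 2L)
  expect_true(all(fit$terms$ci_lo < fit$terms$estimate &
                    fit$terms$estimate < fit$terms$ci_hi))
  expect_true(fit$overall_p >= 0 && fit$overall_p <= 1)
  d$cat2 <- factor(sample(c("0", "1 to <4"), 150, TRUE),
                   levels = c("0", "1 to <4", ">=4"))
  fit2 <- fit_usage_model(d, "cat2")
  expect_identical(fit2$not_estimable, ">=4")
})

test_that("recoding the reference level leaves fitted values unchanged", {
  d <- sim_cohort_frame(120, seed = 11)
  d$per30_kg <- rnorm(120)
  d$cat <- factor(sample(c("a", "b", "c"), 120, TRUE))
  f1 <- fit_usage_model(d, "cat")
  d$cat <- relevel(d$cat, "c")
  f2 <- fit_usage_model(d, "cat")
  expect_equal(fitted(f1$model), fitted(f2$model), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(coef(f1), coef(f2), check.attributes = FALSE)))
})

test_that("backward stepwise removes the weakest block until all p < 0.20", {
  d <- sim_cohort_frame(400, seed = 21)
  set.seed(22)
  d$per30_kg <- rnorm(400)
  d$x1 <- rnorm(400)
  d$per30_kg <- d$per30_kg + 0.9 * d$x1
  d$junk <- factor(sample(c("a", "b", "c"), 400, TRUE))
  sw <- fit_stepwise(d, terms = c("x1", "junk"), outcome = "per30_kg")
  expect_true("x1" %in% sw$final_terms)
  if (nrow(sw$trace)) expect_true(all(sw$trace$p_at_removal >= 0.20))
  expect_true(all(sw$block_p < 0.20))
})

test_that("a single null covariate yields an intercept-only final model", {
  d <- sim_cohort_frame(200, seed = 31)
  set.seed(32)
  d$per30_kg <- rnorm(200)
  d$x <- rnorm(200)
  # choose a draw where the null covariate is clearly non-significant
  while (summary(lm(per30_kg ~ x, d))$coefficients[2, 4] < 0.3) {
    d$x <- rnorm(200)
  }
  sw <- fit_stepwise(d, terms = "x", outcome = "per30_kg")
  expect_identical(sw$final_terms, character(0))
  expect_identical(sw$trace$removed, "x")
})

test_that("rank-deficient full models fail loudly", {
  d <- sim_cohort_frame(100, seed = 41)
  d$per30_kg <- rnorm(100)
  d$dup <- d$baseline_bmi
  expect_error(fit_stepwise(d, terms = c("baseline_bmi", "dup"),
                            outcome = "per30_kg"), "collinear")
})

test_that("stepwise is at most one removal per term and traces removals", {
  d <- sim_cohort_frame(300, seed = 51)
  set.seed(52)
  d$per30_kg <- rnorm(300)
  for (v in c("u1", "u2", "u3")) d[[v]] <- rnorm(300)
  sw <- fit_stepwise(d, terms = c("baseline_bmi", "u1", "u2", "u3"),
                     outcome = "per30_kg")
  expect_lte(nrow(sw$trace), 4L)
  expect_identical(sort(c(sw$final_terms, sw$trace$removed)),
                   sort(c("baseline_bmi", "u1", "u2", "u3")))
})
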