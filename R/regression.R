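# Regression stage: confounder screening, BMI-adjusted univariable models
# of each usage variable, and backward stepwise multiple regression.
# Inference is classical homoskedastic OLS throughout; multi-level
# categorical terms are tested as blocks with joint F tests (drop1), so a
# variable enters or leaves a model whole.

term_table <- function(fit, level = 0.95) {
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = level)
  data.frame(term = rownames(s),
             estimate = s[, 1], se = s[, 2],
             ci_lo = ci[rownames(s), 1], ci_hi = ci[rownames(s), 2],
             p = s[, 4], row.names = NULL, stringsAsFactors = FALSE)
}

block_p <- function(fit) {
  # joint F test per model term (type-II style via drop1)
  d <- stats::drop1(fit, test = "F")
  p <- d[["Pr(>F)"]]
  names(p) <- rownames(d)
  p[!is.na(p)]
}

#' Screen candidate confounders of weight change
#'
#' Fits one univariable OLS of net weight change (kg) on each candidate
#' (baseline BMI, age, gender, registration source, region, and
#' weight-entry span by default) and retains those with an overall
#' p-value below `alpha`. Multi-level categoricals use the joint F test.
#' Constant candidates are skipped with a warning.
#'
#' @param cohort cohort table from [compute_outcomes()]
#' @param candidates candidate column names
#' @param alpha retention significance level
#' @return an object of class `wp_screen`: `table` (candidate, estimate
#'   for numeric candidates, p, retained), `retained` (names), `alpha`
#' @export
screen_confounders <- function(cohort,
                               candidates = c("baseline_bmi", "age", "sex",
                                              "reg_source", "region",
                                              "span_days"),
                               alpha = 0.05) {
  rows <- lapply(candidates, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("candidate not found: ", v, call. = FALSE)
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("skipping constant candidate: ", v)
      return(data.frame(candidate = v, estimate = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        retained = FALSE, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(stats::reformulate(v, "net_kg"), data = cohort)
    p <- unname(block_p(fit)[v])
    est <- ci_lo <- ci_hi <- NA_real_
    if (is.numeric(x)) {
      est <- stats::coef(fit)[[2]]
      ci <- stats::confint(fit)[2, ]
      ci_lo <- ci[[1]]; ci_hi <- ci[[2]]
    }
    data.frame(candidate = v, estimate = est, ci_lo = ci_lo, ci_hi = ci_hi,
               p = p, retained = p < alpha, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- list(table = tab,
              retained = tab$candidate[tab$retained %in% TRUE],
              alpha = alpha, n = nrow(cohort))
  class(out) <- "wp_screen"
  out
}

#' @export
print.wp_screen <- function(x, ...) {
  cat(sprintf("Confounder screen (univariable OLS on net kg, n = %d, P < %.2f)\n",
              x$n, x$alpha))
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab, row.names = FALSE)
  cat("retained:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Fit a BMI-adjusted univariable usage model
#'
#' Ordinary least squares of the outcome on one usage variable plus the
#' adjustment set (baseline BMI by default). Binary flags model net
#' weight change in kg; categorical per-30-day variables model weight
#' change in kg per 30 days. Coefficients are contrasts against the
#' variable's reference level with normal-theory 95% CIs; the overall
#' p-value is the joint F test for the usage variable.
#'
#' @param data cohort-with-features table from [code_usage()]
#' @param variable usage column name (a logical flag or a factor)
#' @param outcome outcome column; defaults to `net_kg` for logical
#'   variables and `per30_kg` for factors
#' @param adjust adjustment covariates
#' @param level CI level
#' @return an object of class `wp_fit` with `terms` (contrast table for
#'   the usage variable), `overall_p`, `adjust_terms`, `n`, `model`
#' @export
fit_usage_model <- function(data, variable, outcome = NULL,
                            adjust = "baseline_bmi", level = 0.95) {
  x <- data[[variable]]
  if (is.null(x)) stop("variable not found: ", variable, call. = FALSE)
  if (is.null(outcome))
    outcome <- if (is.factor(x)) "per30_kg" else "net_kg"
  used <- droplevels(as.factor(x))
  empty <- if (is.factor(x)) setdiff(levels(x), levels(used)) else character(0)
  if (is.factor(x)) data[[variable]] <- droplevels(x)
  fit <- stats::lm(stats::reformulate(c(variable, adjust), outcome),
                   data = data)
  tt <- term_table(fit, level)
  is_var <- startsWith(tt$term, variable)
  out <- list(variable = variable, outcome = outcome,
              terms = tt[is_var, , drop = FALSE],
              adjust_terms = tt[!is_var & tt$term != "(Intercept)", ,
                                drop = FALSE],
              overall_p = unname(block_p(fit)[variable]),
              not_estimable = empty,
              n = stats::nobs(fit), level = level, model = fit)
  class(out) <- "wp_fit"
  out
}

#' @export
print.wp_fit <- function(x, ...) {
  cat(sprintf("Usage model: %s ~ %s (+ %s), n = %d\n", x$outcome,
              x$variable,
              paste(unique(sub("[0-9.]*$", "", x$adjust_terms$term)),
                    collapse = " + "), x$n))
  tab <- x$terms
  tab[-1] <- lapply(tab[-1], function(z) signif(z, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("overall P = %s\n", format.pval(x$overall_p, digits = 3)))
  if (length(x$not_estimable))
    cat("not estimable (empty level):",
        paste(x$not_estimable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.wp_fit <- function(object, ...) stats::coef(object$model)

#' @export
confint.wp_fit <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$model, parm = parm, level = level, ...)
}

#' @export
summary.wp_fit <- function(object, ...) summary(object$model, ...)

#' Backward stepwise selection for per-30-day weight change
#'
#' Starts from the full model (baseline BMI plus all categorical usage
#' variables, plus any extra terms) and iteratively removes the single
#' term with the largest joint-test p-value at or above `retain_p`,
#' refitting after each removal, until every remaining term has
#' p < `retain_p`. Multi-level variables leave as blocks; baseline BMI is
#' eligible for removal like any other term. Ties on the maximal p are
#' broken by removing the term listed later in the declared order.
#'
#' @param data cohort-with-features table
#' @param terms starting model terms, in declared order
#' @param outcome outcome column
#' @param retain_p retention threshold (terms with p below it stay)
#' @param level CI level for the final-model contrast table
#' @return an object of class `wp_stepwise`: `final_terms`, `terms`
#'   (contrast table of the final model), `trace` (removed term, p at
#'   removal, step), `model` (final `lm`), `n`
#' @export
fit_stepwise <- function(data,
                         terms = c("baseline_bmi", "cat_login_days",
                                   "cat_weight_entry_days", "cat_food_days",
                                   "cat_exercise_days",
                                   "cat_exercise_minutes",
                                   "cat_sparkpoints", "cat_forum_posts",
                                   "cat_friends"),
                         outcome = "per30_kg", retain_p = 0.20,
                         level = 0.95) {
  missing <- setdiff(terms, names(data))
  if (length(missing))
    stop("terms not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  fcols <- terms[vapply(data[terms], is.factor, logical(1))]
  data[fcols] <- lapply(data[fcols], droplevels)
  current <- terms
  trace <- data.frame(step = integer(0), removed = character(0),
                      p_at_removal = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- if (length(current)) {
      stats::lm(stats::reformulate(current, outcome), data = data)
    } else stats::lm(stats::reformulate("1", outcome), data = data)
    if (length(current) && any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("full model is rank deficient; collinear terms: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!length(current)) break
    p <- block_p(fit)[current]
    worst <- max(p)
    if (worst < retain_p) break
    # tie-break: later in declared order wins removal
    cand <- current[p >= worst - 1e-12]
    drop_term <- cand[which.max(match(cand, terms))]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = drop_term,
                                     p_at_removal = unname(p[drop_term]),
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, drop_term)
  }
  tt <- term_table(fit, level)
  out <- list(final_terms = current,
              terms = tt[tt$term != "(Intercept)", , drop = FALSE],
              block_p = if (length(current)) block_p(fit) else numeric(0),
              trace = trace, retain_p = retain_p,
              outcome = outcome, n = stats::nobs(fit), model = fit)
  class(out) <- "wp_stepwise"
  out
}

#' @export
print.wp_stepwise <- function(x, ...) {
  cat(sprintf("Backward stepwise OLS: %s, n = %d, retain P < %.2f\n",
              x$outcome, x$n, x$retain_p))
  if (nrow(x$trace)) {
    cat("removed:",
        paste(sprintf("%s (P=%.3f)", x$trace$removed, x$trace$p_at_removal),
              collapse = ", "), "\n")
  } else cat("removed: (none)\n")
  cat("final terms:", if (length(x$final_terms))
    paste(x$final_terms, collapse = ", ") else "(intercept only)", "\n")
  if (nrow(x$terms)) {
    tab <- x$terms
    tab[-1] <- lapply(tab[-1], function(z) signif(z, 4))
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.wp_stepwise <- function(object, ...) stats::coef(object$model)

#' @export
summary.wp_stepwise <- function(object, ...) summary(object$model, ...)
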