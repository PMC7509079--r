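#' EDSS progression rule
#'
#' Progression is an increase of >= 1.0 point from baseline when baseline
#' EDSS is <= 5.5, or >= 0.5 point when baseline EDSS is > 5.5. Both values
#' must lie on the 0-10 scale in 0.5 steps.
#'
#' @param baseline,followup EDSS scores (vectors, recycled).
#' @return Logical vector of progression flags.
#' @export
edss_progression <- function(baseline, followup) {
  check_edss <- function(x, what) {
    bad <- !is.finite(x) | x < 0 | x > 10 | abs(x * 2 - round(x * 2)) > 1e-9
    if (any(bad))
      stop_input("edss_progression: %s EDSS off the 0.5-step 0-10 grid (%s)",
                 what, paste(x[bad], collapse = ", "))
  }
  check_edss(baseline, "baseline")
  check_edss(followup, "follow-up")
  delta <- followup - baseline
  ifelse(baseline <= 5.5, delta >= 1 - 1e-9, delta >= 0.5 - 1e-9)
}

#' 20%-worsening progression rule for clinical scores
#'
#' Progression on T25FW, 9HPT, SDMT or MSWS is an increase of at least 20%
#' from the baseline score (boundary inclusive).
#'
#' @param baseline,followup Scores; `baseline > 0`.
#' @return Logical vector of progression flags.
#' @export
score_progression <- function(baseline, followup) {
  if (any(baseline <= 0))
    stop_input("score_progression: baseline scores must be positive")
  (followup - baseline) / baseline >= 0.2 - 1e-12
}

result_from_lm <- function(fit, term, data_n, covariates) {
  cf <- summary(fit)$coefficients
  if (!(term %in% rownames(cf)))
    stop_input("model term %s not estimable", term)
  ci <- confint(fit, term, level = 0.95)
  structure(list(term = term,
                 coefficient = unname(cf[term, "Estimate"]),
                 ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
                 p_value = unname(cf[term, "Pr(>|t|)"]),
                 n = data_n, covariates = covariates),
            class = "model_result")
}

#' @export
as.data.frame.model_result <- function(x, ...) {
  data.frame(term = x$term, coefficient = x$coefficient,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             p_value = x$p_value, n = x$n, stringsAsFactors = FALSE)
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("%s: Coeff = %.3f; 95%%CI = %.3f, %.3f; p = %.3g (n = %d)\n",
              x$term, x$coefficient, x$ci_lower, x$ci_upper, x$p_value, x$n))
  invisible(x)
}

check_design <- function(fit) {
  cf <- coef(fit)
  if (anyNA(cf))
    stop_input("rank-deficient design: collinear columns %s",
               paste(names(cf)[is.na(cf)], collapse = ", "))
}

#' Covariate-adjusted treatment-arm difference
#'
#' Ordinary least squares of the outcome on the treatment-arm indicator plus
#' confounder covariates (country entered as categorical indicators). The
#' reported coefficient is the arm contrast (second factor level vs the
#' first); the 95% CI uses the t distribution with residual degrees of
#' freedom.
#'
#' @param cohort Cohort data.frame (see [make_cohort()] for the header).
#' @param outcome Name of the outcome column (an atrophy rate).
#' @param group Name of the arm column (two levels; "placebo" is used as
#'   reference when present).
#' @param covariates Confounder columns, always retained.
#' @return A `model_result`.
#' @export
adjusted_group_diff <- function(cohort, outcome = "rate", group = "arm",
                                covariates = c("age", "sex", "height",
                                               "country", "baseline_csa")) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c(outcome, group, covariates), names(cohort))
  if (length(missing_cols))
    stop_input("adjusted_group_diff: missing columns %s",
               paste(missing_cols, collapse = ", "))
  dat <- cohort
  g <- as.factor(dat[[group]])
  if (nlevels(g) != 2L)
    stop_input("adjusted_group_diff: group must have exactly 2 levels")
  if ("placebo" %in% levels(g)) g <- stats::relevel(g, "placebo")
  if (min(table(g)) < 2L)
    stop_input("adjusted_group_diff: need >= 2 subjects per arm")
  dat[[group]] <- g
  fml <- stats::reformulate(c(group, covariates), response = outcome)
  fit <- lm(fml, data = dat)
  check_design(fit)
  term <- paste0(group, levels(g)[2])
  result_from_lm(fit, term, nrow(dat), covariates)
}

candidate_pvalues <- function(fit, candidates) {
  cf <- summary(fit)$coefficients
  p <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (cand in candidates) {
    rows <- rownames(cf)[rownames(cf) == cand |
                           startsWith(rownames(cf), paste0(cand))]
    rows <- rows[rows %in% c(cand, paste0(cand, "TRUE"), paste0(cand, "1"))]
    if (length(rows) == 1L) p[cand] <- cf[rows, "Pr(>|t|)"]
  }
  p
}

#' Backward elimination of clinical candidate variables
#'
#' Starts from the full model containing every candidate plus the fixed
#' confounder covariates (never dropped), then iteratively removes the
#' candidate with the largest p-value above the stay threshold until all
#' retained candidates have `p <= p_threshold`.
#'
#' @param cohort Cohort data.frame.
#' @param outcome Outcome column name.
#' @param candidates Candidate columns (numeric or logical single-df terms),
#'   e.g. progression flags.
#' @param covariates Fixed confounders, exempt from elimination.
#' @param p_threshold Stay threshold (default 0.20).
#' @return List with `retained` (candidate names kept), `dropped` (in drop
#'   order), `results` (a `model_result` per retained candidate) and `fit`
#'   (the final `lm`).
#' @export
backward_select <- function(cohort, outcome, candidates,
                            covariates = c("age", "sex", "height",
                                           "country", "baseline_csa"),
                            p_threshold = 0.20) {
  stopifnot(is.data.frame(cohort), length(candidates) >= 1L)
  missing_cols <- setdiff(c(outcome, candidates, covariates), names(cohort))
  if (length(missing_cols))
    stop_input("backward_select: missing columns %s",
               paste(missing_cols, collapse = ", "))
  dat <- cohort
  for (cand in candidates)
    if (is.logical(dat[[cand]])) dat[[cand]] <- as.numeric(dat[[cand]])

  current <- candidates
  dropped <- character(0)
  repeat {
    fml <- stats::reformulate(c(current, covariates), response = outcome)
    fit <- lm(fml, data = dat)
    check_design(fit)
    if (!length(current)) break
    p <- candidate_pvalues(fit, current)
    worst <- which.max(p)
    if (p[worst] <= p_threshold) break
    dropped <- c(dropped, current[worst])
    current <- current[-worst]
  }
  results <- lapply(current, function(cand)
    result_from_lm(fit, cand, nrow(dat), covariates))
  names(results) <- current
  list(retained = current, dropped = dropped, results = results, fit = fit)
}
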