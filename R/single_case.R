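#' Crawford-Howell single-case test against a normative sample
#'
#' Tests whether one case's score differs from a small normative sample,
#' treating the sample statistics as estimates rather than population values:
#' `t = (case - mean) / (sd * sqrt((n + 1) / n))` with `n - 1` degrees of
#' freedom. The estimated percentile is the modelled proportion of the
#' normative population scoring below the case (higher TDD scores are worse,
#' so a deficit corresponds to a percentile above the cutoff).
#'
#' @param case_score The case's raw score.
#' @param sample Optional numeric vector of normative scores; if supplied,
#'   `sample_mean`, `sample_sd` and `n` are computed from it.
#' @param sample_mean,sample_sd,n Normative summary statistics (`n >= 2`,
#'   `sample_sd > 0`).
#' @param tail `"greater"` (case worse, i.e. higher), `"less"`, or
#'   `"two.sided"`.
#' @return List with `t`, `df`, `p.value`, `percentile`.
#' @export
crawford_howell_test <- function(case_score, sample = NULL,
                                 sample_mean = NULL, sample_sd = NULL,
                                 n = NULL,
                                 tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (!is.null(sample)) {
    sample_mean <- mean(sample)
    sample_sd <- sd(sample)
    n <- length(sample)
  }
  if (is.null(n) || n < 2) stop("normative sample size must be at least 2")
  if (is.null(sample_sd) || sample_sd <= 0)
    stop("normative sample standard deviation must be positive")
  tstat <- (case_score - sample_mean) / (sample_sd * sqrt((n + 1) / n))
  df <- n - 1
  p <- switch(tail,
              greater = pt(tstat, df, lower.tail = FALSE),
              less = pt(tstat, df),
              two.sided = 2 * pt(-abs(tstat), df))
  list(t = tstat, df = df, p.value = p, percentile = 100 * pt(tstat, df))
}

#' Crawford single-case test against an age regression
#'
#' Tests whether a case's score differs from the value predicted by an
#' ordinary least-squares regression of score on age in the normative sample,
#' accounting for prediction uncertainty at the case's age:
#' `t = (case - predicted) / (s * sqrt(1 + 1/n + (age - mean_age)^2 / Sxx))`
#' with `n - 2` degrees of freedom.
#'
#' @param case_age,case_score The case's age (years) and raw score.
#' @param sample_age,sample_score Normative ages and scores (`n >= 3`,
#'   non-constant age).
#' @inheritParams crawford_howell_test
#' @return List with `t`, `df`, `p.value`, `percentile`, `predicted`.
#' @export
crawford_regression_test <- function(case_age, case_score, sample_age,
                                     sample_score,
                                     tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(length(sample_age) == length(sample_score))
  n <- length(sample_age)
  if (n < 3) stop("normative sample must have at least 3 records")
  if (length(unique(sample_age)) < 2)
    stop("age is constant in the normative sample; no regression identifiable")
  fit <- lm(sample_score ~ sample_age)
  pred <- coef(fit)[[1]] + coef(fit)[[2]] * case_age
  s <- summary(fit)$sigma
  sxx <- sum((sample_age - mean(sample_age))^2)
  se <- s * sqrt(1 + 1 / n + (case_age - mean(sample_age))^2 / sxx)
  tstat <- (case_score - pred) / se
  df <- n - 2
  p <- switch(tail,
              greater = pt(tstat, df, lower.tail = FALSE),
              less = pt(tstat, df),
              two.sided = 2 * pt(-abs(tstat), df))
  list(t = tstat, df = df, p.value = p, percentile = 100 * pt(tstat, df),
       predicted = pred)
}

#' Compare percentile-threshold and single-case classification strategies
#'
#' Classifies each patient twice: (i) raw score strictly above the normative
#' percentile threshold (flat per age band, or age-linear), and (ii) Crawford
#' estimated percentile above the same level (Crawford-Howell for flat
#' normative structure, Crawford regression when the scores depend on age).
#' Reports per-patient agreement and the discordant patients.
#'
#' @param cohort Data frame with columns `patient`, `age`, `raw_score`.
#' @param normative Data frame with columns `age`, `raw_score`.
#' @param model `"flat"` (banded percentile + Crawford-Howell) or `"linear"`
#'   (age-linear percentile + Crawford regression).
#' @param bands Age bands for the flat model.
#' @param prob Normative level (default 0.9: worse than 90% of controls).
#' @return Data frame with `patient`, `abnormal_threshold`,
#'   `abnormal_crawford`, `concordant`; attributes `n_concordant` and
#'   `discordant` (patient ids).
#' @export
compare_classification_strategies <- function(cohort, normative,
                                              model = c("flat", "linear"),
                                              bands = age_bands_default(),
                                              prob = 0.9) {
  model <- match.arg(model)
  stopifnot(all(c("patient", "age", "raw_score") %in% names(cohort)),
            all(c("age", "raw_score") %in% names(normative)))
  if (model == "flat") {
    thr <- fit_flat_threshold(normative, bands = bands, prob = prob)
    abn_thr <- cohort$raw_score > predict(thr, cohort$age)
    abn_cr <- vapply(cohort$raw_score, function(s) {
      crawford_howell_test(s, sample = normative$raw_score)$percentile >
        100 * prob
    }, logical(1))
  } else {
    thr <- fit_linear_threshold(normative, prob = prob)
    abn_thr <- cohort$raw_score > predict(thr, cohort$age)
    abn_cr <- mapply(function(a, s) {
      crawford_regression_test(a, s, normative$age,
                               normative$raw_score)$percentile > 100 * prob
    }, cohort$age, cohort$raw_score)
  }
  out <- data.frame(patient = cohort$patient,
                    abnormal_threshold = abn_thr,
                    abnormal_crawford = abn_cr,
                    concordant = abn_thr == abn_cr)
  attr(out, "n_concordant") <- sum(out$concordant)
  attr(out, "discordant") <- out$patient[!out$concordant]
  out
}
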