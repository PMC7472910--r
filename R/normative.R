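#' Default decade age bands for normative thresholds
#'
#' @return Data frame with `lower` and `upper` (inclusive) band limits in
#'   years: 20-29, 30-39, 40-49, 50-59, 60-69.
#' @export
age_bands_default <- function() {
  data.frame(lower = seq(20, 60, 10), upper = seq(29, 69, 10))
}

.band_index <- function(age, bands) {
  breaks <- c(bands$lower, max(bands$upper) + 1)
  idx <- findInterval(age, breaks)
  # ages outside the normative bands use the nearest band (extrapolation)
  pmin(pmax(idx, 1L), nrow(bands))
}

#' Construct a threshold model directly from coefficients
#'
#' A threshold model separates normal from abnormal raw TDD scores. `flat`
#' models hold a single cutoff or one per age band; `linear` models hold a
#' line `threshold(age) = slope * age + intercept`. Use this constructor to
#' apply published cutoffs (e.g. the reference hand/foot thresholds from
#' [reference_thresholds()]); use [fit_flat_threshold()] or
#' [fit_linear_threshold()] to derive a model from a normative sample.
#'
#' @param kind `"flat"` or `"linear"`.
#' @param value For flat models: a single threshold, or one per band.
#' @param bands Age bands (as [age_bands_default()]) for banded flat models.
#' @param slope,intercept For linear models: score units per year, and the
#'   intercept of the threshold line.
#' @param prob Normative percentile the model represents (default 0.9).
#' @return Object of class `tdd_threshold`.
#' @export
threshold_model <- function(kind = c("flat", "linear"), value = NULL,
                            bands = NULL, slope = NULL, intercept = NULL,
                            prob = 0.9) {
  kind <- match.arg(kind)
  if (kind == "flat") {
    if (is.null(value)) stop("flat model needs `value`")
    if (length(value) > 1 && (is.null(bands) || nrow(bands) != length(value)))
      stop("banded flat model needs one `value` per band")
    if (any(value <= 18 | value >= 186))
      warning("flat threshold outside the attainable score range (18, 186)")
    obj <- list(kind = "flat", value = as.numeric(value), bands = bands,
                prob = prob)
  } else {
    if (is.null(slope) || is.null(intercept))
      stop("linear model needs `slope` and `intercept`")
    obj <- list(kind = "linear", slope = as.numeric(slope),
                intercept = as.numeric(intercept), prob = prob)
  }
  structure(obj, class = "tdd_threshold")
}

#' Reference impairment thresholds for the standard TDD protocol
#'
#' The published normative cutoffs for this protocol: a flat hand threshold of
#' 27.7 (no age effect in the normative hand sample) and an age-linear foot
#' threshold `1.786 * age - 11.77` (foot scores worsen with age). Both are
#' 90th-percentile cutoffs; scores above the threshold are abnormal.
#'
#' @return List with `tdd_threshold` elements `hand` and `foot`.
#' @export
reference_thresholds <- function() {
  list(hand = threshold_model("flat", value = 27.7),
       foot = threshold_model("linear", slope = 1.786, intercept = -11.77))
}

#' @export
print.tdd_threshold <- function(x, ...) {
  if (x$kind == "flat") {
    if (length(x$value) == 1) {
      cat(sprintf("Flat TDD threshold (P%.0f): %.3g\n", 100 * x$prob, x$value))
    } else {
      cat(sprintf("Flat TDD threshold (P%.0f) per age band:\n", 100 * x$prob))
      print(data.frame(band = paste(x$bands$lower, x$bands$upper, sep = "-"),
                       threshold = x$value))
    }
  } else {
    cat(sprintf("Age-linear TDD threshold (P%.0f): %.4g * age %+.4g\n",
                100 * x$prob, x$slope, x$intercept))
  }
  invisible(x)
}

#' Evaluate a threshold model at given ages
#'
#' Flat banded models use the band containing the age (nearest band beyond the
#' normative range); linear models extrapolate the line.
#'
#' @param object A `tdd_threshold`.
#' @param age Numeric vector of ages (years); may be omitted for single flat
#'   models.
#' @param ... Unused.
#' @return Numeric vector of thresholds.
#' @export
predict.tdd_threshold <- function(object, age = NULL, ...) {
  if (object$kind == "linear") {
    if (is.null(age)) stop("linear threshold model needs `age`")
    return(object$slope * age + object$intercept)
  }
  if (length(object$value) == 1)
    return(if (is.null(age)) object$value else rep(object$value, length(age)))
  if (is.null(age)) stop("banded flat model needs `age`")
  object$value[.band_index(age, object$bands)]
}

.check_sample <- function(sample) {
  stopifnot(is.data.frame(sample), "raw_score" %in% names(sample))
  if (any(sample$raw_score < 18 | sample$raw_score > 186, na.rm = TRUE))
    warning("raw scores outside the attainable range [18, 186]")
  invisible(sample)
}

#' Fit a flat (percentile) threshold model
#'
#' The cutoff is the 90th percentile (by default) of the normative raw scores,
#' computed per age band with linear-interpolation quantiles, or pooled when
#' `bands = NULL`. Bands with fewer than two records inherit the pooled
#' threshold with a warning.
#'
#' @param sample Data frame with columns `age` and `raw_score` (and optionally
#'   `sex`).
#' @param bands Age bands as [age_bands_default()], or `NULL` for a single
#'   pooled threshold.
#' @param prob Percentile level (default 0.9).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return A flat `tdd_threshold`.
#' @export
fit_flat_threshold <- function(sample, bands = age_bands_default(),
                               prob = 0.9, quantile_type = 7) {
  .check_sample(sample)
  pooled <- quantile(sample$raw_score, prob, type = quantile_type,
                     names = FALSE)
  if (is.null(bands))
    return(threshold_model("flat", value = pooled, prob = prob))
  idx <- .band_index(sample$age, bands)
  thr <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    x <- sample$raw_score[idx == b]
    if (length(x) < 2) {
      warning(sprintf("age band %d-%d has fewer than 2 records; using the pooled threshold",
                      bands$lower[b], bands$upper[b]))
      thr[b] <- pooled
    } else {
      thr[b] <- quantile(x, prob, type = quantile_type, names = FALSE)
    }
  }
  threshold_model("flat", value = thr, bands = bands, prob = prob)
}

#' Fit an age-linear threshold model
#'
#' Ordinary least squares of raw score on age, with the intercept shifted
#' upward by the 90th percentile (by default) of the residuals, so that the
#' stated fraction of normative points lies below the threshold line:
#' `threshold(age) = a * age + b`.
#'
#' @inheritParams fit_flat_threshold
#' @return A linear `tdd_threshold` with extra fields `ols_intercept`,
#'   `residual_shift`, `sigma` and `n`.
#' @export
fit_linear_threshold <- function(sample, prob = 0.9, quantile_type = 7) {
  .check_sample(sample)
  if (length(unique(sample$age)) < 3)
    stop("need at least 3 distinct ages to fit an age-linear threshold")
  fit <- lm(raw_score ~ age, data = sample)
  shift <- quantile(resid(fit), prob, type = quantile_type, names = FALSE)
  out <- threshold_model("linear", slope = coef(fit)[["age"]],
                         intercept = coef(fit)[["(Intercept)"]] + shift,
                         prob = prob)
  out$ols_intercept <- coef(fit)[["(Intercept)"]]
  out$residual_shift <- shift
  out$sigma <- suppressWarnings(summary(fit)$sigma)
  out$n <- nrow(sample)
  out
}

#' F test for a linear age effect on raw scores
#'
#' Simple linear regression of raw score on age; returns the F statistic for
#' slope = 0 with (1, n - 2) degrees of freedom. Degenerate noiseless data
#' with exactly zero regression sum of squares report F = 0, p = 1.
#'
#' @param sample Data frame with `age` and `raw_score`; at least 4 records.
#' @return List with `F`, `df`, `p.value`, `slope`.
#' @export
age_effect_test <- function(sample) {
  .check_sample(sample)
  if (nrow(sample) < 4) stop("need at least 4 records")
  if (length(unique(sample$age)) < 2) stop("age is constant; no slope identifiable")
  fit <- lm(raw_score ~ age, data = sample)
  an <- suppressWarnings(anova(fit))  # perfect fits are handled below
  ssreg <- an[1, "Sum Sq"]
  if (ssreg < 1e-12) {
    fstat <- 0
    p <- 1
  } else {
    fstat <- an[1, "F value"]
    p <- an[1, "Pr(>F)"]
  }
  list(F = fstat, df = c(1L, df.residual(fit)), p.value = p,
       slope = coef(fit)[["age"]])
}

#' Rank-sum test for a sex effect on raw scores
#'
#' Two-sided Mann-Whitney U test (with tie correction via the normal
#' approximation when ties are present) comparing raw scores between sexes.
#'
#' @param sample Data frame with `sex` and `raw_score`; both sexes present.
#' @return List with `U` and `p.value`.
#' @export
sex_effect_test <- function(sample) {
  .check_sample(sample)
  g <- split(sample$raw_score, sample$sex)
  if (length(g) < 2 || any(lengths(g) == 0))
    stop("both sexes must be present")
  wt <- suppressWarnings(wilcox.test(g[[1]], g[[2]]))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Relative TDD score
#'
#' `(raw - threshold) / threshold`: a dimensionless signed ratio. Positive
#' values mean performance worse than the normative cutoff.
#'
#' @param raw Raw TDD score(s).
#' @param threshold Positive threshold score(s).
#' @return Numeric vector of relative scores.
#' @export
relative_score <- function(raw, threshold) {
  if (any(threshold <= 0)) stop("`threshold` must be positive")
  (raw - threshold) / threshold
}

#' Classify one patient's sites from relative scores
#'
#' A site is abnormal when its relative score is strictly greater than zero
#' (a value exactly at the threshold is normal) or when an externally supplied
#' side-difference flag is set. The patient is abnormal when any site is.
#' Missing sites are classified on the available sites and flagged incomplete.
#'
#' @param relative Numeric vector of relative scores, one per site (may
#'   contain `NA`).
#' @param flags Optional logical vector of side-difference flags per site.
#' @return List with `site_abnormal`, `abnormal` (any site), `incomplete`.
#' @export
classify_patient <- function(relative, flags = NULL) {
  if (is.null(flags)) flags <- rep(FALSE, length(relative))
  stopifnot(length(flags) == length(relative))
  flags[is.na(flags)] <- FALSE
  site <- (!is.na(relative) & relative > 0) | flags
  list(site_abnormal = site,
       abnormal = any(site),
       incomplete = anyNA(relative))
}

.tp_suffix <- function(timepoint) {
  switch(match.arg(timepoint, c("followup", "acute")),
         followup = "_3m", acute = "_acute")
}

.sites <- c("rh", "lh", "rf", "lf")

#' Classify a patient cohort at one time point
#'
#' Applies the site rule of [classify_patient()] to every patient of a cohort
#' table (as returned by [read_cohort()] or [table2_fixture()]), using the
#' relative scores and side-difference flags of the requested time point.
#'
#' @param cohort A cohort data frame with per-site relative score columns
#'   (`rh_acute`, ..., `lf_3m`) and side-difference flag columns (`sd_*`).
#' @param timepoint `"followup"` (3 months) or `"acute"`.
#' @return Data frame with one row per patient: per-site abnormality,
#'   `abnormal` and `incomplete`; the number of abnormal patients is in
#'   attribute `n_abnormal`.
#' @export
classify_cohort <- function(cohort, timepoint = c("followup", "acute")) {
  suf <- .tp_suffix(timepoint)
  score_cols <- paste0(.sites, suf)
  flag_cols <- paste0("sd_", .sites, suf)
  stopifnot(all(score_cols %in% names(cohort)))
  out <- data.frame(patient = cohort$patient)
  site_mat <- matrix(FALSE, nrow(cohort), length(.sites),
                     dimnames = list(NULL, paste0("abnormal_", .sites)))
  incomplete <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rel <- as.numeric(cohort[i, score_cols])
    fl <- if (all(flag_cols %in% names(cohort)))
      as.logical(cohort[i, flag_cols]) else NULL
    cl <- classify_patient(rel, fl)
    site_mat[i, ] <- cl$site_abnormal
    incomplete[i] <- cl$incomplete
  }
  out <- cbind(out, as.data.frame(site_mat))
  out$abnormal <- apply(site_mat, 1, any)
  out$incomplete <- incomplete
  attr(out, "n_abnormal") <- sum(out$abnormal)
  out
}

#' Inter-examiner agreement for repeated TDD measurements
#'
#' Squared Pearson correlation between two examiners' scores on the same
#' participants, and a two-sided paired t test of the mean difference.
#'
#' @param scores_a,scores_b Numeric vectors of paired scores (>= 3 pairs).
#' @return List with `r_squared`, `mean_diff`, `t`, `df`, `p.value`.
#' @export
interexaminer_agreement <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  if (length(scores_a) < 3) stop("need at least 3 pairs")
  if (sd(scores_a) == 0 || sd(scores_b) == 0) {
    r2 <- NA_real_
    message("zero variance in one examiner's scores; R-squared undefined")
  } else {
    r2 <- stats::cor(scores_a, scores_b)^2
  }
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    tt <- list(statistic = NA_real_, parameter = length(d) - 1,
               p.value = if (mean(d) == 0) 1 else NA_real_)
  } else {
    tt <- t.test(scores_a, scores_b, paired = TRUE)
  }
  list(r_squared = r2, mean_diff = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p.value = tt$p.value)
}
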