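make_norm <- function(ages, scores, sex = NULL) {
  data.frame(age = ages, raw_score = scores,
             sex = if (is.null(sex)) rep(c("F", "M"), length.out = length(ages))
                   else sex)
}

test_that("flat thresholds are per-band percentiles with pooled fallback", {
  ages <- rep(c(25, 35, 45, 55, 65), each = 4)
  s <- make_norm(ages, rep(30, 20))
  thr <- fit_flat_threshold(s)
  expect_equal(unname(predict(thr, c(22, 47, 68))), c(30, 30, 30))

  # interpolated 90th percentile of 11 evenly spaced values on [18, 186]
  x <- seq(18, 186, length.out = 11)
  s2 <- make_norm(rep(45, 11), x)
  thr2 <- fit_flat_threshold(s2, bands = NULL)
  expect_equal(thr2$value, unname(quantile(x, 0.9, type = 7)))
  expect_equal(thr2$value, x[10])  # h = 10 exactly for n = 11, p = 0.9

  # a band with < 2 records inherits the pooled threshold, with a warning
  s3 <- make_norm(c(25, 35, 36, 45, 46, 55, 56, 65, 66),
                  c(50, 21, 22, 23, 24, 25, 26, 27, 28))
  expect_warning(thr3 <- fit_flat_threshold(s3), "band 20-29.*pooled")
  pooled <- unname(quantile(s3$raw_score, 0.9, type = 7))
  expect_equal(unname(predict(thr3, 25)), pooled)
})

test_that("linear thresholds shift the OLS line by the residual percentile", {
  # zero residuals: threshold line equals the fitted line
  ages <- 20:29
  s <- make_norm(ages, 2 * ages + 5)
  thr <- fit_linear_threshold(s)
  expect_equal(thr$slope, 2, tolerance = 1e-10)
  expect_equal(thr$intercept, 5, tolerance = 1e-8)

  # known residual pattern: shift equals the interpolated residual quantile
  e <- c(-4, -3, -2, -1, 0, 1, 2, 3, 4, 10)
  set.seed(1)
  e <- sample(e)
  s2 <- make_norm(ages, 2 * ages + 5 + e)
  thr2 <- fit_linear_threshold(s2)
  fit <- lm(raw_score ~ age, data = s2)
  r <- sort(resid(fit))
  h <- (10 - 1) * 0.9 + 1  # type-7 interpolation position
  shift <- unname(r[floor(h)] + (h - floor(h)) * (r[ceiling(h)] - r[floor(h)]))
  expect_equal(thr2$residual_shift, shift, tolerance = 1e-10)
  expect_equal(thr2$intercept, coef(fit)[[1]] + shift, tolerance = 1e-10)

  expect_error(fit_linear_threshold(make_norm(rep(40, 5), 21:25)), "distinct ages")
})

test_that("age effect F test matches the textbook closed form", {
  # degenerate noiseless zero-slope data
  s0 <- make_norm(20:27, rep(40, 8))
  a0 <- age_effect_test(s0)
  expect_equal(a0$F, 0)
  expect_equal(a0$p.value, 1)

  # small worked dataset against F = MSreg / MSres computed by hand
  ages <- c(22, 30, 41, 47, 55, 63)
  y <- c(25, 31, 28, 45, 49, 58)
  s <- make_norm(ages, y)
  res <- age_effect_test(s)
  sxx <- sum((ages - mean(ages))^2)
  sxy <- sum((ages - mean(ages)) * (y - mean(y)))
  ssreg <- sxy^2 / sxx
  sse <- sum((y - mean(y))^2) - ssreg
  f_hand <- ssreg / (sse / (length(y) - 2))
  expect_equal(res$F, f_hand, tolerance = 1e-10)
  expect_equal(res$df, c(1L, 4L))
  expect_error(age_effect_test(make_norm(rep(30, 5), 21:25)), "constant")
})

test_that("age effect test holds its size under the null", {
  set.seed(202)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    s <- make_norm(sample(22:68, 20, replace = TRUE), rnorm(20, 60, 8))
    age_effect_test(s)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("sex effect rank-sum test agrees with exact enumeration at 3 vs 3", {
  a <- c(21, 25, 33)
  b <- c(27, 40, 52)
  s <- make_norm(rep(40, 6), c(a, b), sex = rep(c("F", "M"), each = 3))
  res <- sex_effect_test(s)
  # enumerate all assignments of the pooled scores to the first group
  pool <- c(a, b)
  obs_u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  us <- apply(utils::combn(6, 3), 2, function(idx) {
    g1 <- pool[idx]; g2 <- pool[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  })
  center <- length(a) * length(b) / 2
  p_enum <- mean(abs(us - center) >= abs(obs_u - center))
  expect_equal(res$p.value, p_enum, tolerance = 1e-10)

  # identical groups give the maximal p
  s_id <- make_norm(rep(40, 6), rep(c(30, 35, 40), 2),
                    sex = rep(c("F", "M"), each = 3))
  expect_equal(sex_effect_test(s_id)$p.value, 1)
  expect_error(sex_effect_test(make_norm(40:42, 21:23, sex = rep("F", 3))),
               "both sexes")
})

test_that("relative scores are signed threshold ratios, monotone both ways", {
  expect_equal(relative_score(27.7, 27.7), 0)
  expect_equal(relative_score(55.4, 27.7), 1)
  expect_equal(relative_score(20, 40), -0.5)
  expect_error(relative_score(30, 0), "positive")
  raws <- seq(20, 180, 20)
  expect_true(all(diff(relative_score(raws, 50)) > 0))
  thrs <- seq(20, 120, 20)
  expect_true(all(diff(relative_score(60, thrs)) < 0))
})

test_that("site and patient classification follows the strict > 0 or-flag rule", {
  # a relative score of exactly 0 alone does not make a site abnormal
  cl <- classify_patient(c(0, -0.2, -0.3, -0.1))
  expect_false(cl$abnormal)
  cl2 <- classify_patient(c(0, -0.2, -0.3, -0.1), flags = c(FALSE, TRUE, FALSE, FALSE))
  expect_true(cl2$abnormal)
  expect_equal(cl2$site_abnormal, c(FALSE, TRUE, FALSE, FALSE))
  cl3 <- classify_patient(c(NA, -0.2, 0.4, -0.1))
  expect_true(cl3$abnormal)
  expect_true(cl3$incomplete)

  # thresholds at +Inf mark every raw score normal
  expect_true(all(relative_score(c(18, 186), 1e9) < 0))
})

test_that("the packaged cohort classifies 21 of 28 abnormal at follow-up", {
  co <- table2_fixture()
  cls <- classify_cohort(co, "followup")
  expect_equal(attr(cls, "n_abnormal"), 21L)
  # patients 20 and 21 qualify only through the side-difference footnote
  expect_true(all(cls$abnormal[co$patient %in% c(20, 21)]))
  only_flags <- classify_cohort(within(co, {
    sd_rf_3m <- FALSE
  }), "followup")
  expect_equal(attr(only_flags, "n_abnormal"), 19L)
})

test_that("inter-examiner agreement returns squared correlation and paired t", {
  a <- c(20, 24, 30, 41)
  expect_equal(interexaminer_agreement(a, a)$r_squared, 1)
  expect_equal(interexaminer_agreement(a, a)$mean_diff, 0)

  b <- c(22, 23, 33, 38)
  res <- interexaminer_agreement(a, b)
  r2_hand <- (sum((a - mean(a)) * (b - mean(b))) /
                sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
  expect_equal(res$r_squared, r2_hand, tolerance = 1e-12)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_message(interexaminer_agreement(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_error(interexaminer_agreement(1:2, 1:2), "3 pairs")
})
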