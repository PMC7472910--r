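.as_2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
    m <- x
  } else {
    stopifnot(length(x) == 4)
    m <- matrix(x, 2, 2, byrow = TRUE)
  }
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  m
}

#' One-sided Fisher exact test (upper tail)
#'
#' Conditional on both margins of a 2x2 table (rows = lesion group, columns =
#' impaired / not impaired), the top-left count follows a hypergeometric
#' distribution; the one-sided p-value is the upper tail `P(X >= a)`,
#' testing whether row 1 carries an excess of column-1 outcomes.
#' Tables with a zero row or column margin return `p = 1` by convention.
#'
#' @param table 2x2 integer matrix, or a length-4 vector `c(a, b, c, d)`
#'   filled by row.
#' @return One-sided p-value.
#' @export
fisher_exact_one_sided <- function(table) {
  m <- .as_2x2(table)
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  if (any(c(a + b, cc + d, a + cc, b + d) == 0)) return(1)
  phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
}

# Upper-tail probability P(X >= a) of Fisher's noncentral hypergeometric
# distribution with odds parameter psi, conditional on the table margins.
.nchg_tail_ge <- function(a, m1, m2, k, psi) {
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  x <- lo:hi
  lw <- lchoose(m1, x) + lchoose(m2, k - x) + x * log(psi)
  w <- exp(lw - max(lw))
  sum(w[x >= a]) / sum(w)
}

#' Lower bound of the one-sided conditional exact odds-ratio CI
#'
#' For a 2x2 table, finds the odds parameter `psi_L` of Fisher's noncentral
#' hypergeometric distribution at which the conditional upper-tail probability
#' of the observed top-left count equals `1 - conf.level` (0.05 by default).
#' This is the lower limit of the one-sided interval `(psi_L, Inf)`; when the
#' observed count sits at its conditional minimum the bound is 0.
#'
#' @inheritParams fisher_exact_one_sided
#' @param conf.level One-sided confidence level (default 0.95).
#' @return Odds-ratio lower bound.
#' @export
fisher_or_ci_lower <- function(table, conf.level = 0.95) {
  m <- .as_2x2(table)
  a <- m[1, 1]
  m1 <- m[1, 1] + m[1, 2]
  m2 <- m[2, 1] + m[2, 2]
  k <- m[1, 1] + m[2, 1]
  alpha <- 1 - conf.level
  if (a <= max(0L, k - m2)) return(0)
  f <- function(lp) .nchg_tail_ge(a, m1, m2, k, exp(lp)) - alpha
  root <- uniroot(f, c(-50, 50), tol = 1e-12)
  exp(root$root)
}

#' One-sided conditional exact confidence interval for the odds ratio
#'
#' @inheritParams fisher_or_ci_lower
#' @return Numeric vector `c(lower, upper)`; the upper limit is `Inf` when
#'   the observed count is at its conditional maximum (the interval the
#'   one-sided bound implies).
#' @export
fisher_or_ci <- function(table, conf.level = 0.95) {
  m <- .as_2x2(table)
  a <- m[1, 1]
  m1 <- m[1, 1] + m[1, 2]
  m2 <- m[2, 1] + m[2, 2]
  k <- m[1, 1] + m[2, 1]
  lower <- fisher_or_ci_lower(table, conf.level)
  upper <- if (a >= min(k, m1)) Inf else {
    alpha <- 1 - conf.level
    f <- function(lp) (1 - .nchg_tail_ge(a + 1L, m1, m2, k, exp(lp))) - alpha
    exp(uniroot(f, c(-50, 50), tol = 1e-12)$root)
  }
  c(lower = lower, upper = upper)
}

#' Paired t test on pre/post score pairs
#'
#' Classical paired t test on `pre - post`. With differences of exactly zero
#' variance the t statistic is undefined and reported as `NA` (p = 1 when the
#' mean difference is also zero).
#'
#' @param pre,post Numeric vectors of equal length (>= 2 pairs), paired by
#'   patient-site.
#' @return List with `mean_diff`, `t`, `df`, `p.value`, `n`.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- pre - post
  if (sd(d) == 0) {
    return(list(mean_diff = mean(d), t = NA_real_, df = n - 1,
                p.value = if (mean(d) == 0) 1 else NA_real_, n = n))
  }
  tt <- t.test(pre, post, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p.value = tt$p.value, n = n)
}

#' Holm-Bonferroni step-down correction
#'
#' Orders the p-values and compares the k-th smallest against
#' `alpha / (m - k + 1)`, rejecting until the first failure.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return List with `reject` and `critical_alpha` (both in the input order),
#'   `adjusted_p` (Holm-adjusted p-values), and `alpha`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  o <- order(pvals)
  crit_sorted <- alpha / (m - seq_len(m) + 1)
  ps <- pvals[o]
  pass <- ps <= crit_sorted
  k <- if (all(pass)) m else which(!pass)[1] - 1L
  reject <- logical(m)
  reject[o[seq_len(k)]] <- TRUE
  crit <- numeric(m)
  crit[o] <- crit_sorted
  adj_sorted <- pmin(cummax((m - seq_len(m) + 1) * ps), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  list(reject = reject, critical_alpha = crit, adjusted_p = adj,
       alpha = alpha)
}

#' Compare relative TDD scores between time points
#'
#' Pools left and right relative scores for one site type (hand or foot) and
#' runs a paired t test of acute minus follow-up, so a positive mean
#' difference means improvement over time.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param site `"hand"` or `"foot"`.
#' @return As [paired_t()], plus `site`.
#' @export
compare_timepoints <- function(cohort, site = c("hand", "foot")) {
  site <- match.arg(site)
  cols <- if (site == "hand") c("rh", "lh") else c("rf", "lf")
  pre <- unlist(lapply(cols, function(cl) cohort[[paste0(cl, "_acute")]]),
                use.names = FALSE)
  post <- unlist(lapply(cols, function(cl) cohort[[paste0(cl, "_3m")]]),
                 use.names = FALSE)
  out <- paired_t(pre, post)
  out$site <- site
  out
}
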