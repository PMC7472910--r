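#' Default TDD stimulus distance series
#'
#' The seven stimulus path lengths of the standard tactile direction
#' discrimination (TDD) protocol, an approximately logarithmic series in mm.
#'
#' @return Strictly increasing numeric vector of distances (mm).
#' @export
tdd_series <- function() c(3, 6, 10, 18, 32, 56, 100)

#' Staircase protocol configuration
#'
#' Bundles the parameters of the adaptive TDD staircase: the distance series,
#' the number of trials, the starting distance, and the number of consecutive
#' correct responses required to step down to a shorter (harder) distance.
#' Stimulus speed and vertical load are recorded as metadata only; they do not
#' enter any computation.
#'
#' @param series Strictly increasing numeric vector of stimulus distances (mm).
#' @param n_trials Total number of trials; must be even so that the two
#'   movement directions can be balanced.
#' @param start_distance Distance (mm) of the first trial; must be a member of
#'   `series`.
#' @param n_correct_to_step_down Number of consecutive correct responses that
#'   triggers a step to the next shorter distance.
#' @param speed_mm_s Probe speed in mm/s (metadata).
#' @param load_g Vertical probe load in grams (metadata).
#' @return An object of class `tdd_staircase_config`.
#' @export
staircase_config <- function(series = tdd_series(), n_trials = 32L,
                             start_distance = 18,
                             n_correct_to_step_down = 3L,
                             speed_mm_s = 10, load_g = 16) {
  if (length(series) < 2 || any(diff(series) <= 0))
    stop("`series` must be strictly increasing with at least two distances")
  n_trials <- as.integer(n_trials)
  if (n_trials <= 0 || n_trials %% 2L != 0L)
    stop("`n_trials` must be a positive even count (direction balance)")
  if (!start_distance %in% series)
    stop("`start_distance` must be a member of `series`")
  n_correct_to_step_down <- as.integer(n_correct_to_step_down)
  if (n_correct_to_step_down < 1)
    stop("`n_correct_to_step_down` must be at least 1")
  structure(list(series = as.numeric(series), n_trials = n_trials,
                 start_distance = start_distance,
                 n_correct_to_step_down = n_correct_to_step_down,
                 speed_mm_s = speed_mm_s, load_g = load_g),
            class = "tdd_staircase_config")
}

#' @export
print.tdd_staircase_config <- function(x, ...) {
  cat("TDD staircase configuration\n")
  cat("  series (mm):", paste(x$series, collapse = ", "), "\n")
  cat(sprintf("  %d trials, start %g mm, %d-correct step-down\n",
              x$n_trials, x$start_distance, x$n_correct_to_step_down))
  invisible(x)
}

#' Staircase state transition
#'
#' Advances the staircase state by one trial. An incorrect response moves the
#' level one step toward longer (easier) distances and resets the consecutive
#' correct counter; a correct response increments the counter, and when the
#' counter reaches `n_correct_to_step_down` the level moves one step toward
#' shorter distances and the counter resets. Levels clamp at both ends of the
#' series.
#'
#' @param level 1-based index into the distance series.
#' @param consecutive_correct Current count of consecutive correct responses,
#'   in `0:(n_correct_to_step_down - 1)`.
#' @param correct Logical; was the response correct?
#' @param config A [staircase_config()].
#' @return List with elements `level` and `consecutive_correct`.
#' @export
next_state <- function(level, consecutive_correct, correct,
                       config = staircase_config()) {
  k <- length(config$series)
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level != round(level) || level < 1 || level > k)
    stop("`level` must be a valid 1-based index into the series")
  if (consecutive_correct < 0 ||
      consecutive_correct >= config$n_correct_to_step_down)
    stop("`consecutive_correct` out of range")
  level <- as.integer(level)
  if (!correct)
    return(list(level = min(level + 1L, k), consecutive_correct = 0L))
  cc <- as.integer(consecutive_correct) + 1L
  if (cc >= config$n_correct_to_step_down)
    list(level = max(level - 1L, 1L), consecutive_correct = 0L)
  else
    list(level = level, consecutive_correct = cc)
}

#' Balanced pseudo-random direction sequence
#'
#' Generates the order of movement directions for a staircase run: exactly
#' half the trials in each direction, in a seeded uniform shuffle. An optional
#' maximum run length can be enforced by rejection sampling (off by default;
#' the protocol requires only pseudo-randomness).
#'
#' @param n_trials Even number of trials.
#' @param seed Optional integer seed; the same seed reproduces the sequence.
#' @param max_run Optional maximum number of identical consecutive directions.
#' @return Character vector with values `"distoproximal"`/`"proximodistal"`.
#' @export
make_direction_sequence <- function(n_trials = 32L, seed = NULL,
                                    max_run = Inf) {
  if (n_trials %% 2 != 0) stop("`n_trials` must be even")
  dirs <- rep(c("distoproximal", "proximodistal"), each = n_trials / 2)
  .with_seed(seed, {
    repeat {
      s <- sample(dirs)
      if (!is.finite(max_run) || max(rle(s)$lengths) <= max_run) break
    }
    s
  })
}

#' Simulate one staircase run for a given observer
#'
#' Runs the full adaptive protocol against an observer model: a function
#' mapping stimulus distance (mm) to the probability of a correct direction
#' judgement. Each trial outcome is a Bernoulli draw at the current distance,
#' and the distance evolves under [next_state()]. Direction scheduling is an
#' independent balanced shuffle and does not influence correctness.
#'
#' @param observer Function `distance -> P(correct)`, with values in `[0, 1]`
#'   at every series distance (e.g. [psychometric_observer()]).
#' @param config A [staircase_config()].
#' @param seed Optional integer seed stored in the sheet for reproducibility.
#' @return A `tdd_sheet`: list with `config`, `trials` (data frame with
#'   columns `trial`, `distance_mm`, `direction`, `correct`), `seed`, `score`.
#' @export
run_staircase <- function(observer, config = staircase_config(), seed = NULL) {
  p <- vapply(config$series, function(d) as.numeric(observer(d)), numeric(1))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("observer must return probabilities in [0, 1] at every series distance")
  n <- config$n_trials
  k <- length(config$series)
  res <- .with_seed(seed, {
    direction <- make_direction_sequence(n)
    distance <- numeric(n)
    correct <- logical(n)
    level <- match(config$start_distance, config$series)
    cc <- 0L
    u <- runif(n)
    for (i in seq_len(n)) {
      distance[i] <- config$series[level]
      correct[i] <- u[i] < p[level]
      st <- next_state(level, cc, correct[i], config)
      level <- st$level
      cc <- st$consecutive_correct
    }
    list(distance = distance, direction = direction, correct = correct)
  })
  trials <- data.frame(trial = seq_len(n), distance_mm = res$distance,
                       direction = res$direction, correct = res$correct,
                       stringsAsFactors = FALSE)
  sheet <- structure(list(config = config, trials = trials, seed = seed,
                          score = NA_integer_),
                     class = "tdd_sheet")
  sheet$score <- score_sheet(sheet)
  sheet
}

#' Score a staircase run ("boxes to the left")
#'
#' The TDD score is the sum, over trials, of the 0-based index of the trial's
#' distance within the series. It approximates the area under the staircase
#' trace: under the default 32-trial protocol an always-correct run scores the
#' minimum of 18 and an always-incorrect run the maximum of 186. The score
#' depends only on the distances visited, not on direction labels.
#'
#' @param sheet A `tdd_sheet`, or a numeric vector of trial distances.
#' @param series Distance series used when `sheet` is a bare numeric vector.
#' @return Integer score.
#' @export
score_sheet <- function(sheet, series = tdd_series()) {
  if (inherits(sheet, "tdd_sheet")) {
    series <- sheet$config$series
    d <- sheet$trials$distance_mm
  } else {
    d <- as.numeric(sheet)
  }
  idx <- match(d, series)
  if (anyNA(idx))
    stop("trial distance not in the series: ",
         paste(unique(d[is.na(idx)]), collapse = ", "))
  as.integer(sum(idx - 1L))
}

#' Replay-validate a scoring sheet
#'
#' Checks that the stored trial distances are exactly those produced by
#' replaying the staircase update rule on the stored correctness sequence,
#' and that the stored score matches a recomputation.
#'
#' @param sheet A `tdd_sheet`.
#' @return `TRUE` invisibly; errors on any inconsistency.
#' @export
validate_sheet <- function(sheet) {
  stopifnot(inherits(sheet, "tdd_sheet"))
  cfg <- sheet$config
  tr <- sheet$trials
  if (nrow(tr) != cfg$n_trials)
    stop("sheet has ", nrow(tr), " trials; config says ", cfg$n_trials)
  level <- match(cfg$start_distance, cfg$series)
  cc <- 0L
  for (i in seq_len(nrow(tr))) {
    if (tr$distance_mm[i] != cfg$series[level])
      stop("trial ", i, " distance ", tr$distance_mm[i],
           " does not replay under the update rule (expected ",
           cfg$series[level], ")")
    st <- next_state(level, cc, tr$correct[i], cfg)
    level <- st$level
    cc <- st$consecutive_correct
  }
  if (!identical(as.integer(sheet$score), score_sheet(sheet)))
    stop("stored score does not match recomputation")
  invisible(TRUE)
}

#' Exact expected staircase score by dynamic programming
#'
#' Computes the exact expectation of the TDD score for a given observer by
#' forward dynamic programming over the Markov state
#' (trial, level, consecutive-correct counter). No sampling is involved; this
#' serves as an analytic oracle for Monte-Carlo simulations.
#'
#' @inheritParams run_staircase
#' @return Expected score (numeric scalar).
#' @export
expected_score_dp <- function(observer, config = staircase_config()) {
  p <- vapply(config$series, function(d) as.numeric(observer(d)), numeric(1))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("observer must return probabilities in [0, 1] at every series distance")
  k <- length(config$series)
  m <- config$n_correct_to_step_down
  P <- matrix(0, k, m)  # columns are counter states 0..m-1
  P[match(config$start_distance, config$series), 1] <- 1
  escore <- 0
  for (t in seq_len(config$n_trials)) {
    escore <- escore + sum(rowSums(P) * (seq_len(k) - 1))
    Q <- matrix(0, k, m)
    for (l in seq_len(k)) {
      for (cidx in seq_len(m)) {
        pr <- P[l, cidx]
        if (pr == 0) next
        up <- min(l + 1L, k)
        Q[up, 1] <- Q[up, 1] + pr * (1 - p[l])
        if (cidx == m) {
          dn <- max(l - 1L, 1L)
          Q[dn, 1] <- Q[dn, 1] + pr * p[l]
        } else {
          Q[l, cidx + 1] <- Q[l, cidx + 1] + pr * p[l]
        }
      }
    }
    P <- Q
  }
  escore
}

#' @export
print.tdd_sheet <- function(x, ...) {
  cat(sprintf("TDD scoring sheet: %d trials, score %d\n",
              nrow(x$trials), x$score))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  lev <- table(factor(x$trials$distance_mm, levels = x$config$series))
  cat("  trials per distance (mm):\n")
  print(lev)
  invisible(x)
}

#' Write a scoring sheet to disk
#'
#' JSON files carry the full sheet (config, seed, score, trials). CSV files
#' carry one row per trial (`trial`, `distance_mm`, `direction`, `correct`),
#' with config and score in a JSON sidecar at `<path>.json`.
#'
#' @param sheet A `tdd_sheet`.
#' @param path Output path; format inferred from the `.json`/`.csv` extension.
#' @return `path`, invisibly.
#' @export
write_scoring_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "tdd_sheet"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(config = unclass(sheet$config), seed = sheet$seed,
           score = sheet$score, trials = sheet$trials),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(sheet$trials, path, row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(sheet$config), seed = sheet$seed,
           score = sheet$score),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported extension; use .json or .csv")
  }
  invisible(path)
}

#' Read a scoring sheet written by [write_scoring_sheet()]
#'
#' @param path Path to a `.json` or `.csv` sheet.
#' @return A validated `tdd_sheet`.
#' @export
read_scoring_sheet <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    trials <- obj$trials
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    trials <- read.csv(path, stringsAsFactors = FALSE)
    obj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else {
    stop("unsupported extension; use .json or .csv")
  }
  cfg <- staircase_config(series = obj$config$series,
                          n_trials = obj$config$n_trials,
                          start_distance = obj$config$start_distance,
                          n_correct_to_step_down = obj$config$n_correct_to_step_down,
                          speed_mm_s = obj$config$speed_mm_s,
                          load_g = obj$config$load_g)
  sheet <- structure(list(config = cfg, trials = as.data.frame(trials),
                          seed = obj$seed, score = as.integer(obj$score)),
                     class = "tdd_sheet")
  validate_sheet(sheet)
  sheet
}
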