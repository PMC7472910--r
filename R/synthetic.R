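#' Psychometric observer model
#'
#' A two-alternative forced-choice observer: the probability of a correct
#' direction judgement as a function of stimulus distance `d` (mm) is
#' `guess + (1 - guess - lapse) * F(d)`, with chance level `guess = 0.5`
#' (forced choice between two directions), a lapse rate for
#' stimulus-independent errors, and `F` either a logistic in log-distance
#' (default; the distance series is near-geometric) or a Weibull.
#'
#' @param alpha Distance (mm) at the inflection of `F` (sensitivity; larger
#'   alpha = worse observer).
#' @param beta Slope parameter of `F` on the log-distance scale.
#' @param lapse Lapse rate in `[0, 0.1]`.
#' @param guess Chance performance level (fixed at 0.5 for 2AFC).
#' @param form `"logistic"` (default) or `"weibull"`.
#' @return Function `distance -> P(correct)`, of class `tdd_observer`.
#' @export
psychometric_observer <- function(alpha, beta = 0.7, lapse = 0.02,
                                  guess = 0.5,
                                  form = c("logistic", "weibull")) {
  form <- match.arg(form)
  stopifnot(alpha > 0, beta > 0, lapse >= 0, lapse <= 0.1)
  f <- if (form == "logistic") {
    function(d) guess + (1 - guess - lapse) * plogis((log(d) - log(alpha)) / beta)
  } else {
    function(d) guess + (1 - guess - lapse) * (1 - exp(-(d / alpha)^(1 / beta)))
  }
  structure(f, class = c("tdd_observer", "function"),
            params = list(alpha = alpha, beta = beta, lapse = lapse,
                          guess = guess, form = form))
}

#' @export
print.tdd_observer <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Psychometric observer (%s): alpha %.3g mm, beta %.3g, lapse %.3g, guess %.2g\n",
              p$form, p$alpha, p$beta, p$lapse, p$guess))
  invisible(x)
}

# Site presets for the normative generator, calibrated via the exact DP
# expectation of the staircase score so that (a) the mean foot score at the
# cohort mean age is ~41 with an emergent age slope of ~1.2 score points per
# year, and (b) the mean hand score is ~21.5 with no age effect (near-floor
# performance, as on the dorsum of the hand).
.norm_presets <- list(
  foot = list(n = 43L, alpha_ref = 3.0, age_factor = 1.05,
              alpha_cv = 0.45, beta = 0.5, lapse = 0.01),
  hand = list(n = 34L, alpha_ref = 0.55, age_factor = 1.0,
              alpha_cv = 0.45, beta = 0.5, lapse = 0.01)
)

#' Simulate a normative TDD cohort
#'
#' Draws ages uniformly over the normative range, builds one psychometric
#' observer per participant with between-subject lognormal variation in
#' sensitivity and (for the foot) a multiplicative per-year loss of
#' sensitivity, then runs the full adaptive staircase for each participant.
#' Sex is assigned at random and has no effect on scores (matching the null
#' sex effect the thresholds assume).
#'
#' @param n Number of participants (defaults per site: 43 foot, 34 hand).
#' @param site `"foot"` or `"hand"`.
#' @param age_range Age range in years, default 22-68.
#' @param alpha_ref Observer alpha (mm) at `ref_age`; site preset if `NULL`.
#' @param age_factor Multiplicative change in alpha per year of age; site
#'   preset if `NULL` (1 = no age effect).
#' @param alpha_cv Between-subject lognormal sd of alpha; preset if `NULL`.
#' @param beta,lapse Observer shape parameters; site presets if `NULL`.
#' @param ref_age Age (years) at which `alpha_ref` applies.
#' @param seed Optional integer seed (bit-reproducible output).
#' @return Data frame with columns `site`, `age`, `sex`, `raw_score`.
#' @export
simulate_normative_cohort <- function(n = NULL, site = c("foot", "hand"),
                                      age_range = c(22, 68),
                                      alpha_ref = NULL, age_factor = NULL,
                                      alpha_cv = NULL, beta = NULL,
                                      lapse = NULL, ref_age = 44,
                                      seed = NULL) {
  site <- match.arg(site)
  preset <- .norm_presets[[site]]
  if (is.null(n)) n <- preset$n
  if (is.null(alpha_ref)) alpha_ref <- preset$alpha_ref
  if (is.null(age_factor)) age_factor <- preset$age_factor
  if (is.null(alpha_cv)) alpha_cv <- preset$alpha_cv
  if (is.null(beta)) beta <- preset$beta
  if (is.null(lapse)) lapse <- preset$lapse
  .with_seed(seed, {
    age <- round(runif(n, age_range[1], age_range[2]))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    raw <- integer(n)
    for (i in seq_len(n)) {
      alpha_i <- alpha_ref * age_factor^(age[i] - ref_age) *
        rlnorm(1, 0, alpha_cv)
      obs <- psychometric_observer(alpha_i, beta = beta, lapse = lapse)
      raw[i] <- run_staircase(obs)$score
    }
    data.frame(site = site, age = age, sex = sex, raw_score = raw,
               stringsAsFactors = FALSE)
  })
}

.fill_shape <- function(grid, shape) {
  if (shape$type == "cuboid") {
    lo <- shape$corner
    hi <- shape$corner + shape$size - 1
    if (any(lo < 1) || any(hi > grid)) stop("node extends outside the grid")
    idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  } else if (shape$type == "sphere") {
    r <- shape$radius
    ctr <- shape$center
    lo <- pmax(floor(ctr - r), 1)
    hi <- pmin(ceiling(ctr + r), grid)
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
    idx <- g[d2 <= r^2, , drop = FALSE]
    if (any(ctr - r < 1) || any(ctr + r > grid))
      stop("node extends outside the grid")
  } else stop("unknown shape type: ", shape$type)
  idx
}

#' Build a phantom parcellation with known structure
#'
#' Fills a 3-D grid with labelled cuboids or spheres. Overlapping shapes are
#' rejected, so the component structure (and every node's voxel count) is
#' known by construction; deterministic given its arguments.
#'
#' @param grid Integer vector of grid dimensions, e.g. `c(30, 30, 30)`.
#' @param shapes List of shapes: `list(label =, type = "cuboid", corner =,
#'   size =)` or `list(label =, type = "sphere", center =, radius =)`.
#' @return Integer label array (0 = background).
#' @export
make_phantom_parcellation <- function(grid, shapes) {
  vol <- array(0L, grid)
  for (sh in shapes) {
    idx <- .fill_shape(grid, sh)
    lin <- (idx[, 3] - 1) * grid[1] * grid[2] + (idx[, 2] - 1) * grid[1] + idx[, 1]
    if (any(vol[lin] != 0)) stop("overlapping nodes are not allowed")
    vol[lin] <- as.integer(sh$label)
  }
  vol
}

#' Default phantom: two large nodes and one small (ineligible) node
#'
#' Two 12-cube parcels of 1728 voxels each (both above the 100-voxel node
#' criterion) and one 4-cube of 64 voxels (below it), on a 30-cube grid.
#'
#' @return List with `grid` and `shapes`, usable with
#'   [make_phantom_parcellation()].
#' @export
phantom_default_spec <- function() {
  list(grid = c(30L, 30L, 30L),
       shapes = list(
         list(label = 1L, type = "cuboid", corner = c(2, 2, 2),
              size = c(12, 12, 12)),
         list(label = 2L, type = "cuboid", corner = c(17, 2, 2),
              size = c(12, 12, 12)),
         list(label = 3L, type = "cuboid", corner = c(17, 17, 17),
              size = c(4, 4, 4))))
}

.cuboid_mask <- function(grid, corner, size) {
  m <- array(0L, grid)
  m[corner[1]:(corner[1] + size[1] - 1),
    corner[2]:(corner[2] + size[2] - 1),
    corner[3]:(corner[3] + size[3] - 1)] <- 1L
  m
}

#' Simulate a patient cohort with node-linked deficits
#'
#' Emulates the study design on a phantom: `n_lesioned` patients receive a
#' lesion placed inside the designated deficit node (sufficient overlap by
#' construction), the rest receive lesions in background tissue. In `"fast"`
#' mode relative TDD scores are drawn directly: every site-time score is
#' normal with mean `score_mean` and sd `score_sd`, and patients lesioned in
#' the deficit node have their left-side scores shifted up (worse) so the
#' left composite moves by `effect_size` pooled composite standard
#' deviations. In `"full"` mode raw scores are produced by degrading a
#' psychometric observer and running the staircase, then converted to
#' relative scores with the [reference_thresholds()].
#'
#' @param n_patients Number of patients (default 28).
#' @param n_lesioned Patients lesioned in the deficit node (default
#'   `round(0.3 * n_patients)`).
#' @param effect_size Deficit size in composite standard deviations (default
#'   1.5; 0 gives a null cohort).
#' @param score_mean,score_sd Site-level relative-score distribution in fast
#'   mode.
#' @param mode `"fast"` (score-level injection) or `"full"` (observer +
#'   staircase).
#' @param phantom Phantom spec as [phantom_default_spec()].
#' @param nodes Optional precomputed [split_into_contiguous_nodes()] result
#'   for the phantom (to amortise labelling across replicates).
#' @param deficit_label Parcel label whose node carries the deficit.
#' @param lesion_alpha_factor Full mode: multiplicative observer degradation
#'   on lesioned-side sites.
#' @param seed Optional integer seed.
#' @return List of class `tdd_synth_cohort`: `cohort` (cohort-format data
#'   frame with `target` = lesioned-in-deficit-node), `lesions` (list of
#'   masks), `nodes`, `ground_truth` (`deficit_node` id, `lesioned` indices).
#' @export
simulate_patient_cohort <- function(n_patients = 28L, n_lesioned = NULL,
                                    effect_size = 1.5, score_mean = -0.2,
                                    score_sd = 0.35,
                                    mode = c("fast", "full"),
                                    phantom = phantom_default_spec(),
                                    nodes = NULL, deficit_label = 1L,
                                    lesion_alpha_factor = 3,
                                    seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_lesioned)) n_lesioned <- round(0.3 * n_patients)
  if (is.null(nodes)) {
    parc <- make_phantom_parcellation(phantom$grid, phantom$shapes)
    nodes <- split_into_contiguous_nodes(parc)
  }
  grid <- dim(nodes$nodes)
  deficit_node <- nodes$table$node[nodes$table$parent_label == deficit_label][1]
  .with_seed(seed, {
    lesioned <- sort(sample(n_patients, n_lesioned))
    is_les <- seq_len(n_patients) %in% lesioned
    lesions <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      if (is_les[i]) {
        corner <- c(sample(2:6, 1), sample(2:6, 1), sample(2:6, 1))
        lesions[[i]] <- .cuboid_mask(grid, corner, c(8, 8, 8))
      } else {
        corner <- c(sample(2:8, 1), sample(17:23, 1), sample(2:23, 1))
        lesions[[i]] <- .cuboid_mask(grid, corner, c(6, 6, 6))
      }
    }
    age <- round(runif(n_patients, 29, 82))
    sex <- sample(c("F", "M"), n_patients, replace = TRUE)
    site_cols <- as.vector(outer(.sites, c("_acute", "_3m"), paste0))
    if (mode == "fast") {
      sc <- matrix(rnorm(n_patients * 8, score_mean, score_sd),
                   n_patients, 8, dimnames = list(NULL, site_cols))
      # shift each left site so the left composite moves by
      # effect_size * sd(composite) = effect_size * score_sd * sqrt(2)
      shift <- effect_size * score_sd / sqrt(2)
      for (cl in c("lh_acute", "lf_acute", "lh_3m", "lf_3m"))
        sc[is_les, cl] <- sc[is_les, cl] + shift
    } else {
      thr <- reference_thresholds()
      sc <- matrix(NA_real_, n_patients, 8,
                   dimnames = list(NULL, site_cols))
      for (i in seq_len(n_patients)) {
        for (cl in site_cols) {
          st <- substr(cl, 1, 2)
          fp <- .norm_presets[[if (st %in% c("rf", "lf")) "foot" else "hand"]]
          alpha_i <- fp$alpha_ref * fp$age_factor^(age[i] - 44) *
            rlnorm(1, 0, fp$alpha_cv)
          if (is_les[i] && st %in% c("lh", "lf"))
            alpha_i <- alpha_i * lesion_alpha_factor
          raw <- run_staircase(psychometric_observer(alpha_i, beta = fp$beta,
                                                     lapse = fp$lapse))$score
          model <- if (st %in% c("rf", "lf")) thr$foot else thr$hand
          sc[i, cl] <- relative_score(raw, predict(model, age[i]))
        }
      }
    }
    cohort <- data.frame(patient = seq_len(n_patients), age = age, sex = sex,
                         stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(sc))
    cohort$lesion <- ifelse(is_les, "phantom deficit node", "phantom other")
    cohort$target <- is_les
    for (cl in as.vector(outer(paste0("sd_", .sites), c("_acute", "_3m"),
                               paste0)))
      cohort[[cl]] <- FALSE
    class(cohort) <- c("tdd_cohort", "data.frame")
    structure(list(cohort = cohort, lesions = lesions, nodes = nodes,
                   ground_truth = list(deficit_node = deficit_node,
                                       lesioned = lesioned,
                                       effect_size = effect_size)),
              class = "tdd_synth_cohort")
  })
}
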