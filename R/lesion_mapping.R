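#' Eligibility criteria for node-level lesion-symptom mapping
#'
#' Three criteria control which parcellation nodes enter the analysis:
#' (i) a node must contain strictly more than `min_node_voxels` voxels;
#' (ii) a patient counts as lesioned in a node when the lesion covers at
#' least `min(overlap_abs, ceiling(overlap_frac * node_size))` voxels of it
#' (the smaller of an absolute and a fractional criterion, since nodes vary a
#' lot in size); (iii) a node is analysed only when at least `min_patients`
#' patients are lesioned in it.
#'
#' @param min_node_voxels Minimum node size (strict, default 100).
#' @param overlap_abs Absolute overlap criterion in voxels (default 100).
#' @param overlap_frac Fractional overlap criterion (default 0.10).
#' @param min_patients Minimum lesioned patients per analysed node (default 4).
#' @return Object of class `tdd_node_criteria`.
#' @export
node_criteria <- function(min_node_voxels = 100, overlap_abs = 100,
                          overlap_frac = 0.10, min_patients = 4) {
  stopifnot(min_node_voxels > 0, overlap_abs > 0,
            overlap_frac > 0, overlap_frac <= 1, min_patients > 0)
  structure(list(min_node_voxels = min_node_voxels,
                 overlap_abs = overlap_abs, overlap_frac = overlap_frac,
                 min_patients = min_patients),
            class = "tdd_node_criteria")
}

.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  r <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = r == 1, "18" = r <= 2, "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Split a parcellation into contiguous nodes
#'
#' Connected-component labelling within each parcel label of a 3-D integer
#' label volume (0 = background), producing one "node" per contiguous
#' component. Node ids are stable: sorted by parent label, then by size
#' descending (ties by first voxel in array order).
#'
#' @param parcellation 3-D integer array of parcel labels (0 = background).
#' @param connectivity Voxel neighbourhood: 6 (faces, default), 18 or 26.
#' @return List with `nodes` (integer array of node ids, 0 = background) and
#'   `table` (data frame: `node`, `parent_label`, `n_voxels`).
#' @export
split_into_contiguous_nodes <- function(parcellation, connectivity = 6) {
  vol <- parcellation
  dims <- dim(vol)
  if (length(dims) != 3) stop("parcellation must be a 3-D array")
  if (any(vol < 0)) stop("labels must be nonnegative")
  offs <- .neighbor_offsets(connectivity)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  comp <- integer(length(vol))
  v <- as.integer(round(as.vector(vol)))
  seeds <- which(v != 0)
  next_id <- 0L
  first_voxel <- integer(0)
  parent <- integer(0)
  for (s in seeds) {
    if (comp[s] != 0L) next
    next_id <- next_id + 1L
    lab <- v[s]
    parent[next_id] <- lab
    first_voxel[next_id] <- s
    comp[s] <- next_id
    frontier <- s
    while (length(frontier)) {
      i <- ((frontier - 1L) %% nx) + 1L
      j <- (((frontier - 1L) %/% nx) %% ny) + 1L
      kk <- ((frontier - 1L) %/% (nx * ny)) + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; zz <- kk + offs[o, 3]
        ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & zz >= 1 & zz <= nz
        if (!any(ok)) next
        lin <- (zz[ok] - 1L) * nx * ny + (jj[ok] - 1L) * nx + ii[ok]
        lin <- lin[v[lin] == lab & comp[lin] == 0L]
        if (length(lin)) {
          lin <- unique(lin)
          comp[lin] <- next_id
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  if (next_id == 0L) {
    nodes <- array(0L, dims)
    return(list(nodes = nodes,
                table = data.frame(node = integer(0), parent_label = integer(0),
                                   n_voxels = integer(0))))
  }
  sizes <- tabulate(comp, nbins = next_id)
  ord <- order(parent, -sizes, first_voxel)
  relabel <- integer(next_id)
  relabel[ord] <- seq_len(next_id)
  out <- integer(length(vol))
  nz_idx <- comp != 0L
  out[nz_idx] <- relabel[comp[nz_idx]]
  nodes <- array(out, dims)
  tab <- data.frame(node = seq_len(next_id),
                    parent_label = parent[ord],
                    n_voxels = sizes[ord])
  list(nodes = nodes, table = tab)
}

#' Filter nodes by the size criterion
#'
#' Keeps nodes with strictly more voxels than `min_node_voxels` (a node of
#' exactly the minimum size is excluded).
#'
#' @param node_table Node table from [split_into_contiguous_nodes()].
#' @param criteria A [node_criteria()].
#' @return Subset of `node_table`.
#' @export
eligible_nodes <- function(node_table, criteria = node_criteria()) {
  node_table[node_table$n_voxels > criteria$min_node_voxels, , drop = FALSE]
}

.check_geometry <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("geometry mismatch: volumes have different grid dimensions; ",
         "no resampling is performed")
  invisible(TRUE)
}

#' Does a lesion sufficiently overlap a node?
#'
#' The overlap criterion is `min(overlap_abs, ceiling(overlap_frac *
#' node_size))` voxels, so small nodes use the fractional rule and large nodes
#' the absolute one. Volumes must share one grid; there is no silent
#' resampling.
#'
#' @param lesion Binary 3-D lesion mask.
#' @param nodes Node id volume from [split_into_contiguous_nodes()].
#' @param node_id Node to test.
#' @param criteria A [node_criteria()].
#' @param node_size Optional precomputed node size in voxels.
#' @return Logical.
#' @export
lesion_in_node <- function(lesion, nodes, node_id,
                           criteria = node_criteria(), node_size = NULL) {
  .check_geometry(lesion, nodes)
  in_node <- nodes == node_id
  if (is.null(node_size)) node_size <- sum(in_node)
  required <- min(criteria$overlap_abs,
                  ceiling(criteria$overlap_frac * node_size))
  overlap <- sum(lesion[in_node] != 0)
  overlap >= required
}

#' Build the patients-by-nodes lesion matrix
#'
#' Applies the overlap criterion to every patient and every eligible node.
#' Nodes with at least `min_patients` lesioned patients are marked analyzable.
#'
#' @param lesions List of binary lesion masks, one per patient, sharing the
#'   node volume's grid.
#' @param nodes Node id volume.
#' @param node_table Node table from [split_into_contiguous_nodes()].
#' @param criteria A [node_criteria()].
#' @return Object of class `tdd_node_matrix`: list with `matrix` (logical
#'   patients x eligible nodes), `node_table` (eligible nodes) and
#'   `analyzable` (logical per eligible node).
#' @export
build_matrix <- function(lesions, nodes, node_table,
                         criteria = node_criteria()) {
  elig <- eligible_nodes(node_table, criteria)
  M <- matrix(FALSE, length(lesions), nrow(elig),
              dimnames = list(names(lesions), paste0("node", elig$node)))
  for (p in seq_along(lesions)) {
    .check_geometry(lesions[[p]], nodes)
    for (j in seq_len(nrow(elig))) {
      M[p, j] <- lesion_in_node(lesions[[p]], nodes, elig$node[j],
                                criteria, node_size = elig$n_voxels[j])
    }
  }
  structure(list(matrix = M, node_table = elig,
                 analyzable = colSums(M) >= criteria$min_patients,
                 criteria = criteria),
            class = "tdd_node_matrix")
}

#' @export
print.tdd_node_matrix <- function(x, ...) {
  cat(sprintf("Node-lesion matrix: %d patients x %d eligible nodes (%d analyzable)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$analyzable)))
  invisible(x)
}

#' Side-composite relative TDD scores
#'
#' Per patient, the left composite is the sum of the left-hand and left-foot
#' relative scores at one time point, and likewise on the right.
#'
#' @param cohort Cohort data frame.
#' @param timepoint `"followup"` or `"acute"`.
#' @return Data frame with `patient`, `left`, `right`.
#' @export
side_composite_scores <- function(cohort, timepoint = c("followup", "acute")) {
  suf <- .tp_suffix(timepoint)
  data.frame(patient = cohort$patient,
             left = cohort[[paste0("lh", suf)]] + cohort[[paste0("lf", suf)]],
             right = cohort[[paste0("rh", suf)]] + cohort[[paste0("rf", suf)]])
}

#' Node-level lesion-symptom tests
#'
#' For every analyzable node and each body side, compares the side-composite
#' relative scores of patients lesioned in the node against the rest with a
#' one-tailed two-sample t test (lesioned group worse, i.e. higher scores;
#' pooled variance by default), then applies Holm-Bonferroni across all tests
#' performed.
#'
#' @param node_matrix A `tdd_node_matrix` from [build_matrix()].
#' @param side_scores Data frame from [side_composite_scores()], rows aligned
#'   with the lesion list used to build the matrix.
#' @param alpha Family-wise error level.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Data frame with one row per node-side test: `node`, `side`,
#'   `n_lesioned`, `t`, `df`, `p.value`, `critical_alpha`, `reject`.
#' @export
node_symptom_test <- function(node_matrix, side_scores, alpha = 0.05,
                              var_equal = TRUE) {
  stopifnot(inherits(node_matrix, "tdd_node_matrix"),
            nrow(side_scores) == nrow(node_matrix$matrix))
  an <- which(node_matrix$analyzable)
  if (!length(an)) stop("no analyzable nodes")
  rows <- list()
  for (j in an) {
    lesioned <- node_matrix$matrix[, j]
    for (side in c("left", "right")) {
      g1 <- side_scores[[side]][lesioned]
      g0 <- side_scores[[side]][!lesioned]
      if (length(g1) < 2 || length(g0) < 2) {
        warning(sprintf("node %s, %s side: a group has fewer than 2 patients; skipped",
                        colnames(node_matrix$matrix)[j], side))
        next
      }
      tt <- t.test(g1, g0, alternative = "greater", var.equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        node = node_matrix$node_table$node[j], side = side,
        n_lesioned = sum(lesioned), t = unname(tt$statistic),
        df = unname(tt$parameter), p.value = tt$p.value)
    }
  }
  if (!length(rows)) stop("no node-side test could be performed")
  res <- do.call(rbind, rows)
  hb <- holm_bonferroni(res$p.value, alpha)
  res$critical_alpha <- hb$critical_alpha
  res$reject <- hb$reject
  res
}

#' Target-area association with TDD impairment
#'
#' Builds the 2x2 table of (lesion includes a target area) versus (abnormal
#' TDD at the chosen time point) from a cohort table, and runs the one-sided
#' Fisher exact test with the conditional exact odds-ratio bound. Patients
#' with a missing target annotation are excluded with a warning.
#'
#' @param cohort Cohort data frame with a logical `target` column.
#' @param timepoint `"followup"` or `"acute"`.
#' @param conf.level One-sided confidence level for the odds-ratio bound.
#' @return List with `table` (2x2: rows target/other, columns
#'   impaired/normal), `p.value`, `or_ci`, `n`.
#' @export
target_area_association <- function(cohort,
                                    timepoint = c("followup", "acute"),
                                    conf.level = 0.95) {
  cls <- classify_cohort(cohort, timepoint)
  keep <- !is.na(cohort$target)
  if (any(!keep))
    warning(sum(!keep), " patient(s) without lesion annotation excluded")
  tgt <- as.logical(cohort$target)[keep]
  abn <- cls$abnormal[keep]
  tab <- matrix(c(sum(tgt & abn), sum(tgt & !abn),
                  sum(!tgt & abn), sum(!tgt & !abn)),
                2, 2, byrow = TRUE,
                dimnames = list(c("target", "other"),
                                c("impaired", "normal")))
  list(table = tab,
       p.value = fisher_exact_one_sided(tab),
       or_ci = fisher_or_ci(tab, conf.level),
       n = sum(keep))
}
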