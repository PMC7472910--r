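test_that("connected-component splitting recovers known phantom structure", {
  # one cuboid of a single label -> one node of that size
  v <- array(0L, c(10, 10, 10))
  v[2:4, 2:4, 2:4] <- 1L
  sp <- split_into_contiguous_nodes(v)
  expect_equal(nrow(sp$table), 1)
  expect_equal(sp$table$n_voxels, 27)

  # two disjoint cubes sharing a label -> two nodes
  v[7:9, 7:9, 7:9] <- 1L
  sp2 <- split_into_contiguous_nodes(v)
  expect_equal(nrow(sp2$table), 2)
  expect_equal(sort(sp2$table$n_voxels), c(27, 27))
  expect_true(all(sp2$table$parent_label == 1))

  # corner-touching cubes are separate under 6-connectivity, merged under 26
  w <- array(0L, c(6, 6, 6))
  w[1:2, 1:2, 1:2] <- 1L
  w[3:4, 3:4, 3:4] <- 1L
  expect_equal(nrow(split_into_contiguous_nodes(w, 6)$table), 2)
  expect_equal(nrow(split_into_contiguous_nodes(w, 26)$table), 1)

  # node voxel counts sum to the parcellation's nonzero count
  spec <- phantom_default_spec()
  parc <- make_phantom_parcellation(spec$grid, spec$shapes)
  sp3 <- split_into_contiguous_nodes(parc)
  expect_equal(sum(sp3$table$n_voxels), sum(parc != 0))
  expect_equal(sp3$table$n_voxels, c(1728, 1728, 64))
  expect_equal(sp3$table$parent_label, c(1L, 2L, 3L))

  # empty parcellation -> empty table
  sp4 <- split_into_contiguous_nodes(array(0L, c(4, 4, 4)))
  expect_equal(nrow(sp4$table), 0)
})

test_that("node eligibility is strict at the 100-voxel boundary", {
  tab <- data.frame(node = 1:3, parent_label = 1L,
                    n_voxels = c(100L, 101L, 5000L))
  kept <- eligible_nodes(tab, node_criteria())
  expect_equal(kept$node, c(2L, 3L))
})

test_that("lesion-in-node uses the smaller of absolute and fractional overlap", {
  # node of 2000 voxels: requirement is min(100, 200) = 100
  g <- c(20, 20, 20)
  nodes <- array(0L, g)
  nodes[1:20, 1:10, 1:10] <- 1L  # 2000 voxels
  crit <- node_criteria()
  les99 <- array(0L, g); les99[1:20, 1:5, 1][1:99] <- 1L
  stopifnot(sum(les99[nodes == 1]) == 99)
  expect_false(lesion_in_node(les99, nodes, 1, crit))
  les100 <- les99; les100[20, 5, 2] <- 1L
  expect_true(lesion_in_node(les100, nodes, 1, crit))

  # node of 500 voxels: requirement is min(100, 50) = 50
  nodes2 <- array(0L, g)
  nodes2[1:5, 1:10, 1:10] <- 2L
  les50 <- array(0L, g); les50[1:5, 1:10, 1] <- 1L
  expect_true(lesion_in_node(les50, nodes2, 2, crit))
  expect_false(lesion_in_node(array(0L, g), nodes2, 2, crit))

  # monotone: adding lesion voxels never flips TRUE -> FALSE
  grown <- les50; grown[1:5, 1:10, 2] <- 1L
  expect_true(lesion_in_node(grown, nodes2, 2, crit))

  # mismatched grids are rejected, never resampled
  expect_error(lesion_in_node(array(0L, c(10, 10, 10)), nodes2, 2, crit),
               "geometry mismatch")
})

test_that("the lesion matrix flags analyzable nodes at the 4-patient rule", {
  spec <- phantom_default_spec()
  parc <- make_phantom_parcellation(spec$grid, spec$shapes)
  sp <- split_into_contiguous_nodes(parc)
  mask_in_node1 <- function() {
    m <- array(0L, spec$grid); m[2:9, 2:9, 2:9] <- 1L; m
  }
  empty <- array(0L, spec$grid)

  # three lesioned patients: node not analyzable
  lesions3 <- c(replicate(3, mask_in_node1(), simplify = FALSE),
                replicate(4, empty, simplify = FALSE))
  nm3 <- build_matrix(lesions3, sp$nodes, sp$table)
  expect_equal(sum(nm3$analyzable), 0)

  # four: exactly the deficit node analyzable
  lesions4 <- c(replicate(4, mask_in_node1(), simplify = FALSE),
                replicate(4, empty, simplify = FALSE))
  nm4 <- build_matrix(lesions4, sp$nodes, sp$table)
  expect_equal(sum(nm4$analyzable), 1)
  expect_equal(nm4$node_table$node[nm4$analyzable], 1L)
  # the small 64-voxel node never appears among the columns
  expect_false("node3" %in% colnames(nm4$matrix))
})

test_that("node-level tests are one-tailed toward worse scores with Holm control", {
  spec <- phantom_default_spec()
  parc <- make_phantom_parcellation(spec$grid, spec$shapes)
  sp <- split_into_contiguous_nodes(parc)
  synth <- simulate_patient_cohort(nodes = sp, seed = 31)
  nm <- build_matrix(synth$lesions, sp$nodes, sp$table)
  scores <- side_composite_scores(synth$cohort, "followup")
  res <- node_symptom_test(nm, scores)
  expect_equal(sort(res$critical_alpha), c(0.025, 0.05))
  expect_true(all(res$df == nrow(synth$cohort) - 2))  # pooled-variance df

  # equal group means give t = 0 and one-tailed p = 0.5
  flat <- scores
  set.seed(8)
  base <- rnorm(nrow(flat))
  # centre each group so the two means coincide while variance remains
  flat$left <- base - ave(base, nm$matrix[, 1])
  flat$right <- flat$left
  res0 <- node_symptom_test(nm, flat)
  expect_equal(res0$t, rep(0, nrow(res0)), tolerance = 1e-12)
  expect_equal(res0$p.value, rep(0.5, nrow(res0)), tolerance = 1e-12)
})

test_that("target-area association reproduces the fixture's 2x2 and degenerates safely", {
  co <- table2_fixture()
  assoc <- target_area_association(co)
  expect_equal(unname(assoc$table["target", ]), c(9L, 0L))
  expect_equal(unname(assoc$table["other", ]), c(12L, 7L))
  expect_equal(sum(assoc$table), 28)

  no_target <- co
  no_target$target <- FALSE
  expect_equal(target_area_association(no_target)$p.value, 1)

  with_na <- co
  with_na$target[3] <- NA
  expect_warning(a2 <- target_area_association(with_na), "excluded")
  expect_equal(a2$n, 27)
})
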