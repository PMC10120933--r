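test_that("thinning collapses bars to lines, keeps singletons, is idempotent", {
  m <- matrix(FALSE, 20, 40)
  m[9:11, 5:24] <- TRUE               # 3-px-wide bar of length 20
  sk <- skeletonize(m, 1)$mask
  expect_true(all(sk[!m] == FALSE))   # subset of the foreground
  expect_equal(max(octaquant:::cpp_label8(sk)), 1)
  expect_true(sum(sk) <= 20 && sum(sk) >= 16)  # a ~1-px medial line
  expect_true(all(rowSums(sk)[c(1:7, 13:20)] == 0))

  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(skeletonize(single, 1)$mask, single)
  expect_equal(sum(skeletonize(matrix(FALSE, 8, 8), 1)$mask), 0)
})

test_that("thinning preserves component count and is a fixed point on random masks", {
  set.seed(99)
  for (k in 1:25) {
    m <- random_vessel_mask(32, 32)
    sk <- skeletonize(m, 1)$mask
    expect_true(all(!sk[!m]))
    expect_equal(max(octaquant:::cpp_label8(sk)), max(octaquant:::cpp_label8(m)))
    expect_identical(skeletonize(sk, 1)$mask, sk)
    # 1-px wide: no solid 2x2 block survives
    expect_false(octaquant:::has_thick_block(sk))
  }
})

test_that("tagging the cross, the line and the lone pixel gives the hand counts", {
  g <- tag_skeleton(vessel_map(cross_raster(31, 10), 1))
  expect_equal(sum(g$nodes$kind == "junction"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4)
  expect_equal(nrow(g$branches), 4)

  line <- matrix(FALSE, 5, 60); line[3, 6:55] <- TRUE
  gl <- tag_skeleton(vessel_map(line, 1))
  expect_equal(sum(gl$nodes$kind == "junction"), 0)
  expect_equal(sum(gl$nodes$kind == "endpoint"), 2)
  expect_equal(nrow(gl$branches), 1)
  expect_equal(gl$branches$geodesic_mm, gl$branches$euclidean_mm)
  expect_equal(gl$branches$geodesic_mm, 49)  # 49 axial steps at scale 1

  lone <- matrix(FALSE, 7, 7); lone[4, 4] <- TRUE
  gi <- tag_skeleton(vessel_map(lone, 1))
  expect_equal(gi$nodes$kind, "isolated")
  expect_equal(nrow(gi$branches), 0)

  thick <- matrix(FALSE, 6, 6); thick[2:3, 2:3] <- TRUE
  expect_error(tag_skeleton(vessel_map(thick, 1)), "thin")
})

test_that("geodesic metrics: diagonal runs, chain vs polyline, arc-chord bound", {
  diagonal <- diag(TRUE, 100) | matrix(FALSE, 100, 100)
  for (lm in c("polyline", "chain")) {
    gd <- tag_skeleton(vessel_map(diagonal, 170), length_method = lm)
    expect_equal(gd$branches$geodesic_mm, 99 * sqrt(2) / 170, tolerance = 1e-12)
  }
  # geodesic >= euclidean on arbitrary thin skeletons
  set.seed(17)
  for (k in 1:10) {
    g <- tag_skeleton(skeletonize(random_vessel_mask(32, 32), 1))
    if (nrow(g$branches))
      expect_true(all(g$branches$geodesic_mm >= g$branches$euclidean_mm - 1e-9))
  }
})

test_that("pixel classification agrees with the neighbour-count oracle", {
  set.seed(23)
  for (k in 1:10) {
    sk <- skeletonize(random_vessel_mask(32, 32), 1)$mask
    nb <- octaquant:::cpp_neighbour_count8(sk)
    idx <- which(sk, arr.ind = TRUE)
    for (i in seq_len(nrow(idx)))
      expect_equal(nb[idx[i, 1], idx[i, 2]],
                   oracle_neighbour_count(sk, idx[i, 1], idx[i, 2]))
  }
})

test_that("every skeleton pixel is accounted for exactly once (conservation)", {
  set.seed(31)
  for (k in 1:15) {
    sk <- skeletonize(random_vessel_mask(40, 40), 1)$mask
    g <- tag_skeleton(vessel_map(sk, 1))
    n_junction_px <- sum(g$nodes$n_pixels[g$nodes$kind == "junction"])
    n_end <- sum(g$nodes$kind == "endpoint")
    n_iso <- sum(g$nodes$kind == "isolated")
    n_slab <- if (nrow(g$branches)) sum(g$branches$n_slab) else 0
    expect_equal(n_slab + n_junction_px + n_end + n_iso, sum(sk))
  }
})

test_that("pruning removes flecks and short spurs and reaches a fixed point", {
  # a 2-px fleck next to a large cross: only the cross survives
  m <- cross_raster(41, 15)
  m[3, 3:4] <- TRUE
  g <- tag_skeleton(vessel_map(m, 1))
  gp <- prune_skeleton(g, prune_config(min_component_pixels = 5))
  expect_equal(max(octaquant:::cpp_label8(gp$mask)), 1)
  expect_equal(sum(gp$nodes$kind == "junction"), 1)

  # the all-defaults configuration with the end-branch rule off is identity
  g0 <- prune_skeleton(g, prune_config(min_component_pixels = 0,
                                       prune_end_branches_shorter_than = 0))
  expect_identical(g0$mask, g$mask)

  # "+" with one 2-px arm: pruning that arm leaves a 3-armed junction
  p <- matrix(FALSE, 31, 31)
  p[16, 6:26] <- TRUE                 # full horizontal
  p[6:16, 16] <- TRUE                 # upper arm only
  p[17:18, 16] <- TRUE                # stub lower arm, 2 px
  gs <- tag_skeleton(vessel_map(p, 1))
  gp2 <- prune_skeleton(gs, prune_config(min_component_pixels = 0,
                                         prune_end_branches_shorter_than = 5))
  expect_equal(sum(gp2$nodes$kind == "junction"), 1)
  expect_equal(sum(gp2$nodes$kind == "endpoint"), 3)
  expect_equal(nrow(gp2$branches), 3)
})

test_that("small enclosed holes are filled, real background is not", {
  m <- matrix(FALSE, 20, 20)
  m[5:15, 5:15] <- TRUE
  m[10, 10] <- FALSE                  # 1-px hole
  f <- fill_small_holes(m, 10)
  expect_true(f[10, 10])
  expect_equal(sum(f), sum(m) + 1)
  # border-touching background is never filled
  expect_identical(fill_small_holes(!m & FALSE, 10), !m & FALSE)
  big <- matrix(TRUE, 30, 30); big[10:20, 10:20] <- FALSE  # 121-px hole
  expect_identical(fill_small_holes(big, 10), big)
})
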