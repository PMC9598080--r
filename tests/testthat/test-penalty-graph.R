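test_that("neighbor spec enumerates the radius-4 offset set", {
  nb <- neighborSpec(4)
  expect_equal(nrow(nb@offsets), 48L)
  expect_false(any(nb@offsets[, 1] == 0 & nb@offsets[, 2] == 0))
  expect_equal(anyDuplicated(paste(nb@offsets[, 1], nb@offsets[, 2])), 0L)
  expect_true(all(sqrt(rowSums(nb@offsets^2)) <= 4))
  # radius 1 is the 4-connected neighborhood
  expect_equal(nrow(neighborSpec(1)@offsets), 4L)
})

test_that("identical phasor maps produce an all-zero penalty graph", {
  p <- matrix(exp(1i * 0.3), 4, 4)
  g <- buildPenaltyGraph(matrix(1, 4, 4), p, p, neighborSpec(2))
  expect_true(all(g@blocks == 0))
  expect_equal(selectionEnergy(g, matrix(1L, 4, 4)), 0)
  expect_equal(selectionEnergy(g, matrix(2L, 4, 4)), 0)
})

test_that("penalty blocks match the hand-evaluated formula on a pixel pair", {
  # |S1| = (2, 3), opposed unit phasors, distance 1:
  # min(2, 3) / 1 * |1 - (-1)|^2 = 8
  s1m <- matrix(c(2, 3), 1, 2)
  p1 <- matrix(c(1 + 0i, -1 + 0i), 1, 2)
  p2 <- matrix(c(1i, 1i), 1, 2)
  g <- buildPenaltyGraph(s1m, p1, p2, neighborSpec(1))
  expect_equal(length(g@r), 2L) # both ordered directions
  k <- which(g@r == 1L & g@s == 2L)
  expect_equal(g@blocks[k, "v11"], 8)
  # candidate-2/candidate-2 pair: identical phasors, zero penalty
  expect_equal(g@blocks[k, "v22"], 0)
  # energy of labels (1, 1): 8 per ordered pair
  expect_equal(selectionEnergy(g, c(1L, 1L)), 16)
  expect_equal(selectionEnergy(g, c(2L, 2L)), 0)
  expect_error(selectionEnergy(g, c(1L, 3L)), "labels")
})

test_that("the distance weighting divides by default and can multiply", {
  s1m <- matrix(1, 1, 3)
  p1 <- matrix(c(1 + 0i, 1i, -1 + 0i), 1, 3)
  p2 <- p1
  nb <- neighborSpec(2)
  gDiv <- buildPenaltyGraph(s1m, p1, p2, nb)
  gMul <- buildPenaltyGraph(s1m, p1, p2, nb, distanceWeight = "multiply")
  k <- which(gDiv@r == 1L & gDiv@s == 3L) # distance 2
  expect_equal(gMul@blocks[k, "v11"], 4 * gDiv@blocks[k, "v11"])
})

test_that("neighbors outside the image are dropped, no wraparound", {
  g <- buildPenaltyGraph(
    matrix(1, 3, 3), matrix(1 + 0i, 3, 3), matrix(1i, 3, 3), neighborSpec(1)
  )
  # corner pixels have 2 neighbors, edges 3, center 4
  degree <- table(g@r)
  expect_equal(sort(unique(as.integer(degree))), c(2L, 3L, 4L))
  expect_equal(length(g@r), 24L) # 2 * number of 4-adjacencies on 3x3
})

test_that("energy is symmetric under relabeling with exchanged candidates", {
  g <- randomPhasorGraph(4, 4, seed = 5, radius = 2)
  withr::with_seed(8, {
    lab <- matrix(sample(1:2, 16, replace = TRUE), 4, 4)
  })
  # rebuild with p1/p2 exchanged by swapping block columns
  gSwap <- g
  gSwap@blocks <- g@blocks[, c(4, 3, 2, 1), drop = FALSE]
  colnames(gSwap@blocks) <- colnames(g@blocks)
  expect_equal(
    selectionEnergy(g, lab),
    selectionEnergy(gSwap, 3L - lab)
  )
})

test_that("brute force finds the global optimum with lexicographic ties", {
  # all-zero graph: all labelings tie at zero, all-1 wins the tie-break
  p <- matrix(1 + 0i, 1, 3)
  g0 <- buildPenaltyGraph(matrix(1, 1, 3), p, p, neighborSpec(1))
  bf <- bruteForceSelect(g0)
  expect_equal(bf@energy, 0)
  expect_true(all(bf@labels == 1L))

  # two-pixel graph where only the (1, 2) assignment has zero penalty
  s1m <- matrix(1, 1, 2)
  p1 <- matrix(c(1 + 0i, 1i), 1, 2)
  p2 <- matrix(c(-1i, 1 + 0i), 1, 2)
  g <- buildPenaltyGraph(s1m, p1, p2, neighborSpec(1))
  bf <- bruteForceSelect(g)
  expect_equal(as.integer(bf@labels), c(1L, 2L))
  expect_equal(bf@energy, 0)

  # global optimality: never beaten by random labelings
  g8 <- randomPhasorGraph(2, 4, seed = 3, radius = 3)
  bf8 <- bruteForceSelect(g8)
  withr::with_seed(10, {
    for (i in 1:50) {
      lab <- sample(1:2, 8, replace = TRUE)
      expect_gte(selectionEnergy(g8, lab), bf8@energy)
    }
  })
  expect_error(bruteForceSelect(randomPhasorGraph(5, 5, 1)), "20 pixels")
})
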