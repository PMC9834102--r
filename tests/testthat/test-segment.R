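test_that("component labelling agrees with a flood-fill oracle at both connectivities", {
  set.seed(21)
  for (rep in 1:10) {
    m <- randomMask(12, 12, p = 0.4)
    for (conn in c(4, 8)) {
      got <- labelComponents(m, conn)
      want <- floodFillLabels(m, conn)
      # same partition: label images equal up to renaming
      expect_equal(got > 0, want > 0)
      expect_equal(length(unique(got[got > 0])),
                   length(unique(want[want > 0])))
      key <- paste(got[got > 0], want[want > 0])
      expect_equal(length(unique(key)), length(unique(got[got > 0])))
    }
  }
})

test_that("labelling matches EBImage's 4-connected labeller", {
  set.seed(5)
  for (rep in 1:5) {
    m <- randomMask(16, 16, p = 0.35)
    lab <- labelComponents(m, connectivity = 4)
    ref <- EBImage::bwlabel(m * 1)
    expect_equal(max(lab), max(ref))
    key <- paste(lab[m], ref[m])
    expect_equal(length(unique(key)), max(lab))
  }
})

test_that("diagonally touching pixels merge under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(labelComponents(m, 8)), 1L)
  expect_equal(max(labelComponents(m, 4)), 2L)
  expect_false(any(removeSmallComponents(m, minSize = 2, connectivity = 4)))
  expect_true(all(removeSmallComponents(m, minSize = 2, connectivity = 8) == m))
})

test_that("mean + SD thresholding matches the hand-computed example", {
  # trepanation of 5 pixels with values {0,0,0,0,10}: mean 2,
  # population SD 4, threshold 6 -> exactly the 10-valued pixel survives
  m <- matrix(0, 1, 5); m[1, 5] <- 10
  trep <- matrix(TRUE, 1, 5)
  th <- thresholdActivity(m, trep)
  expect_equal(th$zThresh, 6)
  expect_equal(which(th$mask), 5L)

  # constant map: SD 0, strict inequality leaves nothing
  flat <- thresholdActivity(matrix(2, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(flat$zThresh, 2)
  expect_false(any(flat$mask))

  expect_error(thresholdActivity(m, matrix(FALSE, 1, 5)), "empty")
})

test_that("thresholding restricts to the trepanation and scales with kSd", {
  set.seed(13)
  m <- matrix(stats::runif(100), 10, 10)
  trep <- matrix(FALSE, 10, 10); trep[3:8, 3:8] <- TRUE
  th <- thresholdActivity(m, trep)
  expect_false(any(th$mask & !trep))
  v <- m[trep]
  expect_equal(th$zThresh, mean(v) + sqrt(mean((v - mean(v))^2)))

  masks <- lapply(c(0.5, 1, 1.5, 2), function(k)
    thresholdActivity(m, trep, kSd = k)$mask)
  for (i in 1:3)                                 # monotone shrinkage
    expect_true(all(!masks[[i + 1]] | masks[[i]]))
})

test_that("area opening removes components strictly below the size floor", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE                            # 9-pixel blob
  expect_false(any(removeSmallComponents(m, minSize = 10)))
  m[5, 4] <- TRUE                                # now 10 pixels (8-conn)
  expect_identical(removeSmallComponents(m, minSize = 10), m)
  expect_false(any(removeSmallComponents(matrix(FALSE, 5, 5))))
})

test_that("largest-component selection keeps the top k with deterministic ties", {
  m <- matrix(FALSE, 20, 40)
  m[2:11, 2:6] <- TRUE                           # 50 px
  m[2:7, 10:14] <- TRUE                          # 30 px
  m[2:5, 20:24] <- TRUE                          # 20 px
  m[2:3, 30:34] <- TRUE                          # 10 px
  sel <- selectLargestComponents(m, k = 3)
  expect_equal(sel$components$size, c(50L, 30L, 20L, 10L))
  expect_equal(sel$components$selected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(sel$mask), 100L)

  two <- matrix(FALSE, 5, 9); two[1:2, 1:2] <- TRUE; two[4:5, 6:7] <- TRUE
  sel2 <- selectLargestComponents(two, k = 3)
  expect_identical(sel2$mask, two)               # fewer than k: keep all

  # four equal 2x2 blocks: raster order (rows scanned first) decides
  tie <- matrix(FALSE, 9, 9)
  tie[1:2, 1:2] <- TRUE; tie[1:2, 5:6] <- TRUE
  tie[5:6, 1:2] <- TRUE; tie[5:6, 5:6] <- TRUE
  sel3 <- selectLargestComponents(tie, k = 3)
  kept <- sel3$mask
  expect_true(all(kept[1:2, 1:2]) && all(kept[1:2, 5:6]) &&
                all(kept[5:6, 1:2]))
  expect_false(any(kept[5:6, 5:6]))              # last in raster order
})

test_that("convex hull rasterization matches the separating-line oracle", {
  set.seed(31)
  for (rep in 1:8) {
    m <- matrix(FALSE, 10, 10)
    pts <- cbind(sample(10, 5, TRUE), sample(10, 5, TRUE))
    m[pts] <- TRUE
    expect_identical(convexHullMask(m), bruteHullMask(m))
  }
})

test_that("convex hull handles segments, fixed points and degenerate input", {
  m <- matrix(FALSE, 3, 8); m[2, 2] <- TRUE; m[2, 7] <- TRUE
  h <- convexHullMask(m)
  expect_equal(which(h, arr.ind = TRUE)[, "col"], 2:7)  # 6 filled pixels

  rect <- matrix(FALSE, 8, 8); rect[3:6, 2:5] <- TRUE
  expect_identical(convexHullMask(rect), rect)

  empty <- matrix(FALSE, 4, 4)
  expect_identical(convexHullMask(empty), empty)
  single <- empty; single[2, 3] <- TRUE
  expect_identical(convexHullMask(single), single)

  diag4 <- matrix(FALSE, 9, 9)
  for (i in 1:4) diag4[2 * i, 2 * i] <- TRUE     # collinear off-axis
  hd <- convexHullMask(diag4)
  expect_true(all(hd[cbind(2:8, 2:8)]))          # lattice points on segment
  expect_equal(sum(hd), 7L)
})

test_that("hulls are supersets and idempotent on random masks", {
  set.seed(17)
  for (rep in 1:10) {
    m <- randomMask(9, 9, p = 0.15)
    h <- convexHullMask(m)
    expect_true(all(!m | h))
    expect_identical(convexHullMask(h), h)
  }
})

test_that("the segmentation chain nests and respects its parameters", {
  set.seed(19)
  for (rep in 1:100) {
    m <- matrix(stats::runif(16 * 16)^3, 16, 16)
    trep <- matrix(FALSE, 16, 16)
    trep[sample(256, 140)] <- TRUE
    seg <- segmentActivation(m, trep, minSize = 3, k = 2)
    expect_true(all(!seg@activation | seg@openedMap))
    expect_true(all(!seg@openedMap | seg@thresholdedMap))
    expect_true(all(!seg@thresholdedMap | trep))
    expect_true(all(!seg@activation | seg@hull))
    expect_lte(sum(seg@components$selected), 2L)
    if (nrow(seg@components))
      expect_true(all(seg@components$size >= 3L))
  }
})

test_that("segmentation is unchanged by positive affine rescaling of the map", {
  set.seed(23)
  trep <- matrix(FALSE, 16, 16)
  trep[(row(trep) - 8.5)^2 + (col(trep) - 8.5)^2 <= 36] <- TRUE
  for (rep in 1:5) {
    m <- matrix(stats::rlnorm(256), 16, 16)
    a <- segmentActivation(m, trep, minSize = 2)
    b <- segmentActivation(2.3 * m + 7, trep, minSize = 2)
    expect_identical(a@thresholdedMap, b@thresholdedMap)
    expect_identical(a@activation, b@activation)
    expect_identical(a@hull, b@hull)
  }
})
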