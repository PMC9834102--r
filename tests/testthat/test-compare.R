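test_that("DICE algebra: identity, disjointness, counted overlap, symmetry", {
  m <- matrix(FALSE, 4, 4); n <- m
  m[1:2, 1:2] <- TRUE
  expect_equal(dice(m, m), 1)
  n[3:4, 3:4] <- TRUE
  expect_equal(dice(m, n), 0)
  n <- matrix(FALSE, 4, 4); n[2:3, 1:2] <- TRUE  # |A|=|B|=4, overlap 2
  expect_equal(dice(m, n), 0.5)
  expect_equal(dice(m, n), countingDice(m, n))

  set.seed(29)
  for (rep in 1:100) {
    a <- randomMask(6, 6); b <- randomMask(6, 6)
    expect_identical(suppressWarnings(dice(a, b)),
                     suppressWarnings(dice(b, a)))
  }
})

test_that("DICE rejects shape mismatches and warns on double-empty input", {
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
  expect_warning(d0 <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
                 "empty")
  expect_equal(d0, 0)
})

test_that("enlarging a mask toward a union never reduces its DICE with the base", {
  set.seed(37)
  for (rep in 1:20) {
    a <- randomMask(8, 8, 0.4); b <- randomMask(8, 8, 0.4)
    if (!any(a) || !any(b)) next
    expect_gte(dice(a, a | b), dice(a, b))
  }
})

test_that("the DICE triplet compares activation, hull and thresholded map", {
  set.seed(41)
  m <- matrix(stats::rlnorm(400), 20, 20)
  trep <- matrix(FALSE, 20, 20); trep[3:18, 3:18] <- TRUE
  seg <- segmentActivation(m, trep, minSize = 2)
  tri <- diceTriplet(seg, seg@activation, trep)
  expect_equal(unname(tri["activation"]), 1)
  expect_equal(unname(tri["hull"]), dice(seg@hull, seg@activation))
  expect_equal(unname(tri["full"]), dice(seg@thresholdedMap, seg@activation))

  # a convex activation equal to the whole thresholded map: all three are 1
  conv <- matrix(0, 12, 12); conv[4:8, 4:8] <- 10
  trep2 <- matrix(TRUE, 12, 12)
  seg2 <- segmentActivation(conv, trep2, minSize = 2)
  expect_equal(unname(diceTriplet(seg2, seg2@activation, trep2)),
               c(1, 1, 1))

  # the reference is clipped to the trepanation before comparison
  ref <- seg@activation
  refOutside <- ref; refOutside[1, 1] <- TRUE
  expect_equal(unname(diceTriplet(seg, refOutside, trep)["activation"]), 1)
})

test_that("region statistics use interpolated quartiles and partition the trepanation", {
  m <- matrix(0, 5, 5)
  trep <- matrix(TRUE, 5, 5)
  psc <- matrix(FALSE, 5, 5); psc[2:4, 2:4] <- TRUE
  ref <- matrix(FALSE, 5, 5); ref[3, 2:4] <- TRUE
  m[ref] <- c(1, 2, 3)
  m[psc & !ref] <- 7
  masks <- regionMaskSet(trep, psc, ref)
  rs <- regionStatistics(m, masks)
  expect_equal(rs$region, c("reference_activation", "psc_minus_reference",
                            "surrounding"))
  expect_equal(rs$n, c(3L, 6L, 16L))
  expect_equal(sum(rs$n), sum(trep))
  expect_equal(rs$median[1], 2)
  expect_equal(rs[rs$region == "psc_minus_reference", ]$median, 7)
  expect_equal(rs[rs$region == "psc_minus_reference", ]$q1, 7)

  # five-value region: median 3, Q1 2, Q3 4 under linear interpolation
  m2 <- matrix(0, 1, 5); m2[1, ] <- c(5, 3, 1, 2, 4)
  masks2 <- regionMaskSet(matrix(TRUE, 1, 5), matrix(TRUE, 1, 5),
                          matrix(TRUE, 1, 5))
  rs2 <- regionStatistics(m2, masks2)
  expect_equal(unlist(rs2[1, c("median", "q1", "q3")], use.names = FALSE),
               c(3, 2, 4))

  # single-pixel region: all three quartiles equal the value
  ref3 <- matrix(FALSE, 1, 5); ref3[1, 2] <- TRUE
  rs3 <- regionStatistics(m2, regionMaskSet(matrix(TRUE, 1, 5),
                                            matrix(TRUE, 1, 5), ref3))
  expect_equal(unlist(rs3[1, c("median", "q1", "q3")], use.names = FALSE),
               c(3, 3, 3))

  # an empty region reports n = 0 with undefined statistics, not an error
  rs4 <- regionStatistics(m2, regionMaskSet(matrix(TRUE, 1, 5),
                                            matrix(TRUE, 1, 5),
                                            matrix(FALSE, 1, 5)))
  expect_equal(rs4$n[1], 0L)
  expect_true(is.na(rs4$median[1]))
})

test_that("quartiles match a hand-rolled sort-and-interpolate oracle", {
  set.seed(43)
  for (rep in 1:200) {
    v <- stats::rnorm(sample(1:40, 1))
    m <- matrix(v, 1)
    masks <- regionMaskSet(matrix(TRUE, 1, length(v)),
                           matrix(TRUE, 1, length(v)),
                           matrix(TRUE, 1, length(v)))
    rs <- regionStatistics(m, masks)[1, ]
    expect_equal(rs$median, sortQuartiles(v, 0.5))
    expect_equal(rs$q1, sortQuartiles(v, 0.25))
    expect_equal(rs$q3, sortQuartiles(v, 0.75))
  }
})

test_that("region statistics demand the PSC and reference masks", {
  m <- matrix(1, 3, 3)
  expect_error(regionStatistics(m, regionMaskSet(matrix(TRUE, 3, 3))),
               "PSC")
})

test_that("topographic composition labels sites and resolves overlaps", {
  a <- matrix(FALSE, 6, 6); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  topo <- composeTopography(list(a, b), c("leg", "hand"))
  expect_equal(sort(unique(as.vector(topo@labelMap))), c(0L, 1L, 2L))
  expect_true(all(topo@labelMap[a] == 1L))
  expect_true(all(topo@labelMap[b] == 2L))
  expect_equal(topo@overlapDice["leg", "hand"], 0)

  # identical masks: overlap DICE 1; earlier-listed site wins the pixels
  topo2 <- composeTopography(list(a, a), c("first", "second"))
  expect_equal(topo2@overlapDice["first", "second"], 1)
  expect_true(all(topo2@labelMap[a] == 1L))
  expect_identical(topo2@siteMasks$second, a)    # per-site masks preserved

  expect_error(composeTopography(list(a, b), c("x", "x")), "duplicated")
  expect_error(composeTopography(list(a), c("x", "y")), "one name per site")
})

test_that("site centroids recover the injected somatotopic order", {
  masks <- lapply(c(5, 15, 25), function(cc) {
    m <- matrix(FALSE, 30, 30); m[14:16, cc + (-1:1)] <- TRUE; m
  })
  topo <- composeTopography(masks, c("leg", "arm", "hand"))
  cen <- siteCentroids(topo)
  expect_equal(cen$site, c("leg", "arm", "hand"))
  expect_true(all(diff(cen$col) > 0))
})
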