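test_that("nuclei tables read and write losslessly", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,x,y,z,TBXT",
               "1,0,0,0,5.5",
               "2,10,0,0,2.25",
               "3,20,5,1,7.125"), tmp)
  ns <- readNucleiTable(tmp)
  expect_s4_class(ns, "NucleiSet")
  expect_equal(ncol(ns), 3)
  expect_equal(channelNames(ns), "TBXT")
  expect_equal(unname(assay1(ns, "raw")), c(5.5, 2.25, 7.125))

  # full-precision round trip, including NaN and extra assays
  ns2 <- generateEmbryo(syntheticSpec(n_nuclei = 120, seed = 4))
  ns2 <- computeNFI(ns2)
  a <- SummarizedExperiment::assay(ns2, "nfi")
  a["TBXT", 1] <- NaN
  SummarizedExperiment::assay(ns2, "nfi", withDimnames = FALSE) <- a
  out <- tempfile(fileext = ".csv")
  writeNucleiTable(ns2, out)
  back <- readNucleiTable(out)
  expect_identical(unname(SummarizedExperiment::assay(back, "raw")),
                   unname(SummarizedExperiment::assay(ns2, "raw")))
  expect_identical(unname(SummarizedExperiment::assay(back, "nfi")),
                   unname(SummarizedExperiment::assay(ns2, "nfi")))
  expect_identical(centroids(back), centroids(ns2))
  expect_true(is.nan(SummarizedExperiment::assay(back, "nfi")["TBXT", 1]))

  # byte-stable rewrite
  out2 <- tempfile(fileext = ".csv")
  writeNucleiTable(back, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("schema and integrity violations are rejected by name", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,x,y,TBXT", "1,0,0,5"), tmp)
  expect_error(readNucleiTable(tmp), "missing mandatory column 'z'")
  writeLines(c("id,x,y,z,TBXT", "1,0,0,0,5", "1,1,0,0,2"), tmp)
  expect_error(readNucleiTable(tmp), "integrity error")
  writeLines(c("id,x,y,z", "1,0,0,0"), tmp)
  expect_error(readNucleiTable(tmp), "no channel")
})

test_that("voxel coordinates convert to micrometers (depth,row,col)", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,x,y,z,TBXT", "1,1,1,1,5", "2,2,3,4,2"), tmp)
  ns <- readNucleiTable(tmp, voxel_size = c(2, 1, 1), unit = "voxel")
  expect_equal(unname(centroids(ns)[, "z"]), c(2, 8))  # z doubled
  expect_equal(unname(centroids(ns)[, "x"]), c(1, 2))
})

test_that("quantifyFromLabels matches brute-force voxel averages", {
  # single 3x3x3 cube, uniform intensity 7
  lab <- array(0L, c(7, 7, 7))
  lab[3:5, 3:5, 3:5] <- 1L
  ints <- list(ch1 = array(7, c(7, 7, 7)))
  q <- quantifyFromLabels(lab, ints, voxel_size = c(1, 1, 1),
                          ring_radius_um = 1.5)
  expect_equal(unname(assay1(q, "raw", "ch1")), 7)
  expect_equal(unname(centroids(q)[1, ]), c(3.5, 3.5, 3.5))

  # random small label images vs per-label loop oracle
  set.seed(8)
  for (rep in 1:5) {
    lab <- array(sample(0:3, 6 * 6 * 6, replace = TRUE), c(6, 6, 6))
    img <- array(runif(6 * 6 * 6), c(6, 6, 6))
    q <- quantifyFromLabels(lab, list(c1 = img), voxel_size = c(1, 1, 1),
                            ring_radius_um = 0)
    for (l in sort(setdiff(unique(as.vector(lab)), 0))) {
      i <- which(col_data(q)$nucleus_id == l)
      expect_equal(unname(assay1(q, "raw", "c1")[i]),
                   mean(img[lab == l]))
    }
  }
})

test_that("peri-nuclear ring excludes all labels and flags enclosure", {
  lab <- array(0L, c(5, 9, 5))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[2:4, 5:7, 2:4] <- 2L  # adjacent label
  img <- array(1, c(5, 9, 5))
  img[lab > 0] <- 100  # ring must only see background (value 1)
  q <- quantifyFromLabels(lab, list(c1 = img), voxel_size = c(1, 1, 1),
                          ring_radius_um = 1.5)
  expect_equal(unname(SummarizedExperiment::assay(q, "raw_ring")["c1", ]),
               c(1, 1))
  expect_false(any(col_data(q)$ring_missing))

  # fully enclosed label has no ring
  lab2 <- array(2L, c(5, 5, 5))
  lab2[3, 3, 3] <- 1L
  q2 <- quantifyFromLabels(lab2, list(c1 = array(1, c(5, 5, 5))),
                           voxel_size = c(1, 1, 1), ring_radius_um = 1.5)
  expect_true(col_data(q2)$ring_missing[col_data(q2)$nucleus_id == 1])
  expect_true(is.na(SummarizedExperiment::assay(q2, "raw_ring")["c1",
    which(col_data(q2)$nucleus_id == 1)]))

  # shape mismatch and sub-voxel ring
  expect_error(quantifyFromLabels(lab, list(c1 = array(1, c(4, 9, 5))),
                                  voxel_size = c(1, 1, 1)),
               "mismatch")
  expect_warning(quantifyFromLabels(lab, list(c1 = img),
                                    voxel_size = c(1, 1, 1),
                                    ring_radius_um = 0.4),
                 "smaller than one voxel")
})

test_that("sphere label in a gradient image recovers centroid value", {
  # synthetic sphere in a linear-gradient image: nuclear mean equals the
  # gradient evaluated at the centroid (linearity of the mean)
  dims <- c(21, 21, 21)
  lab <- array(0L, dims)
  ctr <- c(11, 11, 11)
  for (z in 1:21) for (y in 1:21) for (x in 1:21)
    if (sum((c(z, y, x) - ctr)^2) <= 16) lab[z, y, x] <- 1L
  grad <- array(0, dims)
  for (x in 1:21) grad[, , x] <- 10 + 3 * x
  q <- quantifyFromLabels(lab, list(c1 = grad), voxel_size = c(1, 1, 1),
                          ring_radius_um = 0)
  expected <- 10 + 3 * 11
  expect_lt(abs(assay1(q, "raw", "c1") - expected) / expected, 0.02)
})

test_that("TIFF stacks round-trip into (depth, row, col) arrays", {
  arr <- array(runif(4 * 6 * 5), c(4, 6, 5))
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 32)
  back <- readImageStack(f)
  expect_equal(dim(back), dim(arr))
  expect_equal(back, arr, tolerance = 1e-6)
})
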