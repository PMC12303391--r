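test_that("principal curves recover lines and arcs", {
  # collinear points: the curve is the line, lambda = projections
  set.seed(1)
  t <- sort(runif(120, 0, 100))
  pts <- cbind(t * 0.6, t * 0.8)
  pc <- fitPrincipalCurve(pts)
  expect_true(pc@converged)
  expect_lt(max(abs(pc@distance)), 1e-6)
  expect_equal(cor(pc@lambda, t), 1, tolerance = 1e-9)

  # circular arc of radius 100 over 60 degrees: arc length within 2%
  th <- seq(-pi / 6, pi / 6, length.out = 300)
  arc <- cbind(100 * sin(th), 100 * cos(th))
  pca <- fitPrincipalCurve(arc, span = 0.2)
  expect_lt(abs(max(pca@arcLength) - 100 * pi / 3) / (100 * pi / 3),
            0.02)

  # determinism on a duplicated input
  pcb <- fitPrincipalCurve(arc, span = 0.2)
  expect_identical(pca@points, pcb@points)
  expect_identical(pca@lambda, pcb@lambda)

  expect_error(fitPrincipalCurve(arc[1:5, ]), "at least 10")
  expect_error(fitPrincipalCurve(matrix(1, 20, 2)), "coincident")
})

test_that("a flat sheet projects to itself up to a rigid transform", {
  ns <- generateEmbryo(syntheticSpec(surface = "flat", n_nuclei = 800,
                                     seed = 5, jitter_um = 0))
  suppressWarnings(ns <- pringleProject(ns))
  cd <- col_data(ns)
  ok <- !is.na(cd$ap_um)
  fit_ap <- lm(cd$ap_um[ok] ~ cd$true_ap[ok])
  fit_lr <- lm(cd$lr_um[ok] ~ cd$true_lr[ok])
  expect_lt(sqrt(mean(resid(fit_ap)^2)), 0.5)
  expect_lt(sqrt(mean(resid(fit_lr)^2)), 0.5)
  expect_equal(abs(coef(fit_ap)[[2]]), 1, tolerance = 0.01)
  expect_equal(abs(coef(fit_lr)[[2]]), 1, tolerance = 0.01)
})

test_that("a half-cylinder unrolls to analytic arc-length coordinates", {
  ns <- generateEmbryo(syntheticSpec(surface = "cylinder", radius = 100,
                                     theta_max = pi / 2,
                                     n_nuclei = 2000, seed = 7))
  ns <- computeNFI(ns)
  g0 <- buildNeighborGraph(ns)
  ns <- smoothIntensities(ns, g0)
  suppressWarnings(ns <- pringleProject(ns))
  ns <- detectMidline(ns)
  cd <- col_data(ns)
  ok <- !is.na(cd$lr_um)
  # midline re-zeroing makes lr comparable to R * azimuth directly
  s <- sign(cor(cd$lr_um[ok], cd$true_lr[ok]))
  err <- s * cd$lr_um[ok] - cd$true_lr[ok]
  rel_rms <- sqrt(mean(err^2)) / sqrt(mean(cd$true_lr[ok]^2))
  expect_lt(rel_rms, 0.02)
  # a nucleus at azimuth ~30 degrees reads ~52.36 um
  near30 <- which.min(abs(cd$true_lr - 100 * pi / 6))
  expect_lt(abs(abs(cd$lr_um[near30]) - 100 * pi / 6), 5)
})

test_that("midline detection is exact under symmetry, equivariant", {
  mk <- function(shift, seed) {
    ns <- generateEmbryo(syntheticSpec(n_nuclei = 1200, seed = seed))
    ns <- computeNFI(ns)
    g <- buildNeighborGraph(ns)
    ns <- smoothIntensities(ns, g)
    suppressWarnings(ns <- pringleProject(ns))
    cd <- col_data(ns)
    cd$lr_um <- cd$lr_um + shift
    SummarizedExperiment::colData(ns) <- cd
    ns
  }
  ns0 <- mk(0, 17)
  ns0 <- detectMidline(ns0)
  off0 <- S4Vectors::metadata(ns0)$midline[[1]]
  expect_lt(abs(off0), 2)
  ns30 <- mk(30, 17)
  ns30 <- detectMidline(ns30)
  expect_equal(S4Vectors::metadata(ns30)$midline[[1]], off0 + 30,
               tolerance = 1e-9)
  expect_equal(col_data(ns30)$lr_um, col_data(ns0)$lr_um,
               tolerance = 1e-9)
})

test_that("landmark normalization pins node to 0, tip to 1", {
  ns <- generateEmbryo(syntheticSpec(n_nuclei = 1000, seed = 23))
  ns <- computeNFI(ns)
  g <- buildNeighborGraph(ns)
  ns <- smoothIntensities(ns, g)
  suppressWarnings(ns <- pringleProject(ns))
  ns <- detectMidline(ns)
  ns <- normalizeAlign(ns)
  cd <- col_data(ns)
  expect_identical(cd$ap_rel[cd$is_node], 0)
  expect_identical(cd$ap_rel[cd$is_ps_tip], 1)
  expect_lt(max(abs(cd$lr_rel[cd$tissue == "epiblast"]), na.rm = TRUE),
            1.2)

  # missing landmark names the embryo
  cd2 <- col_data(ns)
  cd2$is_ps_tip <- FALSE
  SummarizedExperiment::colData(ns) <- cd2
  expect_error(normalizeAlign(ns), "sim1")
})

test_that("alignment maps are invariant to a uniform scale", {
  base <- generateEmbryo(syntheticSpec(n_nuclei = 900, seed = 29))
  doubled <- base
  SummarizedExperiment::colData(doubled)$x <- col_data(base)$x * 2
  SummarizedExperiment::colData(doubled)$y <- col_data(base)$y * 2
  SummarizedExperiment::colData(doubled)$z <- col_data(base)$z * 2
  SummarizedExperiment::colData(doubled)$embryo_id <- "sim2"
  colnames(doubled) <- paste0("sim2:", col_data(doubled)$nucleus_id)
  ns <- combineNucleiSets(list(base, doubled))
  ns <- computeNFI(ns)
  g <- buildNeighborGraph(ns)
  ns <- smoothIntensities(ns, g)
  suppressWarnings(ns <- pringleProject(ns))
  ns <- detectMidline(ns)
  ns <- normalizeAlign(ns)
  cd <- col_data(ns)
  a <- cd$embryo_id == "sim1"
  b <- cd$embryo_id == "sim2"
  expect_lt(max(abs(cd$ap_rel[a] - cd$ap_rel[b])), 0.005)
  expect_lt(max(abs(cd$lr_rel[a] - cd$lr_rel[b]), na.rm = TRUE), 0.02)
})

test_that("folding is idempotent and remembers the side", {
  ns <- generateEmbryo(syntheticSpec(n_nuclei = 600, seed = 31))
  ns <- computeNFI(ns)
  g <- buildNeighborGraph(ns)
  ns <- smoothIntensities(ns, g)
  suppressWarnings(ns <- pringleProject(ns))
  ns <- detectMidline(ns)
  ns <- normalizeAlign(ns)
  lr_before <- col_data(ns)$lr_rel
  f1 <- foldAtMidline(ns)
  expect_true(all(col_data(f1)$lr_rel >= 0, na.rm = TRUE))
  expect_equal(col_data(f1)$lr_rel, abs(lr_before))
  expect_equal(col_data(f1)$side[!is.na(lr_before)],
               ifelse(lr_before[!is.na(lr_before)] < 0, "left",
                      "right"))
  f2 <- foldAtMidline(f1)
  expect_identical(col_data(f2)$lr_rel, col_data(f1)$lr_rel)
  expect_identical(col_data(f2)$side, col_data(f1)$side)
})

test_that("binned maps compute means and normalized densities", {
  ns <- generateEmbryo(syntheticSpec(n_nuclei = 500, seed = 37))
  cd <- col_data(ns)
  cd$ap_rel <- cd$true_ap / 300
  cd$lr_scaled <- cd$true_lr
  SummarizedExperiment::colData(ns) <- cd
  apb <- seq(-0.3, 1.1, 0.2)
  lrb <- seq(-160, 160, 40)
  m1 <- binnedMap(ns, rep(1, ncol(ns)), "mean", apb, lrb)
  expect_true(all(m1@values[is.finite(m1@values)] == 1))
  m2 <- binnedMap(ns, rep(TRUE, ncol(ns)), "density", apb, lrb)
  expect_equal(sum(m2@values), 1, tolerance = 1e-12)
  expect_error(binnedMap(ns, rep(1, ncol(ns)), "mean", 1, lrb),
               "empty grid")

  # known Gaussian bump: argmax within one grid cell of the center
  for (s in 1:3) {
    nsb <- generateEmbryo(syntheticSpec(n_nuclei = 900, seed = 40 + s,
      channels = list(A = list(pattern = "bump", center_ap = 150,
                               center_lr = 40, width = 25),
                      B = list(pattern = "constant"),
                      C = list(pattern = "constant"))))
    cdb <- col_data(nsb)
    cdb$ap_rel <- cdb$true_ap / 300
    cdb$lr_scaled <- cdb$true_lr
    SummarizedExperiment::colData(nsb) <- cdb
    mb <- binnedMap(nsb, assay1(nsb, "raw", "A"), "mean", apb, lrb)
    am <- which(mb@values == max(mb@values, na.rm = TRUE),
                arr.ind = TRUE)
    expect_lte(abs(am[1, 1] - findInterval(40, lrb)), 1)
    expect_lte(abs(am[1, 2] - findInterval(0.5, apb)), 1)
  }
})
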