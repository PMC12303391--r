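random_graph_ns <- function(n, seed, values = NULL) {
  set.seed(seed)
  pts <- matrix(runif(3 * n, 0, 60), n, 3)
  v <- if (is.null(values)) runif(n) else values
  ns <- make_ns(pts, rbind(A = v))
  SummarizedExperiment::assay(ns, "nfi", withDimnames = FALSE) <-
    rbind(A = v)
  list(ns = ns, g = buildNeighborGraph(ns, pruneFactor = Inf))
}

test_that("local CV equals the population sigma/mu of the niche", {
  # niche {1,2,3}: population sd sqrt(2/3), cv ~ 0.4082
  ns <- make_ns(cbind(1:3, 0, 0), rbind(A = c(2, 1, 3)))
  SummarizedExperiment::assay(ns, "nfi", withDimnames = FALSE) <-
    rbind(A = c(2, 1, 3))
  g <- star_graph(ns)
  cv <- assay1(localCV(ns, g, "A"), "cv")
  expect_equal(unname(cv[1]), sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_equal(unname(cv[1]), 0.4082483, tolerance = 1e-6)

  # all-equal niche: cv exactly 0; scaling leaves cv unchanged
  ns0 <- make_ns(cbind(1:3, 0, 0), rbind(A = rep(0.4, 3)))
  SummarizedExperiment::assay(ns0, "nfi", withDimnames = FALSE) <-
    rbind(A = rep(0.4, 3))
  expect_equal(unname(assay1(localCV(ns0, star_graph(ns0), "A"),
                             "cv")[1]), 0)

  # brute-force oracle over a random graph, both sd conventions
  r <- random_graph_ns(200, 51)
  adj <- adjacencyList(r$g)
  v <- assay1(r$ns, "nfi")[match(r$g@nodes, colnames(r$ns))]
  for (sdt in c("population", "sample")) {
    got <- assay1(localCV(r$ns, r$g, "A", sd_type = sdt), "cv")
    for (i in seq(1, 200, by = 7)) {
      niche <- c(v[i], v[adj[[i]]])
      sdv <- if (sdt == "population") oracle_pop_sd(niche) else
        sd(niche)
      expect_equal(unname(got[r$g@nodes[i]]), sdv / mean(niche),
                   tolerance = 1e-12)
    }
  }
  # scale invariance
  r5 <- r
  SummarizedExperiment::assay(r5$ns, "nfi", withDimnames = FALSE) <-
    SummarizedExperiment::assay(r$ns, "nfi") * 5
  expect_equal(assay1(localCV(r5$ns, r5$g, "A"), "cv"),
               assay1(localCV(r$ns, r$g, "A"), "cv"), tolerance = 1e-12)
})

test_that("neighbor ratio is ln(cell / neighbor mean) with a floor", {
  ns <- make_ns(cbind(1:3, 0, 0), rbind(A = c(0.5, 0.25, 0.75)))
  SummarizedExperiment::assay(ns, "nfi", withDimnames = FALSE) <-
    rbind(A = c(0.5, 0.25, 0.75))
  g <- star_graph(ns)
  nr <- assay1(neighborRatio(ns, g, "A", floor = 1e-9), "nr")
  expect_equal(unname(nr[1]), 0, tolerance = 1e-7)  # 0.5 vs mean 0.5

  # 2:1 niche gives ln 2; swapping negates (antisymmetry)
  ns2 <- make_ns(cbind(1:2, 0, 0), rbind(A = c(0.5, 0.25)))
  SummarizedExperiment::assay(ns2, "nfi", withDimnames = FALSE) <-
    rbind(A = c(0.5, 0.25))
  g2 <- path_graph(ns2)
  nr2 <- assay1(neighborRatio(ns2, g2, "A", floor = 1e-9), "nr")
  expect_equal(unname(nr2), c(log(2), -log(2)), tolerance = 1e-7)

  # positive-scale invariance when floor << values
  r <- random_graph_ns(150, 52, values = runif(150, 0.2, 1))
  a1 <- assay1(neighborRatio(r$ns, r$g, "A", floor = 1e-9), "nr")
  r2 <- r
  SummarizedExperiment::assay(r2$ns, "nfi", withDimnames = FALSE) <-
    SummarizedExperiment::assay(r$ns, "nfi") * 7
  a2 <- assay1(neighborRatio(r2$ns, r2$g, "A", floor = 1e-9), "nr")
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("the synthetic null is seeded, degenerate-safe, calibrated", {
  # constant field: sigma = 0 branch gives exactly 0 everywhere
  ns <- make_ns(cbind(1:10, 0, 0), rbind(A = rep(0.3, 10)))
  SummarizedExperiment::assay(ns, "nfi", withDimnames = FALSE) <-
    rbind(A = rep(0.3, 10))
  g <- path_graph(ns)
  nrs <- assay1(simulateNullNR(ns, g, "A", seed = 1), "nr_synthetic")
  expect_equal(unname(nrs), rep(0, 10))

  # same seed is bit-reproducible; different seed differs
  r <- random_graph_ns(150, 53)
  s1 <- assay1(simulateNullNR(r$ns, r$g, "A", seed = 9),
               "nr_synthetic")
  s2 <- assay1(simulateNullNR(r$ns, r$g, "A", seed = 9),
               "nr_synthetic")
  s3 <- assay1(simulateNullNR(r$ns, r$g, "A", seed = 10),
               "nr_synthetic")
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))

  # iid normal field: observed and synthetic NR indistinguishable
  ok_ks <- 0
  for (s in 1:8) {
    nsx <- generateEmbryo(syntheticSpec(surface = "flat",
      n_nuclei = 500, seed = s,
      channels = list(A = list(pattern = "iid", mu = 0.5, sd = 0.15))))
    gx <- buildNeighborGraph(nsx)
    nsx <- neighborRatio(nsx, gx, "A", floor = 0.1, assay = "raw")
    nsx <- simulateNullNR(nsx, gx, "A", seed = s + 100, floor = 0.1,
                          assay = "raw")
    nr <- assay1(nsx, "nr", "A")
    nq <- assay1(nsx, "nr_synthetic", "A")
    keep <- is.finite(nr) & is.finite(nq)
    p <- suppressWarnings(ks.test(nr[keep], nq[keep])$p.value)
    ok_ks <- ok_ks + (p > 0.01)
  }
  expect_gte(ok_ks, 7)
})

test_that("emd1d matches closed forms and the quantile oracle", {
  expect_equal(emd1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd1d(0.2, 0.7), 0.5)
  set.seed(54)
  # shifted uniforms: EMD equals the shift
  a <- runif(10000)
  expect_equal(emd1d(a, a + 0.3), 0.3, tolerance = 0.02)
  # random pairs vs oracle, equal and unequal sizes
  for (rep in 1:200) {
    n1 <- sample(3:40, 1)
    a <- rnorm(n1)
    b <- rnorm(n1, sd = runif(1, 0.5, 2))
    expect_equal(emd1d(a, b), oracle_emd(a, b), tolerance = 1e-9)
  }
  for (rep in 1:30) {
    a <- rnorm(sample(3:30, 1))
    b <- runif(sample(3:30, 1))
    expect_equal(emd1d(a, b), oracle_emd(a, b), tolerance = 1e-3)
  }
  # metric axioms on random triples
  for (rep in 1:100) {
    a <- rnorm(15); b <- rnorm(15); c <- rnorm(15)
    expect_equal(emd1d(a, b), emd1d(b, a), tolerance = 1e-12)
    expect_lte(emd1d(a, c), emd1d(a, b) + emd1d(b, c) + 1e-9)
    expect_equal(emd1d(a, a), 0, tolerance = 1e-12)
  }
  expect_error(emd1d(numeric(0), 1), "non-empty")
  # joint rescaling makes the distance scale-free
  expect_equal(emd1d(c(0, 1), c(10, 11), normalize = TRUE),
               emd1d(c(0, 0.1), c(1, 1.1), normalize = TRUE))
})

test_that("gradients recover direction and vanish on constant fields", {
  # regular hexagon + closed form: gradient along +x within 1 degree
  th <- (0:5) * pi / 3
  pts <- rbind(c(0, 0, 0), cbind(10 * cos(th), 10 * sin(th), 0))
  v <- 0.01 * pts[, 1]
  ns <- make_ns(pts, rbind(A = v + 1))
  SummarizedExperiment::assay(ns, "smooth", withDimnames = FALSE) <-
    rbind(A = v)
  g <- star_graph(ns)
  for (m in c("corrected", "vectorsum")) {
    nsg <- gradientField(ns, g, "A", method = m)
    gv <- c(assay1(nsg, "grad_x")[1], assay1(nsg, "grad_y")[1],
            assay1(nsg, "grad_z")[1])
    ang <- acos(gv[1] / sqrt(sum(gv^2))) * 180 / pi
    expect_lt(ang, 1)
  }

  # constant field: zero vector and zero steepness everywhere (exact)
  r <- random_graph_ns(100, 55, values = rep(0.6, 100))
  SummarizedExperiment::assay(r$ns, "smooth",
                              withDimnames = FALSE) <-
    rbind(A = rep(0.6, 100))
  rg <- gradientField(r$ns, r$g, "A")
  expect_true(all(assay1(rg, "steepness") == 0))

  # vectorsum equals the brute-force per-node formula exactly
  r2 <- random_graph_ns(120, 56)
  SummarizedExperiment::assay(r2$ns, "smooth",
                              withDimnames = FALSE) <-
    SummarizedExperiment::assay(r2$ns, "nfi")
  got <- gradientField(r2$ns, r2$g, "A", method = "vectorsum")
  adj <- adjacencyList(r2$g)
  idx <- match(r2$g@nodes, colnames(r2$ns))
  pts <- centroids(r2$ns)[idx, ]
  v <- assay1(r2$ns, "smooth")[idx]
  for (i in seq(1, 120, 11)) {
    nb <- adj[[i]]
    acc <- c(0, 0, 0)
    for (j in nb) {
      d <- pts[j, ] - pts[i, ]
      acc <- acc + d / sqrt(sum(d^2)) * (v[j] - v[i])
    }
    acc <- acc / length(nb)
    expect_equal(unname(c(assay1(got, "grad_x")[idx[i]],
                          assay1(got, "grad_y")[idx[i]],
                          assay1(got, "grad_z")[idx[i]])),
                 unname(acc), tolerance = 1e-12)
  }
})

test_that("nr profiles report the 1.96 SE confidence band", {
  # hand-checkable CI: embryo means with known sd
  ns <- combineNucleiSets(lapply(1:4, function(e) {
    nsx <- generateEmbryo(syntheticSpec(surface = "flat",
      n_nuclei = 120, seed = 60 + e, embryo_id = paste0("e", e),
      channels = list(A = list(pattern = "iid"))))
    nsx
  }))
  g <- buildNeighborGraph(ns)
  ns <- neighborRatio(ns, g, "A", floor = 0.1, assay = "raw")
  ns <- simulateNullNR(ns, g, "A", seed = 3, floor = 0.1,
                       assay = "raw")
  cd <- col_data(ns)
  cd$pseudospace <- rep(0.5, ncol(ns))  # everything in one bin
  SummarizedExperiment::colData(ns) <- cd
  prof <- nrProfile(ns, "A", bins = c(0, 1))
  em_means <- tapply(assay1(ns, "nr", "A"), cd$embryo_id, mean,
                     na.rm = TRUE)
  se <- sd(em_means) / 2
  expect_equal(prof$obs_mean[1], mean(em_means), tolerance = 1e-9)
  expect_equal(prof$obs_hi[1] - prof$obs_mean[1], 1.96 * se,
               tolerance = 1e-9)
  expect_equal(prof$n_embryos[1], 4)
  expect_true(is.finite(prof$p[1]))
})

test_that("boundary profiles recover stripes and their narrowing", {
  mk_stripe <- function(outer_end, seeds) {
    combineNucleiSets(lapply(seeds, function(e) generateEmbryo(
      syntheticSpec(surface = "flat", n_nuclei = 1800, ap_anterior = 0,
        seed = e, embryo_id = paste0("e", e),
        channels = list(TW = list(pattern = "stripe", inner = 10,
                                  outer = 45, outer_end = outer_end),
                        B = list(pattern = "constant"),
                        C = list(pattern = "constant"))))))
  }
  use_truth_frame <- function(ns) {
    cd <- col_data(ns)
    cd$ap_rel <- cd$true_ap / 300
    cd$lr_um <- cd$true_lr
    SummarizedExperiment::colData(ns) <- cd
    ns
  }
  # constant stripe 10 <= |lr| <= 45: flat profile near the truth
  ns <- use_truth_frame(mk_stripe(NULL, 1:2))
  bp <- boundaryProfile(ns, col_data(ns)$truth_TW > 0.5,
                        ap_breaks = seq(0, 1, 0.2))
  expect_true(all(abs(bp$ventral - 10) < 3))
  expect_true(all(abs(bp$dorsal - 45) < 4))
  expect_true(all(abs(bp$width - 35) < 5))

  # dorsal boundary narrowing 45 -> 25: slope within 10% of -20
  ns2 <- use_truth_frame(mk_stripe(25, 3:5))
  bp2 <- boundaryProfile(ns2, col_data(ns2)$truth_TW > 0.5,
                         ap_breaks = seq(0, 1, 0.1))
  sl <- coef(lm(width ~ mid, bp2))[[2]]
  expect_lt(abs(sl - (-20)) / 20, 0.1)

  # empty domain: all-NaN profile
  bp3 <- boundaryProfile(ns, rep(FALSE, ncol(ns)),
                         ap_breaks = seq(0, 1, 0.2))
  expect_true(all(is.nan(bp3$width)))
})

test_that("nrShiftTest flags inhibition patterns, not random fields", {
  p_spots <- sapply(1:3, function(s) {
    ns <- combineNucleiSets(lapply(1:4, function(e) generateEmbryo(
      syntheticSpec(surface = "flat", n_nuclei = 600, seed = s * 31 + e,
        embryo_id = paste0("e", e),
        channels = list(A = list(pattern = "spots", fraction = 0.1,
                                 contrast = 3))))))
    g <- buildNeighborGraph(ns)
    nrShiftTest(ns, g, "A", seed = s, floor = 0.1, assay = "raw")$p
  })
  expect_true(all(p_spots < 0.05))
})
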