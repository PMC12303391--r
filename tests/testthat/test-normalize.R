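test_that("NFI follows (signal - background) / (p99 - background)", {
  # explicit small case: dominant background at 10, positives at 110
  set.seed(1)
  raw <- c(rnorm(900, 10, 0.5), rnorm(100, 110, 2))
  ns <- make_ns(cbind(seq_along(raw), 0, 0), rbind(A = pmax(raw, 0)))
  ns <- computeNFI(ns)
  pars <- S4Vectors::metadata(ns)$normalization$e1$A
  expect_lt(abs(pars$background - 10), 1)   # KDE mode near 10
  expect_equal(pars$max_signal, quantile(pmax(raw, 0), 0.99,
                                         names = FALSE))
  v <- assay1(ns, "nfi")
  manual <- pmin(1, pmax(0, (pmax(raw, 0) - pars$background) /
                           (pars$max_signal - pars$background)))
  expect_equal(unname(v), manual)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("NFI is invariant to affine rescaling of raw values", {
  set.seed(2)
  raw <- c(rnorm(600, 20, 2), rnorm(200, 150, 10))
  ns1 <- computeNFI(make_ns(cbind(seq_along(raw), 0, 0),
                            rbind(A = raw)))
  ns2 <- computeNFI(make_ns(cbind(seq_along(raw), 0, 0),
                            rbind(A = 3.7 * raw + 11)))
  expect_equal(unname(assay1(ns1, "nfi")), unname(assay1(ns2, "nfi")),
               tolerance = 1e-9)
})

test_that("degenerate channels raise an error", {
  ns <- make_ns(cbind(1:50, 0, 0), rbind(A = rep(5, 50)))
  expect_error(computeNFI(ns), "degenerate channel")
})

test_that("bleed-through unmixing subtracts, clips, and auto-fits", {
  ns <- make_ns(cbind(1:2, 0, 0), rbind(S = c(10, 10), T = c(5, 5)))
  u1 <- unmixBleedthrough(ns, "S", "T", 0.2)
  expect_equal(unname(assay1(u1, "raw", "T")), c(3, 3))
  u2 <- unmixBleedthrough(ns, "S", "T", 1)
  expect_equal(unname(assay1(u2, "raw", "T")), c(0, 0))  # clipped
  expect_equal(unname(assay1(u2, "raw", "S")), c(10, 10))

  # auto-fit recovers an injected coefficient within +/- 0.03
  for (s in 1:3) {
    spec <- syntheticSpec(surface = "flat", n_nuclei = 1200, seed = s,
                          bleed = list(source = "S", target = "T",
                                       c = 0.3),
                          channels = list(
                            S = list(pattern = "midline", width = 40),
                            T = list(pattern = "stripe", inner = 60,
                                     outer = 120),
                            U = list(pattern = "constant")))
    nsb <- generateEmbryo(spec)
    fit <- unmixBleedthrough(nsb, "S", "T", "auto")
    expect_lt(abs(S4Vectors::metadata(fit)$unmix[["S->T"]] - 0.3), 0.03)
  }

  # unmixing with c = 0 is the identity
  u0 <- unmixBleedthrough(ns, "S", "T", 0)
  expect_identical(unname(assay1(u0, "raw", "T")),
                   unname(assay1(ns, "raw", "T")))
  # too few eligible nuclei
  expect_error(unmixBleedthrough(ns, "S", "T", "auto"), "manual")
})

test_that("depth attenuation is fitted and divided out", {
  mk <- function(seed, decay) generateEmbryo(syntheticSpec(
    surface = "cylinder", n_nuclei = 1200, seed = seed,
    depth_decay = decay,
    channels = list(A = list(pattern = "iid", mu = 0.5, sd = 0.1),
                    B = list(pattern = "constant"),
                    C = list(pattern = "constant"))))
  # injected exp(-z/100) decay: residual |r| < 0.1 after correction
  ns <- mk(9, 100)
  z <- col_data(ns)$z
  expect_lt(cor(assay1(ns, "raw", "A"), z), -0.5)
  nsc <- correctDepthAttenuation(ns, "A")
  expect_lt(abs(cor(assay1(nsc, "raw", "A"), z)), 0.1)

  # constant-in-z signal passes through unchanged
  ns0 <- generateEmbryo(syntheticSpec(
    surface = "cylinder", n_nuclei = 800, seed = 2, noise_sd = 0,
    channels = list(A = list(pattern = "constant", value = 0.5),
                    B = list(pattern = "constant"),
                    C = list(pattern = "constant"))))
  ns0c <- correctDepthAttenuation(ns0, "A")
  expect_equal(assay1(ns0c, "raw", "A"), assay1(ns0, "raw", "A"))

  # identical correction factor at equal z; rank order preserved
  nsc2 <- correctDepthAttenuation(ns, "B")
  zb <- round(z, 6)
  dup <- zb[duplicated(zb)]
  ratio <- assay1(nsc2, "raw", "B") / assay1(ns, "raw", "B")
  for (zz in head(dup, 3)) {
    i <- which(zb == zz)
    expect_equal(diff(range(ratio[i])), 0, tolerance = 1e-9)
  }
  same_z_band <- which(abs(z - median(z)) < 0.5)
  expect_equal(order(assay1(nsc2, "raw", "B")[same_z_band]),
               order(assay1(ns, "raw", "B")[same_z_band]))

  # precondition: too few nuclei or too little depth
  small <- make_ns(cbind(1:50, 0, seq(0, 30, length.out = 50)),
                   rbind(A = runif(50)))
  expect_error(correctDepthAttenuation(small, "A"), ">= 200 nuclei")
})

test_that("positive gating uses an inclusive boundary and Otsu", {
  ns <- make_ns(cbind(1:3, 0, 0), rbind(A = c(1, 3, 9)))
  SummarizedExperiment::assay(ns, "nfi", withDimnames = FALSE) <-
    rbind(A = c(0.1, 0.3, 0.9))
  g <- gatePositive(ns, "A", threshold = 0.3)
  expect_equal(unname(g), c(FALSE, TRUE, TRUE))  # >= is positive
  expect_error(gatePositive(ns, "A", threshold = 1.4), "\\[0, 1\\]")

  # otsu lands between the two component means
  set.seed(5)
  v <- c(rnorm(500, 0.15, 0.03), rnorm(300, 0.7, 0.05))
  v <- pmin(1, pmax(0, v))
  ns2 <- make_ns(cbind(seq_along(v), 0, 0), rbind(A = v))
  SummarizedExperiment::assay(ns2, "nfi", withDimnames = FALSE) <-
    rbind(A = v)
  g2 <- gatePositive(ns2, "A", "otsu")
  thr_range <- range(v[g2]) # smallest gated value
  expect_gt(min(v[g2]), 0.15)
  expect_lt(min(v[g2]), 0.7)
  # exhaustive threshold scan oracle: Otsu maximizes between-class var
  expect_gt(mean(g2[v > 0.6]), 0.99)
  expect_lt(mean(g2[v < 0.3]), 0.01)

  # degenerate all-equal channel: warning + all negative
  ns3 <- make_ns(cbind(1:10, 0, 0), rbind(A = rep(0, 10)))
  SummarizedExperiment::assay(ns3, "nfi", withDimnames = FALSE) <-
    rbind(A = rep(0, 10))
  expect_warning(g3 <- gatePositive(ns3, "A", "otsu"), "degenerate")
  expect_false(any(g3))
})
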