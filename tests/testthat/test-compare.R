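aligned_iid_set <- function(seed, n_embryos = 6, n = 300,
                            conditions = c("c1", "c2")) {
  embs <- list()
  for (ci in seq_along(conditions)) for (e in seq_len(n_embryos / 2)) {
    embs[[length(embs) + 1]] <- generateEmbryo(syntheticSpec(
      surface = "flat", n_nuclei = n,
      seed = seed * 101 + ci * 17 + e,
      embryo_id = paste0(conditions[ci], "_e", e),
      condition = conditions[ci],
      channels = list(A = list(pattern = "iid", mu = 0.5, sd = 0.15))))
  }
  ns <- combineNucleiSets(embs)
  cd <- col_data(ns)
  cd$ap_rel <- cd$true_ap / 300
  cd$lr_scaled <- abs(cd$true_lr)
  SummarizedExperiment::colData(ns) <- cd
  ns
}

test_that("k-means bins have the prescribed count and determinism", {
  ns <- aligned_iid_set(1, n_embryos = 2, n = 500)
  p1 <- kmeansBins(ns, target_size = 100, seed = 5)
  expect_equal(p1@k, round(1000 / 100))
  p2 <- kmeansBins(ns, target_size = 100, seed = 5)
  expect_identical(p1@assignment, p2@assignment)

  # two well-separated blobs with target N/2 split exactly
  pts <- rbind(cbind(runif(50, 0, 0.1), runif(50, 0, 5)),
               cbind(runif(50, 0.9, 1), runif(50, 95, 100)))
  nsb <- make_ns(cbind(seq_len(100), 0, 0))
  cd <- col_data(nsb)
  cd$ap_rel <- pts[, 1]
  cd$lr_scaled <- pts[, 2]
  SummarizedExperiment::colData(nsb) <- cd
  pb <- kmeansBins(nsb, target_size = 50, seed = 1)
  expect_equal(length(unique(pb@assignment[1:50])), 1)
  expect_equal(length(unique(pb@assignment[51:100])), 1)
  expect_false(pb@assignment[1] == pb@assignment[100])

  expect_warning(kmeansBins(nsb, target_size = 500, seed = 1),
                 "one bin")
})

test_that("per-bin tests use embryo means and control the FPR", {
  # identical generators in both arms: p approximately uniform
  ps <- c()
  for (s in 1:8) {
    ns <- aligned_iid_set(s)
    part <- kmeansBins(ns, target_size = 150, seed = s)
    v <- setNames(assay1(ns, "raw", "A"), colnames(ns))
    part <- binConditionTest(part, ns, v)
    ps <- c(ps, part@stats$p)
  }
  ps <- ps[!is.na(ps)]
  fpr <- mean(ps < 0.05)
  expect_gt(length(ps), 50)
  expect_lt(abs(fpr - 0.05), 0.05)
  # permuted labels give uniform p-values
  expect_gt(suppressWarnings(
    ks.test(ps, "punif")$p.value), 0.01)

  # a +3 sigma shift confined to one quadrant is found there
  ns <- aligned_iid_set(99)
  cd <- col_data(ns)
  v <- assay1(ns, "raw", "A")
  q <- cd$condition == "c2" & cd$ap_rel > 0.5 & cd$lr_scaled > 75
  v[q] <- v[q] + 3 * 15
  part <- kmeansBins(ns, target_size = 100, seed = 99)
  part <- binConditionTest(part, ns, setNames(v, colnames(ns)))
  st <- part@stats
  inq <- st$centroid_ap > 0.55 & st$centroid_lr > 80
  expect_gte(mean(st$q[inq] < 0.05, na.rm = TRUE), 0.9)
  expect_lte(mean(st$q[!inq] < 0.05, na.rm = TRUE), 0.1)

  # one embryo per condition: nothing is testable
  ns1 <- aligned_iid_set(3, n_embryos = 2)
  part1 <- kmeansBins(ns1, target_size = 150, seed = 3)
  part1 <- binConditionTest(part1, ns1,
                            setNames(assay1(ns1, "raw", "A"),
                                     colnames(ns1)))
  expect_true(all(is.na(part1@stats$p)))
})

test_that("BH adjustment matches a brute-force step-up", {
  set.seed(77)
  for (rep in 1:300) {
    p <- runif(sample(2:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("superplot statistics are per-embryo with paired tests", {
  ns <- combineNucleiSets(lapply(1:4, function(e) {
    nsx <- generateEmbryo(syntheticSpec(surface = "flat",
      n_nuclei = 150, seed = 70 + e, embryo_id = paste0("e", e),
      channels = list(A = list(pattern = "iid"),
                      B = list(pattern = "iid"),
                      C = list(pattern = "iid"))))
    nsx
  }))
  g <- buildNeighborGraph(ns)
  for (ch in c("A", "B", "C")) ns <- localCV(ns, g, ch, assay = "raw")
  st <- superplotStats(ns, c("A", "B", "C"), assay = "cv")
  expect_equal(nrow(st$embryo_means), 12)  # one row per embryo/channel
  expect_equal(nrow(st$tests), 3)
  expect_true(all(is.finite(st$tests$p)))
  expect_equal(st$tests$q, p.adjust(st$tests$p, "BH"))
  # CI from the embryo means
  emA <- st$embryo_means$value[st$embryo_means$channel == "A"]
  expect_equal(st$summary$ci_hi[1] - st$summary$mean[1],
               1.96 * sd(emA) / 2, tolerance = 1e-9)

  # identical channels: t = 0, p = 1; constant nonzero diff: p -> 0
  em <- st$embryo_means
  nsc <- ns
  a <- SummarizedExperiment::assay(nsc, "cv")
  a["B", ] <- a["A", ]
  SummarizedExperiment::assay(nsc, "cv", withDimnames = FALSE) <- a
  st2 <- superplotStats(nsc, c("A", "B"), assay = "cv")
  expect_true(st2$tests$degenerate[1])
  expect_equal(st2$tests$p[1], 1)
  a["B", ] <- a["A", ] + 0.1
  SummarizedExperiment::assay(nsc, "cv", withDimnames = FALSE) <- a
  st3 <- superplotStats(nsc, c("A", "B"), assay = "cv")
  expect_true(st3$tests$degenerate[1])
  expect_equal(st3$tests$p[1], 0)

  # fewer than 3 embryos: tests suppressed
  st4 <- superplotStats(ns[, col_data(ns)$embryo_id %in%
                              c("e1", "e2")],
                        c("A", "B"), assay = "cv")
  expect_true(all(is.na(st4$tests$p)))
})
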