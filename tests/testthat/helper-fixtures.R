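# Shared fixtures and independent oracles, built in code at test time.

suppressWarnings(RNGversion("4.3.0"))

# minimal NucleiSet from points and one or more channel value vectors
make_ns <- function(pts, values = NULL, embryo = "e1", ...) {
  pts <- as.matrix(pts)
  if (is.null(values)) values <- rbind(A = rep(1, nrow(pts)))
  if (is.null(dim(values))) values <- rbind(A = values)
  NucleiSet(raw = values, centroids = pts, embryo_id = embryo, ...)
}

# star-graph NeighborGraph: node 1 connected to all others (hand-built)
star_graph <- function(ns) {
  n <- ncol(ns)
  e <- cbind(1L, 2:n)
  pts <- centroids(ns)
  len <- sqrt(rowSums((pts[e[, 1], , drop = FALSE] -
                         pts[e[, 2], , drop = FALSE])^2))
  methods::new("NeighborGraph", nodes = colnames(ns), edges = e,
               lengths = len, tissue = "epiblast", pruneFactor = Inf,
               isolated = rep(FALSE, n))
}

# path-graph a-b-c-...: consecutive nodes connected
path_graph <- function(ns) {
  n <- ncol(ns)
  e <- cbind(seq_len(n - 1), 2:n)
  pts <- centroids(ns)
  len <- sqrt(rowSums((pts[e[, 1], , drop = FALSE] -
                         pts[e[, 2], , drop = FALSE])^2))
  methods::new("NeighborGraph", nodes = colnames(ns), edges = e,
               lengths = len, tissue = "epiblast", pruneFactor = Inf,
               isolated = rep(FALSE, n))
}

# brute-force 3D Delaunay edge oracle: an edge belongs to the
# triangulation iff it is part of a 4-point simplex whose circumsphere
# contains no other point (enumerates all 4-subsets; small n only)
oracle_delaunay3 <- function(p) {
  n <- nrow(p)
  E <- matrix(0L, 0, 2)
  combs <- utils::combn(n, 4)
  for (ci in seq_len(ncol(combs))) {
    q <- combs[, ci]
    A <- 2 * (p[q[2:4], ] - matrix(p[q[1], ], 3, 3, byrow = TRUE))
    if (abs(det(A)) < 1e-8) next
    cc <- solve(A, rowSums(p[q[2:4], ]^2) - sum(p[q[1], ]^2))
    r2 <- sum((p[q[1], ] - cc)^2)
    d2 <- rowSums((p - matrix(cc, n, 3, byrow = TRUE))^2)
    if (all(d2[-q] > r2 * (1 + 1e-9)))
      E <- rbind(E, t(utils::combn(q, 2)))
  }
  unique(cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2])))
}

# population standard deviation, written independently of the package
oracle_pop_sd <- function(v) sqrt(sum((v - sum(v) / length(v))^2) /
                                    length(v))

# quantile/grid-based Wasserstein-1 oracle
oracle_emd <- function(a, b, grid_n = 20000) {
  if (length(a) == length(b)) return(mean(abs(sort(a) - sort(b))))
  g <- seq(min(c(a, b)), max(c(a, b)), length.out = grid_n)
  Fa <- stats::ecdf(a)(g)
  Fb <- stats::ecdf(b)(g)
  sum(abs(Fa - Fb)[-grid_n] * diff(g))
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# edge keys of a NeighborGraph as "i j" over nucleus_id integers
edge_keys <- function(g) {
  df <- graphEdges(g)
  a <- as.integer(sub(".*:", "", df$id_a))
  b <- as.integer(sub(".*:", "", df$id_b))
  paste(pmin(a, b), pmax(a, b))
}

assay1 <- function(ns, assay, channel = rownames(ns)[1])
  SummarizedExperiment::assay(ns, assay)[channel, ]

col_data <- function(ns) SummarizedExperiment::colData(ns)

# gently undulating epithelial sheet with a deep layer 15 um beneath:
# the classifier fixture
bilayer_ns <- function(seed = 21, n = 1200, n_deep = 600) {
  computeFeatures(computeNFI(generateEmbryo(syntheticSpec(
    surface = "saddle", half_width = 100, ap_length = 100,
    ap_anterior = 100, saddle_scale = 1000, n_nuclei = n,
    sublayer_offset = 15, n_sublayer = n_deep, seed = seed,
    channels = list(SOX2 = list(pattern = "constant", value = 0.6),
                    TBXT = list(pattern = "midline"),
                    TBX6 = list(pattern = "iid"))))))
}
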