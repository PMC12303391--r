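#' @include NucleiSet-methods.R utils.R
NULL

# Delaunay edges for one embryo's point set; pts is n x 3 (or n x 2 in
# monolayer mode). Coordinates are centred and rescaled before the
# incremental triangulation for numerical conditioning.
.delaunay_edges <- function(pts, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  ctr <- colMeans(pts)
  sc <- max(apply(pts, 2, function(v) diff(range(v))), 1e-9)
  norm <- sweep(pts, 2, ctr) / sc
  if (mode == "3d") {
    sv <- svd(sweep(pts, 2, ctr))$d
    if (sv[3] < 1e-8 * max(sv[1], 1e-12))
      stop("dimensionality error: points are (near-)coplanar; ",
           "use monolayer = TRUE for 2D Delaunay")
    .delaunay3_cpp(norm[, 1:3, drop = FALSE])
  } else {
    .delaunay2_cpp(norm[, 1:2, drop = FALSE])
  }
}

#' Build the neighbor graph of a tissue
#'
#' Nearest neighbors are defined by 3D Delaunay tetrahedralization of the
#' nuclei centroids, restricted to a single tissue label (for embryos,
#' only the epiblast is triangulated). Each embryo is triangulated
#' independently, so neighbors never span embryos. Because Delaunay
#' tetrahedralization of shell-like tissues creates spurious edges across
#' internal cavities, edges longer than \code{pruneFactor} times the
#' median edge length (per embryo) are removed; nuclei left without
#' neighbors are flagged as isolated.
#'
#' @param ns a \linkS4class{NucleiSet}.
#' @param tissue tissue label to restrict to (default \code{"epiblast"});
#'   \code{NULL} uses all nuclei.
#' @param pruneFactor prune edges longer than this multiple of the median
#'   edge length (default 2.5; \code{Inf} disables pruning).
#' @param monolayer when \code{TRUE}, a 2D Delaunay triangulation of
#'   (x, y) is used instead (cultured monolayers).
#' @return a \linkS4class{NeighborGraph}.
#' @examples
#' ns <- generateEmbryo(syntheticSpec(n_nuclei = 200, seed = 1))
#' g <- buildNeighborGraph(ns)
#' numNodes(g)
#' @export
buildNeighborGraph <- function(ns, tissue = "epiblast", pruneFactor = 2.5,
                               monolayer = FALSE) {
  keep <- if (is.null(tissue)) rep(TRUE, ncol(ns))
          else tissueLabels(ns) == tissue
  sub <- ns[, keep]
  if (ncol(sub) < 4)
    stop("need at least 4 nuclei in tissue '", tissue, "'")
  keys <- character(0)
  efrom <- integer(0); eto <- integer(0); elen <- numeric(0)
  for (em in embryoIDs(sub)) {
    esub <- sub[, SummarizedExperiment::colData(sub)$embryo_id == em]
    pts <- centroids(esub)
    e <- .delaunay_edges(pts, mode = if (monolayer) "2d" else "3d")
    len <- sqrt(rowSums((pts[e[, 1], , drop = FALSE] -
                           pts[e[, 2], , drop = FALSE])^2))
    if (is.finite(pruneFactor) && nrow(e) > 0) {
      thr <- pruneFactor * stats::median(len)
      keep_e <- len <= thr
      e <- e[keep_e, , drop = FALSE]
      len <- len[keep_e]
    }
    off <- length(keys)
    keys <- c(keys, colnames(esub))
    efrom <- c(efrom, e[, 1] + off)
    eto <- c(eto, e[, 2] + off)
    elen <- c(elen, len)
  }
  edges <- cbind(pmin(efrom, eto), pmax(efrom, eto))
  deg <- tabulate(c(edges[, 1], edges[, 2]), length(keys))
  methods::new("NeighborGraph", nodes = keys, edges = edges,
               lengths = elen, tissue = if (is.null(tissue)) "all" else
                 tissue,
               pruneFactor = pruneFactor, isolated = deg == 0)
}

#' @describeIn buildNeighborGraph number of nodes.
#' @param x a NeighborGraph
#' @export
setMethod("numNodes", "NeighborGraph", function(x) length(x@nodes))

#' @describeIn buildNeighborGraph number of undirected edges.
#' @export
setMethod("numEdges", "NeighborGraph", function(x) nrow(x@edges))

#' @describeIn buildNeighborGraph edge table (keys and lengths in
#'   micrometers).
#' @export
setMethod("graphEdges", "NeighborGraph", function(x)
  data.frame(id_a = x@nodes[x@edges[, 1]], id_b = x@nodes[x@edges[, 2]],
             length_um = x@lengths))

#' @describeIn buildNeighborGraph edge lengths in micrometers.
#' @export
setMethod("edgeLengths", "NeighborGraph", function(x) x@lengths)

#' @describeIn buildNeighborGraph degree per node (named).
#' @export
setMethod("nodeDegrees", "NeighborGraph", function(x) {
  d <- tabulate(c(x@edges[, 1], x@edges[, 2]), length(x@nodes))
  names(d) <- x@nodes
  d
})

#' @describeIn buildNeighborGraph adjacency as a list of integer node
#'   indices, one element per node.
#' @export
setMethod("adjacencyList", "NeighborGraph", function(x) {
  n <- length(x@nodes)
  adj <- vector("list", n)
  if (nrow(x@edges) > 0) {
    sp <- split(c(x@edges[, 2], x@edges[, 1]),
                factor(c(x@edges[, 1], x@edges[, 2]), levels = seq_len(n)))
    adj <- lapply(sp, as.integer)
  }
  names(adj) <- x@nodes
  adj
})

setMethod("show", "NeighborGraph", function(object) {
  cat("NeighborGraph: ", length(object@nodes), " nuclei (tissue: ",
      object@tissue, "), ", nrow(object@edges), " edges\n", sep = "")
  if (nrow(object@edges) > 0)
    cat(sprintf("edge length (um): median %.2f, max %.2f; %d isolated\n",
                stats::median(object@lengths), max(object@lengths),
                sum(object@isolated)))
  invisible(NULL)
})

#' Export a neighbor graph as an edge-list CSV
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @param path output CSV (\code{id_a,id_b,length_um}).
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  utils::write.csv(graphEdges(graph), path, row.names = FALSE)
  invisible(path)
}

#' Iterative neighbor-kernel smoothing of channel values
#'
#' Repeatedly replaces each nucleus's value by the mean over the nucleus
#' and its graph neighbors (synchronous update for all nuclei), the
#' spatial smoothing applied before gradient and pseudospace analysis.
#' Ten rounds are the default. Smoothing operates on the NFI assay; by
#' linearity this is equivalent to smoothing raw values and re-applying
#' the same affine normalization.
#'
#' @param ns a \linkS4class{NucleiSet} with an \code{"nfi"} assay.
#' @param graph a \linkS4class{NeighborGraph} over (a subset of) the
#'   nuclei.
#' @param channels channels to smooth (default: all).
#' @param iterations number of averaging rounds (default 10).
#' @param assay input assay (default \code{"nfi"}).
#' @return the \code{NucleiSet} with a \code{"smooth"} assay; nuclei not
#'   in the graph keep their input value and are flagged in the
#'   \code{in_graph} colData column.
#' @export
smoothIntensities <- function(ns, graph, channels = NULL, iterations = 10,
                              assay = "nfi") {
  if (is.null(channels)) channels <- rownames(ns)
  stopifnot(iterations >= 0)
  idx <- match(graph@nodes, colnames(ns))
  if (anyNA(idx)) stop("graph contains nuclei absent from the NucleiSet")
  adj <- adjacencyList(graph)
  n <- length(idx)
  src <- c(graph@edges[, 1], graph@edges[, 2])
  dst <- c(graph@edges[, 2], graph@edges[, 1])
  deg <- tabulate(src, n)
  SummarizedExperiment::colData(ns)$in_graph <-
    colnames(ns) %in% graph@nodes
  for (ch in channels) {
    full <- .channel_values(ns, ch, assay)
    v <- full[idx]
    it <- 0
    while (it < iterations) {
      acc <- numeric(n)
      if (length(src) > 0) {
        s <- rowsum(v[src], dst)
        acc[as.integer(rownames(s))] <- s[, 1]
      }
      v <- (v + acc) / (deg + 1)
      it <- it + 1
    }
    out <- full  # nuclei outside the graph pass through unchanged
    out[idx] <- v
    ns <- .set_channel_values(ns, ch, out, "smooth")
  }
  ns
}
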