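#' @import methods
#' @import SummarizedExperiment
#' @import S4Vectors
#' @importFrom Rcpp evalCpp
#' @useDynLib pringle, .registration = TRUE
NULL

#' NucleiSet: per-nucleus intensities and geometry
#'
#' The central container of the package. A \code{NucleiSet} extends
#' \linkS4class{SummarizedExperiment} with channels (markers) as rows and
#' nuclei as columns. The \code{"raw"} assay holds mean fluorescence per
#' nucleus per channel; normalization and smoothing add \code{"nfi"} and
#' \code{"smooth"} assays, and the neighborhood statistics add further
#' channel-by-nucleus assays (\code{"cv"}, \code{"nr"},
#' \code{"nr_synthetic"}, \code{"steepness"}, \code{"grad_x"} ...).
#'
#' Column metadata carries, per nucleus: \code{nucleus_id} (integer, unique
#' within an embryo), \code{embryo_id}, \code{condition}, \code{stage},
#' the 3D centroid in micrometers (\code{x}, \code{y}, \code{z}; z is the
#' optical axis), the \code{tissue} label (\code{"epiblast"},
#' \code{"non_epiblast"} or \code{"unassigned"}), and landmark flags
#' \code{is_node} and \code{is_ps_tip}. Projection (\code{ap_um},
#' \code{lr_um}, \code{ap_rel}, \code{lr_rel}, \code{lr_scaled}) and
#' pseudospace columns are appended by the corresponding steps.
#'
#' @seealso \code{\link{NucleiSet}} (constructor),
#'   \code{\link{readNucleiTable}}, \code{\link{buildNeighborGraph}}
#' @export
setClass("NucleiSet", contains = "SummarizedExperiment")

.nucleiset_required_cols <- c("nucleus_id", "embryo_id", "condition",
                              "stage", "x", "y", "z", "tissue",
                              "is_node", "is_ps_tip")

setValidity("NucleiSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.nucleiset_required_cols, colnames(cd))
  if (length(miss) > 0)
    return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (ncol(object) == 0) return(TRUE)
  key <- paste(cd$embryo_id, cd$nucleus_id)
  if (anyDuplicated(key))
    return("nucleus_id values are not unique within embryo_id")
  xyz <- cbind(cd$x, cd$y, cd$z)
  if (!all(is.finite(xyz)))
    return("centroid coordinates must be finite")
  if (!all(cd$tissue %in% c("epiblast", "non_epiblast", "unassigned")))
    return("tissue must be epiblast, non_epiblast or unassigned")
  if ("raw" %in% SummarizedExperiment::assayNames(object)) {
    rw <- SummarizedExperiment::assay(object, "raw")
    if (any(rw < 0, na.rm = TRUE))
      return("raw intensities must be nonnegative")
  }
  if ("nfi" %in% SummarizedExperiment::assayNames(object)) {
    nf <- SummarizedExperiment::assay(object, "nfi")
    if (any(nf < -1e-9 | nf > 1 + 1e-9, na.rm = TRUE))
      return("nfi values must lie in [0, 1]")
  }
  TRUE
})

#' NeighborGraph: pruned Delaunay adjacency over nuclei of one tissue
#'
#' Undirected graph whose nodes are nuclei (of a single tissue label,
#' possibly across several embryos; embryos are triangulated independently
#' so the graph never links nuclei of different embryos) and whose edges
#' come from a 3D Delaunay tetrahedralization (or 2D triangulation in
#' monolayer mode) with long edges pruned.
#'
#' @slot nodes character, nucleus keys (\code{"embryo_id:nucleus_id"}).
#' @slot edges two-column integer matrix of node indices, each row one
#'   undirected edge with \code{edges[,1] < edges[,2]}.
#' @slot lengths numeric, Euclidean edge length in micrometers.
#' @slot tissue tissue label the graph was restricted to.
#' @slot pruneFactor multiplier of the median edge length above which
#'   edges were removed (\code{Inf} = no pruning).
#' @slot isolated logical per node, \code{TRUE} when pruning left the node
#'   without any neighbor.
#' @export
setClass("NeighborGraph",
  representation(nodes = "character", edges = "matrix",
                 lengths = "numeric", tissue = "character",
                 pruneFactor = "numeric", isolated = "logical"))

setValidity("NeighborGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2) return("edges must have two columns")
  if (nrow(e) != length(object@lengths))
    return("lengths must match the number of edges")
  if (length(object@isolated) != length(object@nodes))
    return("isolated flags must match the number of nodes")
  if (nrow(e) > 0) {
    if (any(e[, 1] == e[, 2])) return("self-edges are not allowed")
    if (any(e < 1 | e > length(object@nodes)))
      return("edge indices out of range")
    if (anyDuplicated(paste(e[, 1], e[, 2])))
      return("duplicate edges")
  }
  TRUE
})

#' PrincipalCurve: a fitted one-dimensional curve through a 2D point cloud
#'
#' Result of the iterative projection--smoothing fit used both for tissue
#' flattening and for the pseudospace axis.
#'
#' @slot points ordered polyline vertices (rows) in the fitting plane.
#' @slot arcLength cumulative arc length at each polyline vertex (strictly
#'   increasing, starts at 0).
#' @slot lambda arc-length position of each input point's projection.
#' @slot distance signed distance of each input point to the curve (sign =
#'   side of the curve, by the 2D cross product with the local tangent).
#' @slot span local-regression span used by the smoother.
#' @slot converged logical, whether the fit met the displacement tolerance.
#' @slot iterations number of projection--smoothing rounds run.
#' @export
setClass("PrincipalCurve",
  representation(points = "matrix", arcLength = "numeric",
                 lambda = "numeric", distance = "numeric",
                 span = "numeric", converged = "logical",
                 iterations = "integer"))

setValidity("PrincipalCurve", function(object) {
  if (nrow(object@points) != length(object@arcLength))
    return("arcLength must match polyline vertices")
  if (length(object@arcLength) > 1 && any(diff(object@arcLength) <= 0))
    return("arc length must be strictly increasing")
  TRUE
})

#' LandmarkSet: per-embryo alignment landmarks
#'
#' Positions (in projected coordinates) of the anatomical landmarks used to
#' normalize and register embryos: the node / notochord origin (anterior
#' anchor, ap = 0), the posterior tip of the primitive streak (ap = 1
#' after normalization), the detected midline offset, and the per-AP-bin
#' epiblast edge (robust half-width).
#'
#' @slot embryo embryo identifier.
#' @slot nodeAP arc-length (micrometers) of the node along the sagittal
#'   curve, after re-zeroing (0 by construction).
#' @slot tipAP arc-length of the primitive-streak posterior tip.
#' @slot midlineOffset left--right offset subtracted when the midline was
#'   detected.
#' @slot edgeTable data.frame with columns \code{ap_mid} (bin center,
#'   relative AP units) and \code{half_width} (97.5th percentile of
#'   \code{|lr_um|} in the bin).
#' @export
setClass("LandmarkSet",
  representation(embryo = "character", nodeAP = "numeric",
                 tipAP = "numeric", midlineOffset = "numeric",
                 edgeTable = "data.frame"))

#' PseudospaceModel: 1D cell-state axis in PCA space
#'
#' Log-transformed smoothed marker values are reduced to two principal
#' components and a principal curve is fitted between the two expression
#' extremes; pseudospace is the normalized arc-length position along that
#' curve, oriented so the anchor channel's high end maps to 0.
#'
#' @slot channels channels entering the PCA.
#' @slot pseudocount added before the log transform.
#' @slot center,scale PCA centering/scaling vectors.
#' @slot loadings channels x 2 PCA rotation.
#' @slot curve fitted \linkS4class{PrincipalCurve} in PC1--PC2.
#' @slot anchor channel whose high-expression extreme is pseudospace 0.
#' @slot flip whether arc length was reversed to honor the anchor.
#' @slot arcRange arc-length range mapped to [0, 1].
#' @slot gates numeric(2), fitted (low, high) pseudospace gates (NA until
#'   \code{\link{gateROI}} is run).
#' @export
setClass("PseudospaceModel",
  representation(channels = "character", pseudocount = "numeric",
                 center = "numeric", scale = "numeric",
                 loadings = "matrix", curve = "PrincipalCurve",
                 anchor = "character", flip = "logical",
                 arcRange = "numeric", gates = "numeric"))

#' BinPartition: shared k-means spatial bins with per-bin statistics
#'
#' @slot k number of bins.
#' @slot assignment integer bin id per analyzed nucleus, named by nucleus
#'   key.
#' @slot centers k x 2 matrix of bin centroids in folded aligned
#'   coordinates (ap_rel, lr_scaled).
#' @slot stats per-bin statistics table (filled by
#'   \code{\link{binConditionTest}}).
#' @export
setClass("BinPartition",
  representation(k = "integer", assignment = "integer",
                 centers = "matrix", stats = "data.frame"))

#' Map2D: binned statistic on the aligned 2D map
#'
#' @slot values bin-by-bin statistic (rows = lr bins, columns = ap bins);
#'   \code{NaN} where a mean bin is empty.
#' @slot apBreaks,lrBreaks bin edges.
#' @slot statistic \code{"mean"} or \code{"density"}.
#' @slot nEmbryos number of embryos averaged.
#' @export
setClass("Map2D",
  representation(values = "matrix", apBreaks = "numeric",
                 lrBreaks = "numeric", statistic = "character",
                 nEmbryos = "integer"))
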