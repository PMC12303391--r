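#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a NucleiSet
#'
#' @param raw numeric matrix of raw mean fluorescence, channels x nuclei
#'   (rownames = channel names). A vector is treated as a single channel.
#' @param centroids numeric matrix, nuclei x 3, columns (x, y, z) in
#'   micrometers.
#' @param nucleus_id integer ids, unique within an embryo (default
#'   \code{seq_len(n)}).
#' @param embryo_id,condition,stage per-nucleus metadata (recycled).
#' @param tissue tissue label per nucleus: \code{"epiblast"},
#'   \code{"non_epiblast"} or \code{"unassigned"}.
#' @param is_node,is_ps_tip logical landmark flags (at most one \code{TRUE}
#'   each per embryo is meaningful).
#' @param colData extra per-nucleus columns (data.frame), carried along.
#' @return a \linkS4class{NucleiSet}.
#' @examples
#' ns <- NucleiSet(raw = rbind(TBXT = c(5, 9, 2)),
#'                 centroids = cbind(x = c(0, 10, 20), y = 0, z = 0))
#' channelNames(ns)
#' @export
NucleiSet <- function(raw, centroids, nucleus_id = NULL,
                      embryo_id = "embryo1", condition = "none",
                      stage = "NA", tissue = "epiblast",
                      is_node = FALSE, is_ps_tip = FALSE,
                      colData = NULL) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1,
                                       dimnames = list("channel1", NULL))
  raw <- as.matrix(raw)
  if (is.null(rownames(raw)))
    rownames(raw) <- paste0("channel", seq_len(nrow(raw)))
  centroids <- as.matrix(centroids)
  n <- ncol(raw)
  if (nrow(centroids) != n)
    stop("centroids must have one row per nucleus (column of raw)")
  if (is.null(nucleus_id)) nucleus_id <- seq_len(n)
  cd <- S4Vectors::DataFrame(
    nucleus_id = as.integer(nucleus_id),
    embryo_id = as.character(rep_len(embryo_id, n)),
    condition = as.character(rep_len(condition, n)),
    stage = as.character(rep_len(stage, n)),
    x = as.numeric(centroids[, 1]),
    y = as.numeric(centroids[, 2]),
    z = as.numeric(centroids[, 3]),
    tissue = as.character(rep_len(tissue, n)),
    is_node = rep_len(as.logical(is_node), n),
    is_ps_tip = rep_len(as.logical(is_ps_tip), n))
  if (!is.null(colData)) {
    extra <- S4Vectors::DataFrame(colData)
    keep <- setdiff(colnames(extra), colnames(cd))
    if (length(keep) > 0) cd <- cbind(cd, extra[, keep, drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw), colData = cd)
  colnames(se) <- paste(cd$embryo_id, cd$nucleus_id, sep = ":")
  methods::new("NucleiSet", se)
}

#' @describeIn NucleiSet 3D centroids in micrometers (nuclei x 3 matrix).
#' @param x a NucleiSet
#' @param ... unused
#' @export
setMethod("centroids", "NucleiSet", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(x = cd$x, y = cd$y, z = cd$z)
  rownames(m) <- colnames(x)
  m
})

#' @describeIn NucleiSet tissue label per nucleus.
#' @export
setMethod("tissueLabels", "NucleiSet", function(x)
  SummarizedExperiment::colData(x)$tissue)

#' @describeIn NucleiSet replace tissue labels.
#' @param value replacement labels
#' @export
setMethod("tissueLabels<-", "NucleiSet", function(x, value) {
  SummarizedExperiment::colData(x)$tissue <-
    as.character(rep_len(value, ncol(x)))
  methods::validObject(x)
  x
})

#' @describeIn NucleiSet unique embryo identifiers.
#' @export
setMethod("embryoIDs", "NucleiSet", function(x)
  unique(SummarizedExperiment::colData(x)$embryo_id))

#' @describeIn NucleiSet per-nucleus keys (\code{"embryo_id:nucleus_id"}).
#' @export
setMethod("nucleusKeys", "NucleiSet", function(x) colnames(x))

#' @describeIn NucleiSet channel (marker) names.
#' @export
setMethod("channelNames", "NucleiSet", function(x) rownames(x))

setMethod("show", "NucleiSet", function(object) {
  cat("NucleiSet with", ncol(object), "nuclei,",
      nrow(object), "channel(s)\n")
  cat("channels:", paste(rownames(object), collapse = ", "), "\n")
  cat("embryos:", paste(embryoIDs(object), collapse = ", "), "\n")
  cat("assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
  tl <- table(tissueLabels(object))
  cat("tissue:", paste(names(tl), as.integer(tl), sep = "=",
                       collapse = ", "), "\n")
  invisible(NULL)
})

# fetch one channel's values from an assay, NA-safe
.channel_values <- function(ns, channel, assay = "nfi") {
  if (!assay %in% SummarizedExperiment::assayNames(ns))
    stop("assay '", assay, "' not present; run the upstream step first")
  if (!channel %in% rownames(ns))
    stop("unknown channel '", channel, "'")
  SummarizedExperiment::assay(ns, assay)[channel, ]
}

# write one channel's values into an assay, creating it when absent
.set_channel_values <- function(ns, channel, values, assay) {
  an <- SummarizedExperiment::assayNames(ns)
  if (!assay %in% an) {
    m <- matrix(NA_real_, nrow = nrow(ns), ncol = ncol(ns),
                dimnames = dimnames(ns))
    SummarizedExperiment::assay(ns, assay, withDimnames = FALSE) <- m
  }
  a <- SummarizedExperiment::assay(ns, assay)
  a[channel, ] <- values
  SummarizedExperiment::assay(ns, assay, withDimnames = FALSE) <- a
  ns
}
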