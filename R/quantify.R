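#' @include NucleiSet-methods.R
NULL

#' Quantify per-nucleus signals from a label image
#'
#' Given a 3D integer label image (0 = background) and a matching
#' multichannel intensity stack, computes for every label its mass
#' centroid (unweighted mean of voxel centers, in micrometers) and two
#' intensity summaries per channel: the nuclear mean (over the label's
#' voxels) and the peri-nuclear ring mean. The ring is the morphological
#' dilation of the label by a ball of \code{ring_radius_um} minus the
#' voxels of \emph{all} labels, i.e., an estimate of the immediately
#' surrounding cytoplasm, used for transcript (HCR) signal that is not
#' nuclear. Which compartment populates the \code{"raw"} assay is chosen
#' per channel with \code{compartment}; the other summary is kept in the
#' \code{"raw_ring"} assay (ring means; \code{NA} where a label is fully
#' enclosed by other labels and has no ring voxel).
#'
#' @param labels 3D integer array, dimensions (depth, row, col) = (z, y, x).
#' @param intensities 4D numeric array (depth, row, col, channel), or a
#'   named list of 3D arrays, one per channel.
#' @param voxel_size micrometers per voxel in (depth, row, col) order.
#' @param ring_radius_um ring thickness in micrometers (default 1.5).
#' @param channels channel names (default from \code{intensities} names).
#' @param compartment \code{"nuclear"} or \code{"ring"}, recycled per
#'   channel; selects which summary fills the \code{"raw"} assay.
#' @param embryo_id embryo identifier for the output table.
#' @return a \linkS4class{NucleiSet} with assays \code{"raw"} and
#'   \code{"raw_ring"}; nuclei with empty rings carry a
#'   \code{ring_missing} flag in \code{colData}.
#' @export
quantifyFromLabels <- function(labels, intensities, voxel_size,
                               ring_radius_um = 1.5, channels = NULL,
                               compartment = "nuclear",
                               embryo_id = "embryo1") {
  if (is.list(intensities)) {
    if (is.null(channels)) channels <- names(intensities)
    ints <- intensities
  } else {
    stopifnot(length(dim(intensities)) == 4)
    nc <- dim(intensities)[4]
    if (is.null(channels)) channels <- paste0("channel", seq_len(nc))
    ints <- lapply(seq_len(nc), function(c)
      array(intensities[, , , c], dim = dim(intensities)[1:3]))
    names(ints) <- channels
  }
  dl <- dim(labels)
  for (a in ints)
    if (!identical(dim(a), dl))
      stop("labels and intensities have mismatched spatial shapes")
  if (ring_radius_um < 0) stop("ring_radius_um must be >= 0")
  compartment <- rep_len(compartment, length(channels))

  ring_ok <- ring_radius_um >= min(voxel_size)
  if (ring_radius_um > 0 && !ring_ok)
    warning("ring_radius_um smaller than one voxel; ",
            "reporting nuclear values only")

  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  if (length(ids) == 0) stop("label image contains no labels")

  # ball offsets in voxel units, anisotropy-aware
  if (ring_ok) {
    rad <- ceiling(ring_radius_um / voxel_size)
    off <- as.matrix(expand.grid(dz = -rad[1]:rad[1], dy = -rad[2]:rad[2],
                                 dx = -rad[3]:rad[3]))
    d2 <- (off[, 1] * voxel_size[1])^2 + (off[, 2] * voxel_size[2])^2 +
      (off[, 3] * voxel_size[3])^2
    off <- off[d2 <= ring_radius_um^2 + 1e-9, , drop = FALSE]
  }

  nlab <- length(ids)
  cent <- matrix(NA_real_, nlab, 3)
  nuc <- matrix(NA_real_, length(channels), nlab,
                dimnames = list(channels, NULL))
  ring <- nuc
  ring_missing <- logical(nlab)
  occupied <- labels > 0

  for (k in seq_len(nlab)) {
    vox <- which(labels == ids[k], arr.ind = TRUE)  # (z, y, x) indices
    # voxel centers: (index - 0.5) * voxel size, 0-based convention
    cent[k, ] <- c(mean((vox[, 3] - 0.5) * voxel_size[3]),
                   mean((vox[, 2] - 0.5) * voxel_size[2]),
                   mean((vox[, 1] - 0.5) * voxel_size[1]))
    lin <- vox[, 1] + dl[1] * (vox[, 2] - 1) + dl[1] * dl[2] * (vox[, 3] - 1)
    for (ch in channels) nuc[ch, k] <- mean(ints[[ch]][lin])
    if (ring_ok) {
      cand <- unique(rbind(
        do.call(rbind, lapply(seq_len(nrow(off)), function(o)
          cbind(vox[, 1] + off[o, 1], vox[, 2] + off[o, 2],
                vox[, 3] + off[o, 3])))))
      keep <- cand[, 1] >= 1 & cand[, 1] <= dl[1] &
        cand[, 2] >= 1 & cand[, 2] <= dl[2] &
        cand[, 3] >= 1 & cand[, 3] <= dl[3]
      cand <- cand[keep, , drop = FALSE]
      clin <- cand[, 1] + dl[1] * (cand[, 2] - 1) +
        dl[1] * dl[2] * (cand[, 3] - 1)
      clin <- clin[!occupied[clin]]  # excludes every label, not just this one
      if (length(clin) == 0) {
        ring_missing[k] <- TRUE
      } else {
        for (ch in channels) ring[ch, k] <- mean(ints[[ch]][clin])
      }
    } else {
      ring_missing[k] <- TRUE
    }
  }

  raw <- nuc
  for (i in seq_along(channels))
    if (compartment[i] == "ring") raw[i, ] <- ring[i, ]
  ns <- NucleiSet(raw = raw, centroids = cent, nucleus_id = ids,
                  embryo_id = embryo_id,
                  colData = data.frame(ring_missing = ring_missing))
  SummarizedExperiment::assay(ns, "raw_ring", withDimnames = FALSE) <- ring
  ns
}
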