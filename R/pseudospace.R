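#' @include NucleiSet-methods.R principal-curve.R
NULL

#' Fit the pseudospace cell-state axis
#'
#' Builds a one-dimensional cell-state continuum from spatially smoothed
#' marker values: log(smoothed value + pseudocount) per channel enters a
#' PCA; a principal curve is fitted in the PC1--PC2 plane, tracing the
#' path between the two expression extremes (e.g., SOX2-high neural to
#' TBX6-high mesodermal); pseudospace is the normalized arc-length
#' position of each nucleus's projection, oriented so the anchor
#' channel's high extreme maps to 0. This is a state axis, not a
#' temporal trajectory.
#'
#' @param ns a \linkS4class{NucleiSet} with a \code{"smooth"} assay.
#' @param channels channels entering the PCA (at least 3; the continuum
#'   is defined over a multi-marker profile).
#' @param pseudocount added before the log (default 0.01 on the NFI
#'   scale; use 10 when smoothing was done on raw intensities).
#' @param anchor channel whose high end anchors pseudospace 0 (default:
#'   first channel).
#' @param span principal-curve smoother span (default 0.4).
#' @return list with \code{model} (a \linkS4class{PseudospaceModel}) and
#'   \code{ns} (the input with a \code{pseudospace} colData column).
#' @export
fitPseudospace <- function(ns, channels = rownames(ns),
                           pseudocount = 0.01, anchor = channels[1],
                           span = 0.4) {
  if (length(channels) < 3)
    stop("pseudospace needs at least 3 channels")
  sm <- SummarizedExperiment::assay(ns, "smooth")[channels, ,
                                                  drop = FALSE]
  ok <- colSums(!is.finite(sm)) == 0
  X <- t(log(sm[, ok, drop = FALSE] + pseudocount))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pca$rotation[, 1:2, drop = FALSE]
  scores <- pca$x[, 1:2, drop = FALSE]
  # sign convention: PC1 positively correlated with the anchor channel
  if (stats::cor(scores[, 1], X[, anchor]) < 0) {
    rot[, 1] <- -rot[, 1]; scores[, 1] <- -scores[, 1]
  }
  if (rot[which.max(abs(rot[, 2])), 2] < 0) {
    rot[, 2] <- -rot[, 2]; scores[, 2] <- -scores[, 2]
  }
  curve <- fitPrincipalCurve(scores, span = span)
  lam <- curve@lambda
  rng <- range(lam)
  p <- (lam - rng[1]) / diff(rng)
  # orient: anchor-high extreme at 0
  flip <- FALSE
  lo <- p <= 0.25; hi <- p >= 0.75
  if (mean(X[hi, anchor]) > mean(X[lo, anchor])) {
    p <- 1 - p
    flip <- TRUE
  }
  model <- methods::new("PseudospaceModel", channels = channels,
                        pseudocount = pseudocount, center = pca$center,
                        scale = numeric(0), loadings = rot,
                        curve = curve, anchor = anchor, flip = flip,
                        arcRange = rng, gates = c(NA_real_, NA_real_))
  full <- rep(NA_real_, ncol(ns))
  full[ok] <- p
  SummarizedExperiment::colData(ns)$pseudospace <- full
  list(model = model, ns = ns)
}

#' Apply a fitted pseudospace model to (new) data
#'
#' Projects nuclei onto the stored PCA axes and principal curve, so gate
#' values and the pseudospace scale transfer across embryos and stages.
#'
#' @param model a \linkS4class{PseudospaceModel}.
#' @param ns a \linkS4class{NucleiSet} with a \code{"smooth"} assay for
#'   the model's channels.
#' @return the \code{NucleiSet} with a \code{pseudospace} column (values
#'   clipped to [0, 1] at the curve ends).
#' @export
applyPseudospace <- function(model, ns) {
  sm <- SummarizedExperiment::assay(ns, "smooth")[model@channels, ,
                                                  drop = FALSE]
  ok <- colSums(!is.finite(sm)) == 0
  X <- t(log(sm[, ok, drop = FALSE] + model@pseudocount))
  scores <- sweep(X, 2, model@center) %*% model@loadings
  pr <- projectOnCurve(model@curve, scores)
  p <- (pr$lambda - model@arcRange[1]) / diff(model@arcRange)
  p <- pmin(1, pmax(0, p))
  if (model@flip) p <- 1 - p
  full <- rep(NA_real_, ncol(ns))
  full[ok] <- p
  SummarizedExperiment::colData(ns)$pseudospace <- full
  ns
}

setMethod("show", "PseudospaceModel", function(object) {
  cat("PseudospaceModel over", paste(object@channels, collapse = ", "),
      "\n")
  cat("anchor:", object@anchor, "(high end -> 0)",
      if (object@flip) "[arc reversed]" else "", "\n")
  if (!anyNA(object@gates))
    cat(sprintf("gates: [%.2f, %.2f]\n", object@gates[1],
                object@gates[2]))
  invisible(NULL)
})

#' Fit pseudospace gates to spatial reference regions
#'
#' Scans pseudospace gate pairs on a regular grid and keeps the pair
#' whose gated cell set best matches (maximal Jaccard index) the set of
#' nuclei inside user-supplied reference rectangles in aligned
#' coordinates --- e.g., node-width boxes over the known bi-fated
#' regions. The fitted gates transfer to other embryos via
#' \code{\link{applyPseudospace}} + in-gate membership.
#'
#' @param ns a \linkS4class{NucleiSet} with \code{pseudospace} and
#'   aligned coordinates.
#' @param boxes data.frame with columns \code{ap_min}, \code{ap_max},
#'   \code{lr_min}, \code{lr_max} in (ap_rel, lr_rel) coordinates.
#' @param model optional \linkS4class{PseudospaceModel} to store the
#'   gates in.
#' @param resolution gate grid step (default 0.01).
#' @param exclude optional logical mask of cells excluded from the scan
#'   (outside the neural-to-mesoderm trajectory domain).
#' @return list with \code{gates} (low, high), \code{jaccard},
#'   \code{membership} (named logical), and the updated \code{model} (if
#'   given).
#' @export
gateROI <- function(ns, boxes, model = NULL, resolution = 0.01,
                    exclude = NULL) {
  cd <- SummarizedExperiment::colData(ns)
  p <- cd$pseudospace
  if (is.null(p)) stop("run fitPseudospace/applyPseudospace first")
  usable <- is.finite(p) & is.finite(cd$ap_rel) & is.finite(cd$lr_rel)
  if (!is.null(exclude)) usable <- usable & !exclude
  inbox <- rep(FALSE, ncol(ns))
  for (r in seq_len(nrow(boxes))) {
    inbox <- inbox | (cd$ap_rel >= boxes$ap_min[r] &
                        cd$ap_rel <= boxes$ap_max[r] &
                        cd$lr_rel >= boxes$lr_min[r] &
                        cd$lr_rel <= boxes$lr_max[r])
  }
  inbox <- inbox & usable
  if (!any(inbox)) stop("reference boxes contain no nuclei")
  idx <- which(usable)
  o <- idx[order(p[idx])]
  ps <- p[o]
  boxcum <- c(0, cumsum(inbox[o]))
  total_box <- sum(inbox)
  grid <- seq(0, 1, by = resolution)
  # prefix sums: nuclei (and boxed nuclei) with pseudospace < each gate
  lo_cnt <- findInterval(grid - 1e-12, ps)
  hi_cnt <- findInterval(grid + 1e-12, ps)
  best <- c(-1, NA, NA)
  for (i in seq_along(grid)) {
    lo <- grid[i]
    j <- seq(i, length(grid))
    inter <- boxcum[hi_cnt[j] + 1] - boxcum[lo_cnt[i] + 1]
    size <- hi_cnt[j] - lo_cnt[i]
    jac <- inter / (size + total_box - inter)
    jac[!is.finite(jac)] <- 0
    k <- which.max(jac)
    if (jac[k] > best[1] + 1e-12) best <- c(jac[k], lo, grid[j[k]])
  }
  gates <- c(best[2], best[3])
  membership <- stats::setNames(usable & p >= gates[1] & p <= gates[2],
                                colnames(ns))
  if (!is.null(model)) model@gates <- gates
  list(gates = gates, jaccard = best[1], membership = membership,
       model = model)
}
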