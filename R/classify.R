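#' @include NucleiSet-methods.R
NULL

#' Spatial features for epiblast classification
#'
#' Computes the bespoke features that separate the epiblast sheet from
#' underlying tissue in large embryos: \code{local_density}, the number
#' of other nuclei within a fixed-radius 3D sphere; and
#' \code{dorsal_distance}, the distance (micrometers, along the optical
#' axis) from a surface interpolated through the dorsal-most nucleus of
#' each lateral bin. Features are deliberately not z-scored.
#'
#' @param ns a \linkS4class{NucleiSet}.
#' @param radius_um density sphere radius (default 15).
#' @param bin_um lateral bin size for the dorsal surface (default 20).
#' @param dorsal \code{"max"} when dorsal = largest z (default), or
#'   \code{"min"} for the opposite mounting orientation.
#' @return the \code{NucleiSet} with \code{local_density} and
#'   \code{dorsal_distance} colData columns.
#' @export
computeFeatures <- function(ns, radius_um = 15, bin_um = 20,
                            dorsal = c("max", "min")) {
  dorsal <- match.arg(dorsal)
  cd <- SummarizedExperiment::colData(ns)
  dens <- rep(NA_integer_, ncol(ns))
  dist <- rep(NA_real_, ncol(ns))
  for (em in embryoIDs(ns)) {
    sel <- which(cd$embryo_id == em)
    pts <- centroids(ns)[sel, , drop = FALSE]
    dens[sel] <- .radius_count_cpp(pts, radius_um)
    z <- if (dorsal == "max") pts[, 3] else -pts[, 3]
    xb <- seq(min(pts[, 1]) - 1e-9, max(pts[, 1]) + bin_um, by = bin_um)
    yb <- seq(min(pts[, 2]) - 1e-9, max(pts[, 2]) + bin_um, by = bin_um)
    cell <- paste(.bin_index(pts[, 1], xb), .bin_index(pts[, 2], yb))
    top <- tapply(seq_along(z), cell, function(ii) ii[which.max(z[ii])])
    top <- as.integer(top)
    if (length(top) < 3) {  # degenerate lateral extent: flat roof
      dist[sel] <- pmax(0, max(z) - z)
      next
    }
    # surface through the dorsal-most cells' actual XYZ positions
    sf <- data.frame(x = pts[top, 1], y = pts[top, 2], zz = z[top])
    fit <- stats::loess(zz ~ x + y, data = sf, degree = 1,
                        span = min(1, max(0.2, 25 / nrow(sf))),
                        control = stats::loess.control(
                          surface = "direct"))
    zs <- stats::predict(fit, newdata = data.frame(x = pts[, 1],
                                                   y = pts[, 2]))
    dist[sel] <- pmax(0, zs - z)
  }
  cd$local_density <- dens
  cd$dorsal_distance <- dist
  SummarizedExperiment::colData(ns) <- cd
  ns
}

#' Semi-supervised epiblast classification
#'
#' Nuclei are grouped into micro-clusters of about 5 cells by k-means on
#' the feature space; features are averaged per cluster; a random forest
#' is trained on the clusters that contain labeled nuclei (majority
#' label) and predicts all clusters; cluster labels propagate back to
#' member nuclei. Held-out accuracy is estimated by stratified 5-fold
#' cross-validation over the labeled clusters.
#'
#' @param ns a \linkS4class{NucleiSet} after
#'   \code{\link{computeFeatures}}.
#' @param labels character per nucleus: \code{"epiblast"},
#'   \code{"non_epiblast"} or \code{"unlabeled"}.
#' @param features colData columns / channels used as features (default:
#'   \code{local_density}, \code{dorsal_distance} and all channels' NFI).
#' @param cluster_size intended micro-cluster size (default 5).
#' @param seed RNG seed (clustering restarts, forest, fold split).
#' @return list with \code{labels} (predicted, per nucleus),
#'   \code{accuracy} (held-out), \code{cluster_id} (per nucleus) and the
#'   fitted \code{model}.
#' @export
classifyEpiblast <- function(ns, labels, features = NULL,
                             cluster_size = 5L, seed = 1) {
  cd <- SummarizedExperiment::colData(ns)
  if (is.null(features)) {
    fm <- cbind(local_density = cd$local_density,
                dorsal_distance = cd$dorsal_distance)
    if ("nfi" %in% SummarizedExperiment::assayNames(ns))
      fm <- cbind(fm, t(SummarizedExperiment::assay(ns, "nfi")))
  } else {
    fm <- do.call(cbind, lapply(features, function(f) {
      if (f %in% colnames(cd)) cd[[f]]
      else .channel_values(ns, f, "nfi")
    }))
    colnames(fm) <- features
  }
  fm <- as.matrix(fm)
  n <- nrow(fm)
  k <- max(2L, as.integer(round(n / cluster_size)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(.derive_seed(seed, "microclusters"))
  km <- stats::kmeans(fm, centers = k, nstart = 1, iter.max = 50)
  clus <- km$cluster
  cfeat <- apply(fm, 2, function(col) tapply(col, clus, mean))
  # majority label among labeled members, per cluster
  clab <- rep(NA_character_, k)
  for (cl in seq_len(k)) {
    l <- labels[clus == cl]
    l <- l[l %in% c("epiblast", "non_epiblast")]
    if (length(l) > 0)
      clab[cl] <- names(which.max(table(l)))
  }
  lab_idx <- which(!is.na(clab))
  if (length(lab_idx) < 20)
    stop("need at least 20 labeled micro-clusters (", length(lab_idx),
         " found)")
  train <- data.frame(cfeat[lab_idx, , drop = FALSE],
                      .label = factor(clab[lab_idx]))
  # stratified 5-fold CV over labeled clusters
  folds <- integer(length(lab_idx))
  for (lv in levels(train$.label)) {
    w <- which(train$.label == lv)
    folds[w] <- sample(rep_len(1:5, length(w)))
  }
  correct <- 0
  for (f in 1:5) {
    tr <- train[folds != f, , drop = FALSE]
    te <- train[folds == f, , drop = FALSE]
    if (nrow(te) == 0 || length(unique(tr$.label)) < 2) next
    rf <- ranger::ranger(.label ~ ., data = tr, num.trees = 200,
                         seed = .derive_seed(seed, paste0("fold", f)))
    correct <- correct + sum(stats::predict(rf, te)$predictions ==
                               te$.label)
  }
  accuracy <- correct / length(lab_idx)
  rf_full <- ranger::ranger(.label ~ ., data = train, num.trees = 500,
                            seed = .derive_seed(seed, "rf"))
  pred_clab <- as.character(
    stats::predict(rf_full,
                   data.frame(cfeat, check.names = FALSE))$predictions)
  pred_clab[lab_idx] <- clab[lab_idx]  # keep supervised labels
  out <- pred_clab[clus]
  names(out) <- colnames(ns)
  list(labels = out, accuracy = accuracy, cluster_id = clus,
       model = rf_full)
}

#' Neighbor-vote post-processing of epiblast labels
#'
#' Iteratively converts any non-epiblast nucleus whose neighbors are
#' strictly more than 50% epiblast, with simultaneous flips per round,
#' until a fixed point (the rule is one-directional, so the epiblast set
#' only grows and convergence is guaranteed) or \code{max_iters}.
#'
#' @param labels named character per nucleus (\code{"epiblast"} /
#'   \code{"non_epiblast"}).
#' @param graph a \linkS4class{NeighborGraph} over (at least) the labeled
#'   nuclei.
#' @param max_iters iteration cap (default: number of nuclei).
#' @return updated labels, with an \code{iterations} attribute.
#' @export
postprocessLabels <- function(labels, graph, max_iters = NULL) {
  if (is.null(max_iters)) max_iters <- length(graph@nodes)
  adj <- adjacencyList(graph)
  lab <- labels[graph@nodes]
  it <- 0L
  repeat {
    if (it >= max_iters) break
    epi <- lab == "epiblast"
    flip <- vapply(seq_along(lab), function(i) {
      if (epi[i] || length(adj[[i]]) == 0) return(FALSE)
      mean(epi[adj[[i]]]) > 0.5
    }, logical(1))
    if (!any(flip)) break
    lab[flip] <- "epiblast"
    it <- it + 1L
  }
  out <- labels
  out[graph@nodes] <- lab
  attr(out, "iterations") <- it
  out
}

#' Label surface cells inside the high-density mask
#'
#' Bootstrap labels for \code{\link{classifyEpiblast}} when manual
#' labels are scarce: a 2D map of mean local nuclear density over
#' lateral bins is thresholded (Otsu by default) into a high-density
#' mask, and cells that lie both inside the mask and within
#' \code{surface_um} of the dorsal surface are labeled epiblast.
#' Everything else stays unlabeled.
#'
#' @param ns a \linkS4class{NucleiSet} after
#'   \code{\link{computeFeatures}}.
#' @param bin_um lateral bin size (default 20).
#' @param surface_um maximal dorsal distance of a "surface" cell
#'   (default 5).
#' @param threshold density threshold, or \code{"otsu"} (default).
#' @return character vector per nucleus: \code{"epiblast"} or
#'   \code{"unlabeled"}.
#' @export
autoLabelSurface <- function(ns, bin_um = 20, surface_um = 5,
                             threshold = "otsu") {
  cd <- SummarizedExperiment::colData(ns)
  if (is.null(cd$local_density) || is.null(cd$dorsal_distance))
    stop("run computeFeatures() first")
  out <- rep("unlabeled", ncol(ns))
  for (em in embryoIDs(ns)) {
    sel <- which(cd$embryo_id == em)
    x <- cd$x[sel]; y <- cd$y[sel]
    xb <- seq(min(x) - 1e-9, max(x) + bin_um, by = bin_um)
    yb <- seq(min(y) - 1e-9, max(y) + bin_um, by = bin_um)
    cell <- paste(.bin_index(x, xb), .bin_index(y, yb))
    dens_map <- tapply(cd$local_density[sel], cell, mean)
    thr <- if (identical(threshold, "otsu"))
      .otsu(as.numeric(dens_map)) else threshold
    if (is.na(thr)) thr <- -Inf  # uniform density: whole map is mask
    high_bins <- names(dens_map)[dens_map >= thr]
    hit <- cell %in% high_bins & cd$dorsal_distance[sel] <= surface_um
    out[sel[hit]] <- "epiblast"
  }
  stats::setNames(out, colnames(ns))
}
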