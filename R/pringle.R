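#' @include NucleiSet-methods.R principal-curve.R
NULL

#' Project a curved epithelium onto a 2D map (PRINGLE step 1)
#'
#' Flattens the 3D sheet per embryo in two passes of principal-curve
#' fitting. First a sagittal principal curve is fitted in the (y, z)
#' plane; the anteroposterior coordinate \code{ap_um} of each nucleus is
#' the signed arc length of its nearest curve point (zeroed at the node
#' when flagged, oriented so the primitive-streak tip is positive), and
#' the preliminary dorsoventral offset \code{dv_um} is the signed
#' distance to that curve. Second, nuclei are partitioned into
#' overlapping slabs along \code{ap_um}; per slab a transverse principal
#' curve is fitted in the (x, dv) plane and the left--right coordinate
#' \code{lr_um} is the arc length along it. Slab coordinates are stitched
#' into one continuous \code{lr_um} using the nuclei shared by
#' overlapping slabs.
#'
#' @param ns a \linkS4class{NucleiSet}.
#' @param tissue tissue to project (default \code{"epiblast"}); other
#'   nuclei get \code{NA} coordinates.
#' @param slab_width_um transverse slab width with 50% overlap;
#'   \code{NULL} (default) sizes slabs as 5 times the median
#'   nearest-neighbor spacing, which is 40 micrometers at the reference
#'   nuclear packing of 8 and keeps aligned maps independent of embryo
#'   size (sections scale with the tissue).
#' @param span_ap sagittal principal-curve span (default 0.7: the
#'   sagittal pass should capture only the tissue-scale A-P bend, not
#'   the lateral spread of the sheet).
#' @param span_lr transverse principal-curve span (default 0.2: each
#'   slab's cross-section is strongly curved and needs a local smoother).
#' @param min_slab minimum nuclei per slab; smaller slabs are merged with
#'   their neighbor (default 10).
#' @return the \code{NucleiSet} with \code{ap_um}, \code{lr_um} and
#'   \code{dv_um} colData columns.
#' @export
pringleProject <- function(ns, tissue = "epiblast",
                           slab_width_um = NULL,
                           span_ap = 0.7, span_lr = 0.2,
                           min_slab = 10L) {
  cd <- SummarizedExperiment::colData(ns)
  ap <- rep(NA_real_, ncol(ns))
  lr <- rep(NA_real_, ncol(ns))
  dv <- rep(NA_real_, ncol(ns))
  for (em in embryoIDs(ns)) {
    sel <- which(cd$embryo_id == em &
                   (is.null(tissue) | cd$tissue == tissue))
    if (length(sel) < 10) next
    pts <- centroids(ns)[sel, , drop = FALSE]
    sag <- fitPrincipalCurve(pts[, c("y", "z")], span = span_ap)
    ap_e <- sag@lambda
    dv_e <- sag@distance
    # orientation and origin from landmarks when present
    node_i <- which(cd$is_node[sel])
    tip_i <- which(cd$is_ps_tip[sel])
    if (length(node_i) == 1 && length(tip_i) == 1 &&
        ap_e[tip_i] < ap_e[node_i]) ap_e <- -ap_e
    if (length(node_i) == 1) ap_e <- ap_e - ap_e[node_i]
    width <- if (is.null(slab_width_um))
      5 * .median_nn(pts) else slab_width_um
    lr_e <- .slab_lr(pts[, "x"], dv_e, ap_e, width, span_lr,
                     min_slab)
    ap[sel] <- ap_e
    lr[sel] <- lr_e
    dv[sel] <- dv_e
  }
  cd$ap_um <- ap
  cd$lr_um <- lr
  cd$dv_um <- dv
  SummarizedExperiment::colData(ns) <- cd
  ns
}

# median nearest-neighbor distance (subsampled above 1500 points)
.median_nn <- function(pts) {
  n <- nrow(pts)
  q <- if (n > 1500) round(seq(1, n, length.out = 500)) else seq_len(n)
  nn <- vapply(q, function(i) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
      (pts[, 3] - pts[i, 3])^2
    sqrt(min(d2[-i]))
  }, numeric(1))
  stats::median(nn)
}

# transverse pass: overlapping slabs along ap, one principal curve per
# slab in the (x, dv) plane, stitched by shared-nucleus offsets
.slab_lr <- function(x, dv, ap, width, span, min_slab) {
  n <- length(x)
  rng <- range(ap)
  if (diff(rng) <= width) {
    starts <- rng[1]
  } else {
    starts <- seq(rng[1], rng[2] - width, by = width / 2)
    if (utils::tail(starts, 1) + width < rng[2])
      starts <- c(starts, rng[2] - width)
  }
  members <- lapply(starts, function(s)
    which(ap >= s - 1e-9 & ap <= s + width + 1e-9))
  # merge undersized slabs into their neighbor
  i <- 1
  while (i <= length(members)) {
    if (length(members[[i]]) < max(min_slab, 10)) {
      j <- if (i > 1) i - 1 else i + 1
      if (j >= 1 && j <= length(members)) {
        members[[j]] <- sort(unique(c(members[[j]], members[[i]])))
        members[[i]] <- NULL
        next
      }
    }
    i <- i + 1
  }
  if (length(members) == 0) return(rep(NA_real_, n))
  lr_slab <- vector("list", length(members))
  for (s in seq_along(members)) {
    idx <- members[[s]]
    pc <- fitPrincipalCurve(cbind(x[idx], dv[idx]), span = span)
    l <- pc@lambda
    # orient with the lateral axis, center on the slab for stitching
    if (stats::cor(l, x[idx]) < 0) l <- -l
    lr_slab[[s]] <- l - stats::median(l) + stats::median(x[idx])
  }
  # chain offsets through shared nuclei
  offset <- numeric(length(members))
  for (s in seq_along(members)[-1]) {
    shared <- intersect(members[[s - 1]], members[[s]])
    if (length(shared) >= 3) {
      prev_l <- lr_slab[[s - 1]][match(shared, members[[s - 1]])] +
        offset[s - 1]
      cur_l <- lr_slab[[s]][match(shared, members[[s]])]
      offset[s] <- mean(prev_l - cur_l)
    } else {
      offset[s] <- offset[s - 1]
    }
  }
  acc <- numeric(n)
  cnt <- numeric(n)
  for (s in seq_along(members)) {
    idx <- members[[s]]
    acc[idx] <- acc[idx] + lr_slab[[s]] + offset[s]
    cnt[idx] <- cnt[idx] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Detect the midline and re-zero the left--right coordinate
#'
#' The midline is the mean left--right position of the nuclei whose
#' spatially smoothed marker value (TBXT by default) is at or above the
#' 90th percentile; \code{lr_um} is re-zeroed there.
#'
#' @param ns a \linkS4class{NucleiSet} with \code{lr_um} and a
#'   \code{"smooth"} assay.
#' @param channel midline marker (default \code{"TBXT"} when present).
#' @param percentile quantile defining the marker-high set (default 0.9).
#' @param offset manual midline offset per embryo (named numeric),
#'   bypassing detection.
#' @return the \code{NucleiSet} with re-zeroed \code{lr_um}; offsets are
#'   recorded in \code{metadata(ns)$midline}.
#' @export
detectMidline <- function(ns, channel = NULL, percentile = 0.9,
                          offset = NULL) {
  cd <- SummarizedExperiment::colData(ns)
  if (is.null(channel))
    channel <- if ("TBXT" %in% rownames(ns)) "TBXT" else rownames(ns)[1]
  md <- S4Vectors::metadata(ns)
  md$midline <- list()
  lr <- cd$lr_um
  for (em in embryoIDs(ns)) {
    sel <- which(cd$embryo_id == em & !is.na(lr))
    if (length(sel) == 0) next
    if (!is.null(offset) && em %in% names(offset)) {
      off <- offset[[em]]
    } else {
      v <- .channel_values(ns, channel, "smooth")[sel]
      thr <- stats::quantile(v, percentile, na.rm = TRUE)
      high <- sel[!is.na(v) & v >= thr]
      if (length(high) < 20)
        stop("fewer than 20 nuclei above the ", percentile,
             " quantile of smoothed ", channel, " in embryo ", em,
             "; supply a manual midline offset")
      off <- mean(lr[high])
    }
    lr[sel] <- lr[sel] - off
    md$midline[[em]] <- off
  }
  cd$lr_um <- lr
  SummarizedExperiment::colData(ns) <- cd
  S4Vectors::metadata(ns) <- md
  ns
}

#' Normalize projected coordinates to landmarks and align embryos
#'
#' Converts per-embryo absolute projected coordinates into the shared
#' landmark frame: \code{ap_rel} = arc length rescaled so the node is 0
#' and the primitive-streak posterior tip is 1 (anterior nuclei keep
#' values below 0); \code{lr_rel} = \code{lr_um} divided by the epiblast
#' half-width at that AP bin, where the half-width ("edge of epiblast")
#' is the 97.5th percentile of \code{|lr_um|} among epiblast nuclei in
#' the bin; and \code{lr_scaled} = \code{lr_rel} times the across-embryo
#' mean half-width at that bin, which removes the distortion that purely
#' relative widths introduce.
#'
#' @param ns a \linkS4class{NucleiSet} after \code{\link{pringleProject}}
#'   and \code{\link{detectMidline}}, with node and tip nuclei flagged.
#' @param ap_bin_width AP bin width in relative units (default 0.1).
#' @param edge_percentile robust-maximum percentile for the epiblast edge
#'   (default 0.975).
#' @return the \code{NucleiSet} with \code{ap_rel}, \code{lr_rel},
#'   \code{lr_scaled} columns; per-embryo \linkS4class{LandmarkSet}
#'   objects are stored in \code{metadata(ns)$landmarks}.
#' @export
normalizeAlign <- function(ns, ap_bin_width = 0.1,
                           edge_percentile = 0.975) {
  cd <- SummarizedExperiment::colData(ns)
  ap_rel <- rep(NA_real_, ncol(ns))
  for (em in embryoIDs(ns)) {
    sel <- which(cd$embryo_id == em)
    node <- sel[cd$is_node[sel]]
    tip <- sel[cd$is_ps_tip[sel]]
    if (length(node) != 1 || length(tip) != 1)
      stop("embryo ", em, " is missing a node and/or primitive-streak ",
           "tip landmark")
    span_ap <- cd$ap_um[tip] - cd$ap_um[node]
    if (!is.finite(span_ap) || span_ap <= 0)
      stop("embryo ", em, ": tip must be posterior to the node in ap_um")
    ap_rel[sel] <- (cd$ap_um[sel] - cd$ap_um[node]) / span_ap
  }
  # shared AP bins in relative units
  brk <- seq(floor(min(ap_rel, na.rm = TRUE) / ap_bin_width) *
               ap_bin_width,
             ceiling(max(ap_rel, na.rm = TRUE) / ap_bin_width) *
               ap_bin_width + ap_bin_width, by = ap_bin_width)
  mids <- utils::head(brk, -1) + ap_bin_width / 2
  half <- matrix(NA_real_, length(mids), length(embryoIDs(ns)),
                 dimnames = list(NULL, embryoIDs(ns)))
  bin <- .bin_index(ap_rel, brk)
  for (em in embryoIDs(ns)) {
    sel <- which(cd$embryo_id == em & cd$tissue == "epiblast" &
                   !is.na(cd$lr_um) & !is.na(ap_rel))
    hw <- tapply(abs(cd$lr_um[sel]), factor(bin[sel],
                                            levels = seq_along(mids)),
                 stats::quantile, probs = edge_percentile, names = FALSE)
    hw <- as.numeric(hw)
    ok <- !is.na(hw)
    if (sum(ok) >= 2)  # carry edges across sparse bins
      hw <- stats::approx(mids[ok], hw[ok], xout = mids, rule = 2)$y
    half[, em] <- hw
  }
  mean_half <- rowMeans(half, na.rm = TRUE)
  lr_rel <- rep(NA_real_, ncol(ns))
  lr_scaled <- rep(NA_real_, ncol(ns))
  lm <- list()
  for (em in embryoIDs(ns)) {
    sel <- which(cd$embryo_id == em & !is.na(cd$lr_um) & !is.na(ap_rel))
    # continuous interpolation between bin centers avoids jumps at
    # bin boundaries (the edge estimator itself stays per-bin)
    hw <- stats::approx(mids, half[, em], xout = ap_rel[sel],
                        rule = 2)$y
    lr_rel[sel] <- cd$lr_um[sel] / hw
    lr_scaled[sel] <- lr_rel[sel] *
      stats::approx(mids, mean_half, xout = ap_rel[sel], rule = 2)$y
    node <- sel[cd$is_node[sel]]
    lm[[em]] <- methods::new("LandmarkSet", embryo = em, nodeAP = 0,
                             tipAP = 1,
                             midlineOffset =
                               if (!is.null(S4Vectors::metadata(ns)$
                                              midline[[em]]))
                                 S4Vectors::metadata(ns)$midline[[em]]
                               else NA_real_,
                             edgeTable = data.frame(ap_mid = mids,
                                                    half_width =
                                                      half[, em]))
  }
  cd$ap_rel <- ap_rel
  cd$lr_rel <- lr_rel
  cd$lr_scaled <- lr_scaled
  SummarizedExperiment::colData(ns) <- cd
  md <- S4Vectors::metadata(ns)
  md$landmarks <- lm
  md$mean_half_width <- data.frame(ap_mid = mids, half_width = mean_half)
  S4Vectors::metadata(ns) <- md
  ns
}

#' Fold the map at the midline
#'
#' Replaces the left--right coordinates by their absolute values so that
#' bilaterally symmetric data pool across sides; the original side is
#' recorded. Idempotent.
#'
#' @param ns a \linkS4class{NucleiSet} with projected coordinates.
#' @return the \code{NucleiSet} with folded \code{lr_um}/\code{lr_rel}/
#'   \code{lr_scaled}, a \code{side} column and \code{folded = TRUE}.
#' @export
foldAtMidline <- function(ns) {
  cd <- SummarizedExperiment::colData(ns)
  if (is.null(cd$side))
    cd$side <- ifelse(is.na(cd$lr_um), NA_character_,
                      ifelse(cd$lr_um < 0, "left", "right"))
  for (col in c("lr_um", "lr_rel", "lr_scaled"))
    if (!is.null(cd[[col]])) cd[[col]] <- abs(cd[[col]])
  cd$folded <- TRUE
  SummarizedExperiment::colData(ns) <- cd
  ns
}

#' Binned statistic on the aligned 2D map
#'
#' Bins the aligned coordinates on a regular grid and computes either the
#' per-bin mean of a per-nucleus value or the per-bin density (cell count
#' over total count) of a selected population. With several embryos,
#' per-embryo maps are computed first and then averaged, so each embryo
#' carries equal weight regardless of its size.
#'
#' @param ns a \linkS4class{NucleiSet} with aligned coordinates.
#' @param values numeric per-nucleus values (\code{statistic = "mean"})
#'   or a logical population mask (\code{statistic = "density"}).
#' @param statistic \code{"mean"} or \code{"density"}.
#' @param ap_breaks,lr_breaks grid bin edges.
#' @param coords colData columns used as map coordinates (default
#'   \code{c("ap_rel", "lr_scaled")}).
#' @return a \linkS4class{Map2D}.
#' @export
binnedMap <- function(ns, values, statistic = c("mean", "density"),
                      ap_breaks, lr_breaks,
                      coords = c("ap_rel", "lr_scaled")) {
  statistic <- match.arg(statistic)
  if (length(ap_breaks) < 2 || length(lr_breaks) < 2)
    stop("empty grid")
  cd <- SummarizedExperiment::colData(ns)
  apv <- cd[[coords[1]]]
  lrv <- cd[[coords[2]]]
  nlr <- length(lr_breaks) - 1
  nap <- length(ap_breaks) - 1
  maps <- list()
  for (em in embryoIDs(ns)) {
    sel <- cd$embryo_id == em & !is.na(apv) & !is.na(lrv)
    ai <- .bin_index(apv[sel], ap_breaks)
    li <- .bin_index(lrv[sel], lr_breaks)
    inside <- ai >= 1 & ai <= nap & li >= 1 & li <= nlr
    m <- matrix(NaN, nlr, nap)
    if (statistic == "mean") {
      v <- values[which(sel)][inside]
      f <- interaction(li[inside], ai[inside], drop = FALSE)
      mm <- tapply(v, list(factor(li[inside], levels = seq_len(nlr)),
                           factor(ai[inside], levels = seq_len(nap))),
                   mean, na.rm = TRUE)
      m[] <- mm
    } else {
      pop <- as.logical(values[which(sel)]) & inside
      tot <- sum(pop, na.rm = TRUE)
      cnt <- table(factor(li[pop], levels = seq_len(nlr)),
                   factor(ai[pop], levels = seq_len(nap)))
      m[] <- if (tot > 0) as.numeric(cnt) / tot else 0
    }
    maps[[em]] <- m
  }
  arr <- simplify2array(maps)
  avg <- apply(arr, c(1, 2), function(v)
    if (all(is.nan(v) | is.na(v))) NaN else mean(v[is.finite(v)]))
  methods::new("Map2D", values = avg, apBreaks = ap_breaks,
               lrBreaks = lr_breaks, statistic = statistic,
               nEmbryos = length(maps))
}

setMethod("show", "Map2D", function(object) {
  cat("Map2D (", object@statistic, "): ", nrow(object@values), " x ",
      ncol(object@values), " bins, ", object@nEmbryos, " embryo(s)\n",
      sep = "")
  invisible(NULL)
})

#' Write a Map2D as a CSV grid
#'
#' @param map a \linkS4class{Map2D}.
#' @param path output path; rows = lr bins, columns = ap bins, with bin
#'   centers as names.
#' @return \code{path}, invisibly.
#' @export
writeMap2D <- function(map, path) {
  m <- map@values
  apm <- utils::head(map@apBreaks, -1) + diff(map@apBreaks) / 2
  lrm <- utils::head(map@lrBreaks, -1) + diff(map@lrBreaks) / 2
  dimnames(m) <- list(sprintf("lr=%g", lrm), sprintf("ap=%g", apm))
  utils::write.csv(m, path)
  invisible(path)
}
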