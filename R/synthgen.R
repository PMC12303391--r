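#' @include NucleiSet-methods.R neighbors.R
NULL

#' Specification for a synthetic embryo
#'
#' Describes a curved epithelial sheet of nuclei with known ground truth:
#' the surface geometry, nuclear packing, per-channel expression
#' patterns, and the acquisition artifacts (noise, bleed-through, depth
#' attenuation) that the analysis pipeline is meant to undo. The same
#' spec and seed always generate bit-identical output, and every
#' generated table carries ground-truth columns (\code{true_ap},
#' \code{true_lr}, \code{truth_<channel>}, \code{true_layer}, and
#' \code{truth_pseudospace} for trajectory patterns) sufficient to score
#' each analysis stage.
#'
#' Surfaces: \code{"flat"} (x = lateral, y = AP), \code{"cylinder"} (a
#' cylindrical section of radius \code{radius} and half-angle
#' \code{theta_max} around the AP axis, the idealized curved epiblast;
#' true lateral position is the unrolled arc length), \code{"saddle"}
#' (z = (v^2 - u^2) / \code{saddle_scale}), \code{"ellipsoid"} (an
#' ellipsoidal cap). Patterns per channel: \code{linear} (graded along
#' \code{axis}), \code{stripe} (within \code{inner} <= |lr| <=
#' \code{outer}, with optional linear narrowing to \code{outer_end}),
#' \code{bump} (Gaussian), \code{mshape} (two lateral ridges),
#' \code{midline} (Gaussian ridge at lr = 0), \code{spots}
#' (lateral-inhibition: high cells chosen by sequential inhibition so no
#' two high cells are adjacent on the ground-truth graph),
#' \code{random_spots} (same fraction, placed at random),
#' \code{iid} (i.i.d. normal null), \code{constant}, and
#' \code{trajectory} (channels as functions of a shared latent state
#' parameter increasing along AP; roles \code{"early"}, \code{"mid"},
#' \code{"late"}).
#'
#' @param surface surface type (see Details).
#' @param radius cylinder/ellipsoid radius, micrometers (default 100).
#' @param theta_max cylinder half-angle, radians (default pi/2: a half
#'   cylinder).
#' @param ap_length node-to-streak-tip extent, micrometers (default 300).
#' @param ap_anterior anterior margin beyond the node (default 60).
#' @param half_width lateral half-width for flat/saddle surfaces
#'   (default 150).
#' @param saddle_scale saddle curvature divisor (default 400).
#' @param n_nuclei nuclei in the epithelial layer (default 2000).
#' @param spacing minimum nuclear spacing, micrometers (default 8,
#'   Poisson-disk sampling mimics nuclear exclusion volumes).
#' @param jitter_um 3D positional jitter s.d. (default 1).
#' @param sublayer_offset depth of an optional second (deep) layer below
#'   the sheet (default 0 = none).
#' @param n_sublayer nuclei in the deep layer.
#' @param channels named list of pattern descriptions (see Details);
#'   default: a TBXT midline ridge, an anterior-high SOX2 gradient and a
#'   posterior-high TBX6 gradient.
#' @param background,amplitude raw-intensity offset and dynamic range.
#' @param noise_sd Gaussian noise s.d. as a fraction of amplitude
#'   (default 0.05).
#' @param bleed optional list(source, target, c): target picks up
#'   c x source.
#' @param depth_decay exponential attenuation length constant along z
#'   (micrometers; \code{Inf} = off).
#' @param embryo_id,condition,stage metadata for the generated table.
#' @param seed RNG seed.
#' @return an object of class \code{"SyntheticSpec"} (a validated list).
#' @export
syntheticSpec <- function(surface = c("cylinder", "flat", "saddle",
                                      "ellipsoid"),
                          radius = 100, theta_max = pi / 2,
                          ap_length = 300, ap_anterior = 60,
                          half_width = 150, saddle_scale = 400,
                          n_nuclei = 2000, spacing = 8, jitter_um = 1,
                          sublayer_offset = 0, n_sublayer = 0,
                          channels = list(
                            TBXT = list(pattern = "midline", width = 25),
                            SOX2 = list(pattern = "linear", axis = "ap",
                                        invert = TRUE),
                            TBX6 = list(pattern = "linear",
                                        axis = "ap")),
                          background = 10, amplitude = 100,
                          noise_sd = 0.05, bleed = NULL,
                          depth_decay = Inf, embryo_id = "sim1",
                          condition = "none", stage = "sim",
                          seed = 1) {
  spec <- list(surface = match.arg(surface), radius = radius,
               theta_max = theta_max, ap_length = ap_length,
               ap_anterior = ap_anterior, half_width = half_width,
               saddle_scale = saddle_scale, n_nuclei = n_nuclei,
               spacing = spacing, jitter_um = jitter_um,
               sublayer_offset = sublayer_offset,
               n_sublayer = n_sublayer, channels = channels,
               background = background, amplitude = amplitude,
               noise_sd = noise_sd, bleed = bleed,
               depth_decay = depth_decay, embryo_id = embryo_id,
               condition = condition, stage = stage, seed = seed)
  stopifnot(spec$n_nuclei >= 0, spec$spacing > 0,
            length(spec$channels) >= 1)
  class(spec) <- "SyntheticSpec"
  spec
}

# Poisson-disk (dart-throwing) sampling of n points in a rectangle with
# minimum distance rmin, grid-accelerated; deterministic under the
# caller's RNG state
.poisson_disk <- function(n, ulim, vlim, rmin) {
  if (n == 0) return(cbind(u = numeric(0), v = numeric(0)))
  area <- diff(ulim) * diff(vlim)
  rmin <- min(rmin, 0.7 * sqrt(area / n))  # guarantee n points fit
  cell <- rmin / sqrt(2)
  nu <- max(1, ceiling(diff(ulim) / cell))
  nv <- max(1, ceiling(diff(vlim) / cell))
  grid <- matrix(NA_integer_, nu, nv)
  pu <- numeric(n); pv <- numeric(n)
  got <- 0L
  attempts <- 0L
  max_attempts <- 60L * n
  while (got < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cu <- stats::runif(1, ulim[1], ulim[2])
    cv <- stats::runif(1, vlim[1], vlim[2])
    gi <- min(nu, 1L + floor((cu - ulim[1]) / cell))
    gj <- min(nv, 1L + floor((cv - vlim[1]) / cell))
    ok <- TRUE
    for (i in max(1, gi - 2):min(nu, gi + 2)) {
      for (j in max(1, gj - 2):min(nv, gj + 2)) {
        q <- grid[i, j]
        if (!is.na(q) &&
            (pu[q] - cu)^2 + (pv[q] - cv)^2 < rmin^2) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) {
      got <- got + 1L
      pu[got] <- cu; pv[got] <- cv
      grid[gi, gj] <- got
    }
  }
  cbind(u = pu[seq_len(got)], v = pv[seq_len(got)])
}

# surface coordinate chart: (u = ap, v = lateral arc) -> 3D + inward
# normal (unit vector pointing into the tissue, away from the objective)
.surface_map <- function(spec, u, v) {
  s <- spec$surface
  if (s == "flat") {
    xyz <- cbind(x = v, y = u, z = rep(0, length(u)))
    nrm <- cbind(0, 0, rep(-1, length(u)))
  } else if (s == "cylinder") {
    th <- v / spec$radius
    xyz <- cbind(x = spec$radius * sin(th), y = u,
                 z = spec$radius * cos(th))
    nrm <- cbind(-sin(th), 0, -cos(th))
  } else if (s == "saddle") {
    z <- (v^2 - u^2) / spec$saddle_scale
    xyz <- cbind(x = v, y = u, z = z)
    # unnormalized downward normal of z - f(x,y)
    gx <- 2 * v / spec$saddle_scale
    gy <- -2 * u / spec$saddle_scale
    nn <- sqrt(gx^2 + gy^2 + 1)
    nrm <- cbind(gx / nn, gy / nn, -1 / nn)
  } else {  # ellipsoid cap
    a <- spec$half_width; b <- (spec$ap_length + spec$ap_anterior) / 2
    u0 <- (spec$ap_length - spec$ap_anterior) / 2
    arg <- pmax(0, 1 - (v / a)^2 - ((u - u0) / b)^2)
    z <- spec$radius * sqrt(arg)
    xyz <- cbind(x = v, y = u, z = z)
    gx <- ifelse(arg > 0, -spec$radius * v / (a^2 * sqrt(arg) + 1e-9), 0)
    gy <- ifelse(arg > 0,
                 -spec$radius * (u - u0) / (b^2 * sqrt(arg) + 1e-9), 0)
    nn <- sqrt(gx^2 + gy^2 + 1)
    nrm <- cbind(gx / nn, gy / nn, -1 / nn)
  }
  list(xyz = xyz, normal = nrm)
}

.v_limits <- function(spec) {
  if (spec$surface == "cylinder")
    c(-1, 1) * spec$radius * spec$theta_max
  else c(-1, 1) * spec$half_width
}

# paint one channel's pattern on surface coordinates; returns list with
# value (the noiseless pattern, the ground truth) and optional extras
.paint_pattern <- function(ch, spec, u, v) {
  ulim <- c(-spec$ap_anterior, spec$ap_length)
  vlim <- .v_limits(spec)
  t_ap <- (u - ulim[1]) / diff(ulim)
  extras <- list()
  val <- switch(ch$pattern,
    constant = rep(if (is.null(ch$value)) 0.5 else ch$value, length(u)),
    linear = {
      tt <- if (identical(ch$axis, "lr"))
        (v - vlim[1]) / diff(vlim) else t_ap
      if (isTRUE(ch$invert)) 1 - tt else tt
    },
    midline = {
      w <- if (is.null(ch$width)) 25 else ch$width
      exp(-v^2 / (2 * w^2))
    },
    mshape = {
      pos <- if (is.null(ch$position)) 0.55 else ch$position
      w <- if (is.null(ch$width)) 0.18 else ch$width
      vn <- abs(v) / max(abs(vlim))
      exp(-(vn - pos)^2 / (2 * w^2))
    },
    bump = {
      cu <- if (is.null(ch$center_ap)) mean(ulim) else ch$center_ap
      cv <- if (is.null(ch$center_lr)) 0 else ch$center_lr
      w <- if (is.null(ch$width)) 30 else ch$width
      exp(-((u - cu)^2 + (v - cv)^2) / (2 * w^2))
    },
    stripe = {
      inner <- if (is.null(ch$inner)) 10 else ch$inner
      outer <- if (is.null(ch$outer)) 45 else ch$outer
      out_t <- if (is.null(ch$outer_end)) outer else
        outer + (ch$outer_end - outer) * pmin(1, pmax(0, t_ap))
      as.numeric(abs(v) >= inner & abs(v) <= out_t)
    },
    spots = ,
    random_spots = {
      f <- if (is.null(ch$fraction)) 0.1 else ch$fraction
      contrast <- if (is.null(ch$contrast)) 3 else ch$contrast
      n <- length(u)
      if (ch$pattern == "spots") {
        ed <- .delaunay_edges(cbind(u, v, 0), mode = "2d")
        adj <- vector("list", n)
        for (r in seq_len(nrow(ed))) {
          adj[[ed[r, 1]]] <- c(adj[[ed[r, 1]]], ed[r, 2])
          adj[[ed[r, 2]]] <- c(adj[[ed[r, 2]]], ed[r, 1])
        }
        high <- logical(n)
        for (i in sample.int(n)) {  # sequential inhibition
          if (sum(high) >= round(f * n)) break
          if (!any(high[adj[[i]]])) high[i] <- TRUE
        }
      } else {
        high <- logical(n)
        high[sample.int(n, round(f * n))] <- TRUE
      }
      extras$high <- high
      ifelse(high, 1, 1 / contrast)
    },
    iid = {
      mu <- if (is.null(ch$mu)) 0.5 else ch$mu
      sdv <- if (is.null(ch$sd)) 0.15 else ch$sd
      stats::rnorm(length(u), mu, sdv)
    },
    trajectory = {
      extras$state <- t_ap
      switch(ch$role,
             early = 1 - t_ap,
             mid = exp(-(t_ap - 0.5)^2 / (2 * 0.18^2)),
             late = t_ap)
    },
    stop("unknown pattern '", ch$pattern, "'"))
  c(list(value = val), extras)
}

#' Generate a synthetic embryo with ground truth
#'
#' Samples nuclei on the spec's surface by Poisson-disk sampling, paints
#' the per-channel expression patterns in surface coordinates, maps to
#' 3D, optionally adds a deep cell layer, and applies the acquisition
#' artifacts (noise, bleed-through, depth attenuation) to produce raw
#' channel values. Landmarks (node at ap = 0 on the midline,
#' primitive-streak tip at ap = ap_length) are flagged on the nearest
#' nuclei.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return a \linkS4class{NucleiSet} with ground-truth colData columns
#'   (\code{true_ap}, \code{true_lr}, \code{true_layer},
#'   \code{truth_<channel>}, \code{truth_high_<channel>} for spot
#'   patterns, \code{truth_pseudospace} for trajectory patterns).
#' @export
generateEmbryo <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(.derive_seed(spec$seed, paste0("embryo", spec$embryo_id)))

  ulim <- c(-spec$ap_anterior, spec$ap_length)
  vlim <- .v_limits(spec)
  uv <- .poisson_disk(spec$n_nuclei, ulim, vlim, spec$spacing)
  n <- nrow(uv)
  sm <- .surface_map(spec, uv[, 1], uv[, 2])
  xyz <- sm$xyz
  if (spec$jitter_um > 0)
    xyz <- xyz + matrix(stats::rnorm(3 * n, 0, spec$jitter_um), n, 3)

  chans <- names(spec$channels)
  truth <- matrix(NA_real_, n, length(chans),
                  dimnames = list(NULL, chans))
  extra_cols <- list()
  for (ch in chans) {
    p <- .paint_pattern(spec$channels[[ch]], spec, uv[, 1], uv[, 2])
    truth[, ch] <- p$value
    if (!is.null(p$high)) extra_cols[[paste0("truth_high_", ch)]] <- p$high
    if (!is.null(p$state)) extra_cols[["truth_pseudospace"]] <- p$state
  }

  # deep layer under the sheet (coarser packing)
  n2 <- if (spec$sublayer_offset > 0) spec$n_sublayer else 0
  if (n2 > 0) {
    uv2 <- .poisson_disk(n2, ulim, vlim, spec$spacing)
    sm2 <- .surface_map(spec, uv2[, 1], uv2[, 2])
    xyz2 <- sm2$xyz + spec$sublayer_offset * sm2$normal
    if (spec$jitter_um > 0)
      xyz2 <- xyz2 + matrix(stats::rnorm(3 * nrow(uv2), 0,
                                         spec$jitter_um), nrow(uv2), 3)
    xyz <- rbind(xyz, xyz2)
    truth <- rbind(truth, matrix(0, nrow(uv2), length(chans)))
    uv <- rbind(uv, uv2)
    for (nm in names(extra_cols))
      extra_cols[[nm]] <- c(extra_cols[[nm]],
                            rep(if (is.logical(extra_cols[[nm]]))
                              FALSE else NA_real_, nrow(uv2)))
  }
  ntot <- n + n2

  # raw = background + amplitude * pattern (+ artifacts)
  raw <- t(spec$background + spec$amplitude * truth)
  if (!is.null(spec$bleed))
    raw[spec$bleed$target, ] <- raw[spec$bleed$target, ] +
      spec$bleed$c * raw[spec$bleed$source, ]
  if (is.finite(spec$depth_decay)) {
    depth <- xyz[, 3] - min(xyz[, 3])  # z increases with imaging depth
    raw <- raw * matrix(exp(-depth / spec$depth_decay),
                        nrow(raw), ntot, byrow = TRUE)
  }
  if (spec$noise_sd > 0)
    raw <- raw + matrix(stats::rnorm(length(raw), 0,
                                     spec$noise_sd * spec$amplitude),
                        nrow(raw), ntot)
  raw <- pmax(raw, 0)

  # landmarks on the midline
  node <- which.min((uv[seq_len(n), 1])^2 + (uv[seq_len(n), 2])^2)
  tip <- which.min((uv[seq_len(n), 1] - spec$ap_length)^2 +
                     (uv[seq_len(n), 2])^2)
  is_node <- rep(FALSE, ntot); is_node[node] <- TRUE
  is_tip <- rep(FALSE, ntot); is_tip[tip] <- TRUE

  cdat <- data.frame(true_ap = uv[, 1], true_lr = uv[, 2],
                     true_layer = rep(c("surface", "deep"), c(n, n2)))
  for (nm in names(extra_cols)) cdat[[nm]] <- extra_cols[[nm]]
  for (ch in chans) cdat[[paste0("truth_", ch)]] <- truth[, ch]

  NucleiSet(raw = raw, centroids = xyz,
            embryo_id = spec$embryo_id, condition = spec$condition,
            stage = spec$stage,
            tissue = rep(c("epiblast", "non_epiblast"), c(n, n2)),
            is_node = is_node, is_ps_tip = is_tip, colData = cdat)
}

#' Combine several NucleiSets (e.g., embryos) into one
#'
#' @param ... NucleiSet objects, or a single list of them. All must share
#'   channels; colData columns are unioned (missing entries NA).
#' @return a single \linkS4class{NucleiSet}.
#' @export
combineNucleiSets <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) &&
      !methods::is(lst[[1]], "NucleiSet")) lst <- lst[[1]]
  allcols <- unique(unlist(lapply(lst, function(x)
    colnames(SummarizedExperiment::colData(x)))))
  lst <- lapply(lst, function(x) {
    cd <- SummarizedExperiment::colData(x)
    for (nm in setdiff(allcols, colnames(cd))) cd[[nm]] <- NA
    SummarizedExperiment::colData(x) <- cd[, allcols]
    x
  })
  out <- do.call(cbind, lst)
  methods::as(out, "NucleiSet")
}

#' Rasterize a synthetic embryo into a label image and intensity stack
#'
#' Draws each nucleus as a sphere of \code{radius_um} in a voxel grid
#' sized to the centroid extent, with per-channel intensity equal to the
#' nucleus's raw value inside the sphere and \code{background}
#' elsewhere; enables end-to-end tests of
#' \code{\link{quantifyFromLabels}}.
#'
#' @param ns a \linkS4class{NucleiSet} (typically small).
#' @param voxel_size micrometers per voxel, (depth, row, col) order.
#' @param radius_um nuclear sphere radius (default 3).
#' @param background background intensity (default 0).
#' @param margin_um empty margin around the data (default 5).
#' @return list with \code{labels} (3D integer array, (z, y, x)) and
#'   \code{intensities} (named list of 3D arrays).
#' @export
generateLabelImage <- function(ns, voxel_size = c(1, 1, 1),
                               radius_um = 3, background = 0,
                               margin_um = 5) {
  chans <- rownames(ns)
  if (ncol(ns) == 0) {
    dims <- c(1, 1, 1)
    return(list(labels = array(0L, dims),
                intensities = stats::setNames(
                  lapply(chans, function(ch) array(background, dims)),
                  chans)))
  }
  pts <- centroids(ns)
  lo <- apply(pts, 2, min) - margin_um
  hi <- apply(pts, 2, max) + margin_um
  # (z, y, x) array dims from (x, y, z) extents
  dims <- ceiling((hi - lo)[c(3, 2, 1)] / voxel_size)
  labels <- array(0L, dims)
  ints <- stats::setNames(lapply(chans, function(ch)
    array(background, dims)), chans)
  raw <- SummarizedExperiment::assay(ns, "raw")
  rad_vox <- ceiling(radius_um / voxel_size)
  for (k in seq_len(ncol(ns))) {
    cvox <- (pts[k, c(3, 2, 1)] - lo[c(3, 2, 1)]) / voxel_size  # (z,y,x)
    ctr <- cvox + 0.5  # voxel-center convention: center of voxel i is i-0.5
    zr <- max(1, floor(ctr[1] - rad_vox[1])):min(dims[1],
                                                 ceiling(ctr[1] +
                                                           rad_vox[1]))
    yr <- max(1, floor(ctr[2] - rad_vox[2])):min(dims[2],
                                                 ceiling(ctr[2] +
                                                           rad_vox[2]))
    xr <- max(1, floor(ctr[3] - rad_vox[3])):min(dims[3],
                                                 ceiling(ctr[3] +
                                                           rad_vox[3]))
    g <- expand.grid(z = zr, y = yr, x = xr)
    d2 <- ((g$z - 0.5 - cvox[1]) * voxel_size[1])^2 +
      ((g$y - 0.5 - cvox[2]) * voxel_size[2])^2 +
      ((g$x - 0.5 - cvox[3]) * voxel_size[3])^2
    inside <- d2 <= radius_um^2
    lin <- g$z[inside] + dims[1] * (g$y[inside] - 1) +
      dims[1] * dims[2] * (g$x[inside] - 1)
    labels[lin] <- SummarizedExperiment::colData(ns)$nucleus_id[k]
    for (ch in chans) ints[[ch]][lin] <- raw[ch, k]
  }
  list(labels = labels, intensities = ints)
}
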