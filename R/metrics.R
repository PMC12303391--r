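#' @include NucleiSet-methods.R neighbors.R
NULL

# map graph nodes onto NucleiSet columns; errors when the graph refers
# to nuclei the set does not contain
.graph_index <- function(ns, graph) {
  idx <- match(graph@nodes, colnames(ns))
  if (anyNA(idx)) stop("graph contains nuclei absent from the NucleiSet")
  idx
}

#' Local expression gradient and steepness
#'
#' For each nucleus, unit vectors to its neighbors are scaled by the
#' change in smoothed value along them and averaged, giving the raw
#' directional-sum vector b. Because neighbor directions on an irregular
#' mesh are not isotropic, b equals M g rather than the gradient g
#' itself, with M the neighborhood direction metric
#' (mean of |d| u u^T over neighbors); the default estimator therefore
#' solves for g with the pseudo-inverse of M restricted to the subspace
#' the neighbors actually span (exact on linear fields; on a monolayer
#' the out-of-sheet component is suppressed rather than amplified).
#' \code{method = "vectorsum"} returns the uncorrected degree-normalized
#' sum. The gradient magnitude is the steepness.
#'
#' @param ns a \linkS4class{NucleiSet} with a \code{"smooth"} assay.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param channel channel name.
#' @param method \code{"corrected"} (metric-corrected, default) or
#'   \code{"vectorsum"} (plain degree-normalized vector sum).
#' @param normalizeDegree divide the plain vector sum by the node degree
#'   (default TRUE; only used by \code{method = "vectorsum"}).
#' @param assay values to differentiate (default \code{"smooth"}).
#' @return the \code{NucleiSet} with \code{grad_x}/\code{grad_y}/
#'   \code{grad_z}/\code{steepness} assay entries for the channel (units:
#'   value units per micrometer); isolated nuclei get NaN.
#' @export
gradientField <- function(ns, graph, channel,
                          method = c("corrected", "vectorsum"),
                          normalizeDegree = TRUE, assay = "smooth") {
  method <- match.arg(method)
  idx <- .graph_index(ns, graph)
  v <- .channel_values(ns, channel, assay)[idx]
  pts <- centroids(ns)[idx, , drop = FALSE]
  adj <- adjacencyList(graph)
  n <- length(idx)
  g <- matrix(NaN, n, 3)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) == 0) next
    d <- pts[nb, , drop = FALSE] -
      matrix(pts[i, ], length(nb), 3, byrow = TRUE)
    len <- sqrt(rowSums(d^2))
    u <- d / len
    b <- colSums(u * (v[nb] - v[i])) / length(nb)
    if (method == "vectorsum") {
      g[i, ] <- if (normalizeDegree) b else b * length(nb)
    } else {
      M <- crossprod(u * sqrt(len)) / length(nb)  # mean |d| u u^T
      sv <- svd(M)
      pos <- sv$d > 0.05 * sv$d[1]
      g[i, ] <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
    }
  }
  full <- matrix(NaN, 4, ncol(ns))
  full[1:3, idx] <- t(g)
  full[4, idx] <- sqrt(rowSums(g^2))
  ns <- .set_channel_values(ns, channel, full[1, ], "grad_x")
  ns <- .set_channel_values(ns, channel, full[2, ], "grad_y")
  ns <- .set_channel_values(ns, channel, full[3, ], "grad_z")
  .set_channel_values(ns, channel, full[4, ], "steepness")
}

# niche = the nucleus together with its graph neighbors; returns the
# per-node mean and standard deviation (population by default: the niche
# is the whole population of interest, not a sample from one)
.niche_stats <- function(v, adj, sd_type = "population") {
  n <- length(v)
  mu <- numeric(n)
  sdv <- numeric(n)
  for (i in seq_len(n)) {
    niche <- c(v[i], v[adj[[i]]])
    mu[i] <- mean(niche)
    sdv[i] <- if (sd_type == "population") .pop_sd(niche)
              else stats::sd(niche)
  }
  list(mu = mu, sd = sdv)
}

#' Local coefficient of variation (CV)
#'
#' CV of the niche (a nucleus plus its neighbors): the standard deviation
#' of the niche's values divided by the niche mean, a scale-free measure
#' of local heterogeneity. Computed on unsmoothed NFI: smoothing would
#' average away exactly the heterogeneity being measured.
#'
#' @param ns a \linkS4class{NucleiSet} with an \code{"nfi"} assay.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param channel channel name.
#' @param sd_type \code{"population"} (divide by niche size, default) or
#'   \code{"sample"}.
#' @param assay input assay (default \code{"nfi"}).
#' @return the \code{NucleiSet} with a \code{"cv"} assay entry; NaN where
#'   the niche mean is not positive.
#' @export
localCV <- function(ns, graph, channel, sd_type = c("population",
                                                    "sample"),
                    assay = "nfi") {
  sd_type <- match.arg(sd_type)
  idx <- .graph_index(ns, graph)
  v <- .channel_values(ns, channel, assay)[idx]
  st <- .niche_stats(v, adjacencyList(graph), sd_type)
  cv <- ifelse(st$mu > 0, st$sd / st$mu, NaN)
  full <- rep(NaN, ncol(ns))
  full[idx] <- cv
  .set_channel_values(ns, channel, full, "cv")
}

#' Log neighbor ratio (NR)
#'
#' The natural log of a nucleus's value over the mean of its neighbors'
#' values. The log makes changes in the cell and in its neighborhood
#' contribute symmetrically (ln(x/y) = ln x - ln y), so a cell above its
#' neighborhood scores +r where a cell below an equally contrasting
#' neighborhood scores -r. A small floor keeps the ratio finite at zero
#' expression.
#'
#' @param ns a \linkS4class{NucleiSet} with an \code{"nfi"} assay.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param channel channel name.
#' @param floor added to numerator and denominator (default 1e-3 on the
#'   NFI scale).
#' @param assay input assay (default \code{"nfi"}).
#' @return the \code{NucleiSet} with an \code{"nr"} assay entry; NaN for
#'   isolated nuclei.
#' @export
neighborRatio <- function(ns, graph, channel, floor = 1e-3,
                          assay = "nfi") {
  stopifnot(floor > 0)
  idx <- .graph_index(ns, graph)
  v <- .channel_values(ns, channel, assay)[idx]
  adj <- adjacencyList(graph)
  nr <- vapply(seq_along(v), function(i) {
    if (length(adj[[i]]) == 0) return(NaN)
    log((v[i] + floor) / (mean(v[adj[[i]]]) + floor))
  }, numeric(1))
  full <- rep(NaN, ncol(ns))
  full[idx] <- nr
  .set_channel_values(ns, channel, full, "nr")
}

#' Synthetic-null neighbor ratio
#'
#' The random-pattern reference for NR: for each niche, values for the
#' cell and each of its neighbors are redrawn i.i.d. from a normal
#' distribution with the niche's observed mean and (population) standard
#' deviation, clipped at zero (NFI is nonnegative), and NR is recomputed
#' on the redrawn niche. Under a spatially random pattern the observed NR
#' distribution is indistinguishable from this null; lateral-inhibition
#' patterns shift away from it.
#'
#' @param ns a \linkS4class{NucleiSet} with an \code{"nfi"} assay.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param channel channel name.
#' @param seed integer; the draw is fully reproducible from it.
#' @param floor as in \code{\link{neighborRatio}}.
#' @param assay input assay (default \code{"nfi"}).
#' @return the \code{NucleiSet} with \code{"nr_synthetic"} (null NR) and
#'   \code{"synthetic"} (the redrawn cell values) assay entries.
#' @export
simulateNullNR <- function(ns, graph, channel, seed = 1, floor = 1e-3,
                           assay = "nfi") {
  idx <- .graph_index(ns, graph)
  v <- .channel_values(ns, channel, assay)[idx]
  adj <- adjacencyList(graph)
  st <- .niche_stats(v, adj)
  n <- length(v)
  nr_syn <- rep(NaN, n)
  cell_syn <- rep(NaN, n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(.derive_seed(seed, paste0("nullnr", channel)))
  for (i in seq_len(n)) {
    deg <- length(adj[[i]])
    if (deg == 0) next
    if (st$sd[i] == 0) {
      draws <- rep(st$mu[i], deg + 1)
    } else {
      draws <- pmax(0, stats::rnorm(deg + 1, st$mu[i], st$sd[i]))
    }
    cell_syn[i] <- draws[1]
    nr_syn[i] <- log((draws[1] + floor) / (mean(draws[-1]) + floor))
  }
  full <- rep(NaN, ncol(ns)); full[idx] <- nr_syn
  ns <- .set_channel_values(ns, channel, full, "nr_synthetic")
  full[idx] <- cell_syn
  .set_channel_values(ns, channel, full, "synthetic")
}

#' 1D earth mover's distance (Wasserstein-1)
#'
#' Dissimilarity between two empirical distributions: the integral of the
#' absolute difference of their CDFs. With \code{normalize = TRUE} the
#' two samples are first jointly min-max rescaled to [0, 1], making the
#' distance a scale-free fraction of the pooled range.
#'
#' @param a,b numeric samples (non-empty; each observation carries equal
#'   weight within its sample).
#' @param normalize jointly rescale to [0, 1] first (default FALSE).
#' @return nonnegative number.
#' @examples
#' emd1d(0.2, 0.7)  # 0.5
#' @export
emd1d <- function(a, b, normalize = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  if (normalize) {
    rng <- range(c(a, b))
    if (diff(rng) > 0) {
      a <- (a - rng[1]) / diff(rng)
      b <- (b - rng[1]) / diff(rng)
    } else return(0)
  }
  v <- c(a, b)
  w <- c(rep(1 / length(a), length(a)), rep(-1 / length(b), length(b)))
  o <- order(v)
  v <- v[o]
  cw <- cumsum(w[o])
  sum(abs(utils::head(cw, -1)) * diff(v))
}

#' Observed-vs-synthetic NR profile along an axis
#'
#' Bins nuclei into even intervals along an axis (pseudospace or relative
#' AP), restricted to a population (e.g., the upper half of the positive
#' cells), and summarizes observed and synthetic-null NR per bin with the
#' embryo as the experimental unit: per-embryo means, the across-embryo
#' mean with a 1.96 standard-error confidence band, the mean per-embryo
#' earth mover's distance between the observed and synthetic NR
#' distributions, and a one-way ANOVA p-value comparing observed and
#' synthetic embryo means.
#'
#' @param ns a \linkS4class{NucleiSet} with \code{"nr"} and
#'   \code{"nr_synthetic"} assays for \code{channel}.
#' @param channel channel name.
#' @param axis colData column to bin along (default
#'   \code{"pseudospace"}).
#' @param bins number of even intervals (default 10), or a vector of
#'   breaks.
#' @param population logical mask of nuclei to include (default: all
#'   with finite NR).
#' @return data.frame with one row per bin: bin center, number of
#'   embryos, observed and synthetic means, CI bounds, per-bin EMD, and
#'   ANOVA p (NA where fewer than 2 embryos are represented).
#' @export
nrProfile <- function(ns, channel, axis = "pseudospace", bins = 10,
                      population = NULL) {
  cd <- SummarizedExperiment::colData(ns)
  ax <- cd[[axis]]
  if (is.null(ax)) stop("colData column '", axis, "' not found")
  nr <- .channel_values(ns, channel, "nr")
  nrs <- .channel_values(ns, channel, "nr_synthetic")
  ok <- is.finite(ax) & is.finite(nr) & is.finite(nrs)
  if (!is.null(population)) ok <- ok & population
  brk <- if (length(bins) > 1) bins
         else seq(min(ax[ok]), max(ax[ok]), length.out = bins + 1)
  bi <- .bin_index(ax, brk)
  nb <- length(brk) - 1
  out <- data.frame(bin = seq_len(nb),
                    mid = utils::head(brk, -1) + diff(brk) / 2,
                    n_embryos = NA_integer_, obs_mean = NA_real_,
                    obs_lo = NA_real_, obs_hi = NA_real_,
                    syn_mean = NA_real_, syn_lo = NA_real_,
                    syn_hi = NA_real_, emd = NA_real_, p = NA_real_)
  for (b in seq_len(nb)) {
    sel <- ok & bi == b
    if (!any(sel)) next
    em <- cd$embryo_id[sel]
    obs <- tapply(nr[sel], em, mean)
    syn <- tapply(nrs[sel], em, mean)
    ne <- length(obs)
    out$n_embryos[b] <- ne
    if (ne < 2) next
    ci <- function(m) {
      mu <- mean(m); se <- stats::sd(m) / sqrt(length(m))
      c(mu, mu - 1.96 * se, mu + 1.96 * se)
    }
    out[b, c("obs_mean", "obs_lo", "obs_hi")] <- ci(obs)
    out[b, c("syn_mean", "syn_lo", "syn_hi")] <- ci(syn)
    out$emd[b] <- mean(vapply(unique(em), function(e)
      emd1d(nr[sel][em == e], nrs[sel][em == e]), numeric(1)))
    dat <- data.frame(y = c(obs, syn),
                      g = rep(c("obs", "syn"), c(ne, ne)))
    out$p[b] <- stats::anova(stats::aov(y ~ g, dat))$`Pr(>F)`[1]
  }
  out
}

#' Expression-domain boundary profile along the AP axis
#'
#' For a gated (positive/negative) expression domain, estimates per AP
#' bin the ventral boundary (position closest to the midline where
#' positives begin) and dorsal boundary (farthest extent), as the 5th and
#' 95th percentiles of the positive nuclei's \code{|lr|}; width = dorsal
#' - ventral. Left and right profiles are computed separately per embryo
#' and averaged, then summarized across embryos.
#'
#' @param ns a \linkS4class{NucleiSet} with unfolded projected
#'   coordinates.
#' @param positive logical per-nucleus gate.
#' @param side \code{"both"} (average left and right), \code{"left"} or
#'   \code{"right"}.
#' @param ap_breaks AP bin edges (on \code{axis}).
#' @param axis AP coordinate column (default \code{"ap_rel"}).
#' @param lr_column left-right coordinate column (default
#'   \code{"lr_um"}).
#' @param probs boundary percentiles (default \code{c(0.05, 0.95)}).
#' @return data.frame per bin: mean ventral, dorsal and width across
#'   embryos, their standard deviations, and the embryo count; NaN where
#'   a bin has no positive nuclei.
#' @export
boundaryProfile <- function(ns, positive, side = c("both", "left",
                                                   "right"),
                            ap_breaks, axis = "ap_rel",
                            lr_column = "lr_um",
                            probs = c(0.05, 0.95)) {
  side <- match.arg(side)
  cd <- SummarizedExperiment::colData(ns)
  ap <- cd[[axis]]
  lr <- cd[[lr_column]]
  nb <- length(ap_breaks) - 1
  bi <- .bin_index(ap, ap_breaks)
  per_embryo <- list()
  for (em in embryoIDs(ns)) {
    sides <- switch(side, both = c("left", "right"), side)
    prof <- matrix(NA_real_, nb, 3)
    cnt <- matrix(0, nb, 3)
    for (sd_ in sides) {
      s_sel <- if (sd_ == "left") lr < 0 else lr >= 0
      for (b in seq_len(nb)) {
        sel <- which(cd$embryo_id == em & positive & !is.na(lr) &
                       !is.na(ap) & bi == b & s_sel)
        if (length(sel) == 0) next
        q <- stats::quantile(abs(lr[sel]), probs, names = FALSE)
        vals <- c(q[1], q[2], q[2] - q[1])
        prof[b, ] <- ifelse(is.na(prof[b, ]), 0, prof[b, ]) + vals
        cnt[b, ] <- cnt[b, ] + 1
      }
    }
    prof <- prof / ifelse(cnt == 0, NA, cnt)
    per_embryo[[em]] <- prof
  }
  arr <- simplify2array(per_embryo)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  mean_na <- function(v) if (all(is.na(v))) NaN else mean(v, na.rm = TRUE)
  sd_na <- function(v) if (sum(!is.na(v)) < 2) NA_real_
          else stats::sd(v, na.rm = TRUE)
  data.frame(
    bin = seq_len(nb),
    mid = utils::head(ap_breaks, -1) + diff(ap_breaks) / 2,
    ventral = apply(arr[, 1, , drop = FALSE], 1, mean_na),
    dorsal = apply(arr[, 2, , drop = FALSE], 1, mean_na),
    width = apply(arr[, 3, , drop = FALSE], 1, mean_na),
    ventral_sd = apply(arr[, 1, , drop = FALSE], 1, sd_na),
    dorsal_sd = apply(arr[, 2, , drop = FALSE], 1, sd_na),
    width_sd = apply(arr[, 3, , drop = FALSE], 1, sd_na),
    n_embryos = apply(arr[, 3, , drop = FALSE], 1,
                      function(v) sum(!is.na(v))))
}

#' Test for a non-random neighbor-ratio pattern
#'
#' Calibrated detection of lateral-inhibition-like arrangements: per
#' embryo, the earth mover's distance between the observed NR
#' distribution and one synthetic-null draw is compared with a reference
#' EMD between two further independent null draws (the null's own
#' sampling noise). A one-way ANOVA across embryos on the two EMD sets
#' gives the p-value: significant only when the observed pattern
#' deviates from the per-niche normal null by more than the null
#' fluctuates around itself. On spatially random normal fields the test
#' is calibrated (uniform p); on sequential-inhibition spot patterns it
#' detects the arrangement with high power.
#'
#' @param ns a \linkS4class{NucleiSet}.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param channel channel name.
#' @param seed integer seed for the three synthetic draws.
#' @param floor,assay passed to \code{\link{neighborRatio}} /
#'   \code{\link{simulateNullNR}}.
#' @param population optional logical mask restricting the compared
#'   cells.
#' @return list: \code{p} (ANOVA p across embryos), \code{shift} (mean
#'   observed-vs-null EMD minus mean null-vs-null EMD), \code{emd_obs}
#'   and \code{emd_null} (per-embryo values).
#' @export
nrShiftTest <- function(ns, graph, channel, seed = 1, floor = 1e-3,
                        assay = "nfi", population = NULL) {
  ns <- neighborRatio(ns, graph, channel, floor = floor, assay = assay)
  nr <- .channel_values(ns, channel, "nr")
  syn <- lapply(1:3, function(k) {
    n2 <- simulateNullNR(ns, graph, channel,
                         seed = .derive_seed(seed, paste0("draw", k)),
                         floor = floor, assay = assay)
    .channel_values(n2, channel, "nr_synthetic")
  })
  cd <- SummarizedExperiment::colData(ns)
  keep <- is.finite(nr)
  if (!is.null(population)) keep <- keep & population
  e_obs <- e_null <- c()
  for (em in embryoIDs(ns)) {
    sel <- keep & cd$embryo_id == em
    if (sum(sel) < 10) next
    e_obs <- c(e_obs, emd1d(nr[sel], syn[[1]][sel]))
    e_null <- c(e_null, emd1d(syn[[2]][sel], syn[[3]][sel]))
  }
  if (length(e_obs) < 2)
    return(list(p = NA_real_, shift = mean(e_obs) - mean(e_null),
                emd_obs = e_obs, emd_null = e_null))
  dat <- data.frame(y = c(e_obs, e_null),
                    g = rep(c("obs", "null"),
                            c(length(e_obs), length(e_null))))
  p <- stats::anova(stats::aov(y ~ g, dat))$`Pr(>F)`[1]
  list(p = p, shift = mean(e_obs) - mean(e_null), emd_obs = e_obs,
       emd_null = e_null)
}
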