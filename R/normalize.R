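#' @include NucleiSet-methods.R utils.R
NULL

# KDE mode of a vector: the background estimator ("highest peak in the
# signal histogram"), made binning-free via a Gaussian KDE with
# Silverman's bandwidth
.kde_mode <- function(v) {
  v <- v[is.finite(v)]
  if (length(unique(v)) == 1) return(v[1])
  d <- stats::density(v, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Linear bleed-through unmixing between two channels
#'
#' Subtracts \code{coefficient} times the source channel from the target
#' channel (clipped at zero), the standard correction for spectral
#' bleed-through between neighboring fluorophores. With
#' \code{coefficient = "auto"} the coefficient is estimated as the
#' Theil--Sen slope of target versus source over nuclei that are
#' source-positive and target-negative (Otsu gates on the raw values), the
#' population in which all apparent target signal is bleed-through.
#'
#' @param ns a \linkS4class{NucleiSet} with a \code{"raw"} assay.
#' @param source,target channel names.
#' @param coefficient nonnegative number, or \code{"auto"}.
#' @return the \code{NucleiSet} with the target channel's raw values
#'   replaced; the coefficient used is recorded in
#'   \code{metadata(ns)$unmix}.
#' @export
unmixBleedthrough <- function(ns, source, target, coefficient = "auto") {
  sv <- .channel_values(ns, source, "raw")
  tv <- .channel_values(ns, target, "raw")
  if (identical(coefficient, "auto")) {
    s_thr <- .otsu(sv)
    t_thr <- .otsu(tv)
    if (is.na(s_thr) || is.na(t_thr))
      stop("auto unmixing needs bimodal source/target histograms; ",
           "supply a manual coefficient")
    eligible <- is.finite(sv) & is.finite(tv) & sv >= s_thr & tv < t_thr
    if (sum(eligible) < 50)
      stop("auto unmixing needs >= 50 source-positive/target-negative ",
           "nuclei (", sum(eligible), " found); supply a manual ",
           "coefficient")
    coefficient <- max(0, .theil_sen(sv[eligible], tv[eligible]))
  }
  stopifnot(is.numeric(coefficient), coefficient >= 0)
  ns <- .set_channel_values(ns, target, pmax(0, tv - coefficient * sv),
                            "raw")
  md <- S4Vectors::metadata(ns)
  md$unmix <- c(md$unmix,
                stats::setNames(list(coefficient),
                                paste(source, target, sep = "->")))
  S4Vectors::metadata(ns) <- md
  ns
}

#' Correct depth-dependent attenuation of fluorescence
#'
#' Light scattering attenuates signal with imaging depth (z). Per embryo,
#' the background-subtracted intensity trend versus z is estimated on
#' binned robust (median) means and fitted as an exponential decay; the
#' fitted factor is divided out so that intensity becomes depth-free,
#' anchored so the mean intensity of the shallowest z-decile is
#' preserved. If the fitted trend is increasing (ill-conditioned for a
#' decay model), the correction falls back to per-z-bin quantile matching
#' against the shallowest bin, with a warning.
#'
#' @param ns a \linkS4class{NucleiSet}.
#' @param channel channel to correct.
#' @param nbins number of z bins for the trend fit (default 10).
#' @return the \code{NucleiSet} with corrected raw values for the
#'   channel.
#' @export
correctDepthAttenuation <- function(ns, channel, nbins = 10L) {
  cd <- SummarizedExperiment::colData(ns)
  v <- .channel_values(ns, channel, "raw")
  out <- v
  for (em in embryoIDs(ns)) {
    sel <- cd$embryo_id == em
    z <- cd$z[sel]
    vv <- v[sel]
    if (sum(sel) < 200 || diff(range(z)) < 20)
      stop("depth correction needs >= 200 nuclei spanning >= 20 um in z ",
           "(embryo ", em, ")")
    # additive dark offset (does not attenuate with depth), estimated as
    # a low percentile; the decaying part of the signal sits above it
    b <- stats::quantile(vv, 0.01, names = FALSE)
    brk <- seq(min(z), max(z), length.out = nbins + 1)
    bin <- .bin_index(z, brk)
    med <- tapply(vv, bin, stats::median)
    zmid <- tapply(z, bin, mean)
    eps <- 1e-12 * max(abs(vv), 1)
    lmed <- log(pmax(med - b, eps))
    fit <- stats::lm(lmed ~ zmid)
    k <- stats::coef(fit)[2]
    shallow <- z <= stats::quantile(z, 0.1)
    if (!is.finite(k) || k >= 1e-12) {
      # trend not a decay: per-z-bin quantile matching to the shallowest bin
      warning("depth trend for '", channel, "' (embryo ", em,
              ") is not a monotone decay; falling back to per-bin ",
              "quantile matching")
      ref <- vv[bin == min(bin)]
      corr <- vv
      for (bb in unique(bin)) {
        if (bb == min(bin)) next
        idx <- bin == bb
        r <- rank(vv[idx], ties.method = "average") / (sum(idx) + 1)
        corr[idx] <- stats::quantile(ref, r, names = FALSE, type = 7)
      }
      out[sel] <- corr
    } else {
      zref <- mean(z[shallow])
      factor_z <- exp(k * (z - zref))  # fitted attenuation, 1 at zref
      corr <- b + (vv - b) / factor_z
      # anchor: preserve the shallow-decile mean exactly
      mb <- mean(vv[shallow]); ma <- mean(corr[shallow])
      if (is.finite(ma) && abs(ma - b) > 1e-12)
        corr <- b + (corr - b) * (mb - b) / (ma - b)
      out[sel] <- pmax(corr, 0)
    }
  }
  .set_channel_values(ns, channel, out, "raw")
}

#' Compute normalized fluorescence intensity (NFI)
#'
#' Per embryo and channel, raw values are normalized as
#' \code{(signal - background) / (max_signal - background)}, where the
#' background is the highest peak of the signal histogram (KDE mode;
#' the background population dominates the image) and the maximum is the
#' 99th percentile (excluding hot pixels and staining artifacts), then
#' clipped to [0, 1].
#'
#' @param ns a \linkS4class{NucleiSet}; unmixing/depth correction should
#'   already have been applied if configured.
#' @param channels channels to normalize (default: all).
#' @return the \code{NucleiSet} with an \code{"nfi"} assay; the fitted
#'   background and max per embryo/channel are stored in
#'   \code{metadata(ns)$normalization}.
#' @export
computeNFI <- function(ns, channels = NULL) {
  if (is.null(channels)) channels <- rownames(ns)
  cd <- SummarizedExperiment::colData(ns)
  md <- S4Vectors::metadata(ns)
  if (is.null(md$normalization)) md$normalization <- list()
  for (ch in channels) {
    v <- .channel_values(ns, ch, "raw")
    nfi <- rep(NA_real_, length(v))
    for (em in embryoIDs(ns)) {
      sel <- cd$embryo_id == em
      vv <- v[sel]
      b <- .kde_mode(vv)
      mx <- stats::quantile(vv, 0.99, names = FALSE, na.rm = TRUE)
      if (!is.finite(mx) || mx <= b)
        stop("degenerate channel '", ch, "' in embryo ", em,
             ": 99th percentile (", signif(mx, 4),
             ") does not exceed background (", signif(b, 4), ")")
      nfi[sel] <- pmin(1, pmax(0, (vv - b) / (mx - b)))
      md$normalization[[em]][[ch]] <- list(background = b, max_signal = mx)
    }
    ns <- .set_channel_values(ns, ch, nfi, "nfi")
  }
  S4Vectors::metadata(ns) <- md
  ns
}

#' Gate nuclei as positive or negative for a channel
#'
#' A nucleus is positive when its NFI is greater than or equal to the
#' threshold (inclusive boundary). With \code{threshold = "otsu"} the
#' threshold is computed from the NFI histogram; with
#' \code{pooled = TRUE} (default) one threshold is computed over all
#' embryos combined, the reproducible analogue of manual gating over
#' pooled replicates.
#'
#' @param ns a \linkS4class{NucleiSet} with NFI computed.
#' @param channel channel name.
#' @param threshold number in [0, 1], or \code{"otsu"}.
#' @param pooled pool embryos when computing an automatic threshold.
#' @return named logical vector (one element per nucleus).
#' @export
gatePositive <- function(ns, channel, threshold = "otsu", pooled = TRUE) {
  v <- .channel_values(ns, channel, "nfi")
  if (identical(threshold, "otsu")) {
    if (pooled) {
      thr <- .otsu(v)
      if (is.na(thr)) {
        warning("degenerate NFI distribution for '", channel,
                "'; gating everything negative")
        return(stats::setNames(rep(FALSE, length(v)), colnames(ns)))
      }
      pos <- v >= thr
    } else {
      cd <- SummarizedExperiment::colData(ns)
      pos <- rep(FALSE, length(v))
      for (em in embryoIDs(ns)) {
        sel <- cd$embryo_id == em
        thr <- .otsu(v[sel])
        pos[sel] <- if (is.na(thr)) FALSE else v[sel] >= thr
      }
    }
  } else {
    stopifnot(is.numeric(threshold))
    if (threshold < 0 || threshold > 1)
      stop("threshold must lie in [0, 1]")
    pos <- v >= threshold
  }
  stats::setNames(as.logical(pos), colnames(ns))
}
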