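#' @include NucleiSet-methods.R
NULL

#' Shared k-means spatial bins
#'
#' Partitions the folded, aligned map into compact regions of
#' approximately \code{target_size} cells by k-means on
#' (ap_rel, lr_scaled), pooled over all embryos and conditions so every
#' condition shares the same regions. k = round(N / target_size), with a
#' fixed seed and 10 restarts (best inertia kept), so assignments are
#' deterministic given the seed.
#'
#' @param ns a \linkS4class{NucleiSet} with folded aligned coordinates.
#' @param target_size intended cells per bin (default 100).
#' @param seed RNG seed for the restarts.
#' @param coords coordinate columns (default
#'   \code{c("ap_rel", "lr_scaled")}).
#' @return a \linkS4class{BinPartition}.
#' @export
kmeansBins <- function(ns, target_size = 100L, seed = 1,
                       coords = c("ap_rel", "lr_scaled")) {
  cd <- SummarizedExperiment::colData(ns)
  m <- cbind(cd[[coords[1]]], cd[[coords[2]]])
  ok <- rowSums(!is.finite(m)) == 0
  pts <- m[ok, , drop = FALSE]
  n <- nrow(pts)
  if (n == 0) stop("no nuclei with finite coordinates")
  k <- max(1L, as.integer(round(n / target_size)))
  if (n < target_size) {
    warning("fewer nuclei (", n, ") than target_size; using one bin")
    k <- 1L
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(.derive_seed(seed, "kmeansbins"))
  # normalize axis ranges so bins are compact in both map directions
  # (ap_rel is unitless, lr_scaled is in micrometers)
  rng <- apply(pts, 2, function(v) max(diff(range(v)), 1e-9))
  km <- stats::kmeans(sweep(pts, 2, rng, "/"), centers = k,
                      nstart = 10, iter.max = 100)
  centers <- sweep(km$centers, 2, rng, "*")
  methods::new("BinPartition", k = k,
               assignment = stats::setNames(km$cluster,
                                            colnames(ns)[ok]),
               centers = centers, stats = data.frame())
}

setMethod("show", "BinPartition", function(object) {
  cat("BinPartition:", object@k, "bins over",
      length(object@assignment), "nuclei\n")
  if (nrow(object@stats) > 0)
    cat("tested bins:", sum(!is.na(object@stats$p)), "\n")
  invisible(NULL)
})

#' Per-bin condition comparison
#'
#' For each spatial bin, the metric is first averaged per embryo (the
#' embryo, not the nucleus, is the experimental unit --- per-nucleus
#' testing would be pseudoreplication) and a one-way ANOVA across
#' conditions is run on the embryo means. p-values are
#' Benjamini--Hochberg adjusted across the testable bins; the effect is
#' the difference of condition means (second minus first, in sorted
#' condition order).
#'
#' @param partition a \linkS4class{BinPartition}.
#' @param ns the \linkS4class{NucleiSet} the partition was built from.
#' @param values named numeric per-nucleus metric (names = nucleus
#'   keys), e.g. one row of an assay.
#' @param min_embryos minimum embryos per condition for a bin to be
#'   tested (default 2).
#' @return the partition with a \code{stats} table: bin id, centroid,
#'   per-condition embryo counts, effect, p, q.
#' @export
binConditionTest <- function(partition, ns, values, min_embryos = 2L) {
  cd <- SummarizedExperiment::colData(ns)
  keys <- names(partition@assignment)
  idx <- match(keys, colnames(ns))
  df <- data.frame(bin = partition@assignment,
                   embryo = cd$embryo_id[idx],
                   condition = cd$condition[idx],
                   value = as.numeric(values[keys]))
  conds <- sort(unique(df$condition))
  res <- data.frame(bin_id = seq_len(partition@k),
                    centroid_ap = partition@centers[, 1],
                    centroid_lr = partition@centers[, 2],
                    n_embryos_min = NA_integer_, effect = NA_real_,
                    p = NA_real_, q = NA_real_)
  for (b in seq_len(partition@k)) {
    sub <- df[df$bin == b & is.finite(df$value), ]
    if (nrow(sub) == 0) next
    em <- stats::aggregate(value ~ embryo + condition, sub, mean)
    tab <- table(em$condition)
    res$n_embryos_min[b] <- if (length(tab) == 0) 0L else min(tab)
    if (length(conds) < 2 || !all(conds %in% names(tab)) ||
        min(tab) < min_embryos) next
    fit <- stats::aov(value ~ condition, em)
    res$p[b] <- stats::anova(fit)$`Pr(>F)`[1]
    if (length(conds) >= 2) {
      m <- tapply(em$value, em$condition, mean)
      res$effect[b] <- m[conds[2]] - m[conds[1]]
    }
  }
  tested <- !is.na(res$p)
  res$q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  partition@stats <- res
  partition
}

#' Per-embryo (superplot) summary statistics
#'
#' Summarizes a per-nucleus metric by embryo means per channel within a
#' population, reports the across-embryo mean with its 1.96-standard-
#' error confidence interval, and runs pairwise paired t-tests across
#' channels within embryos with Benjamini--Hochberg adjustment. Tests
#' are suppressed (NA) below 3 embryos. When the paired differences are
#' exactly constant the t statistic degenerates; that case is reported
#' as p = 1 for zero difference and p = 0 with a \code{degenerate} flag
#' otherwise.
#'
#' @param ns a \linkS4class{NucleiSet}.
#' @param channels channels to compare.
#' @param assay assay holding the metric (default \code{"cv"}).
#' @param population optional logical mask of nuclei to include (e.g.,
#'   an ROI membership).
#' @param paired pair tests within embryos (default TRUE; unpaired
#'   otherwise).
#' @return list with \code{embryo_means} (long table), \code{summary}
#'   (per channel: mean, ci_lo, ci_hi, n), and \code{tests} (pairwise:
#'   channel_a, channel_b, p, q, degenerate).
#' @export
superplotStats <- function(ns, channels, assay = "cv",
                           population = NULL, paired = TRUE) {
  cd <- SummarizedExperiment::colData(ns)
  keep <- if (is.null(population)) rep(TRUE, ncol(ns)) else population
  long <- do.call(rbind, lapply(channels, function(ch) {
    v <- .channel_values(ns, ch, assay)
    ok <- keep & is.finite(v)
    data.frame(channel = ch, embryo = cd$embryo_id[ok], value = v[ok])
  }))
  em <- stats::aggregate(value ~ channel + embryo, long, mean)
  summ <- do.call(rbind, lapply(channels, function(ch) {
    v <- em$value[em$channel == ch]
    n <- length(v)
    se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(channel = ch, mean = mean(v), ci_lo = mean(v) - 1.96 * se,
               ci_hi = mean(v) + 1.96 * se, n = n)
  }))
  pairs <- utils::combn(channels, 2)
  tests <- data.frame(channel_a = pairs[1, ], channel_b = pairs[2, ],
                      p = NA_real_, q = NA_real_, degenerate = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- em[em$channel == pairs[1, i], c("embryo", "value")]
    b <- em[em$channel == pairs[2, i], c("embryo", "value")]
    if (paired) {
      mg <- merge(a, b, by = "embryo")
      if (nrow(mg) < 3) next
      d <- mg$value.x - mg$value.y
      if (stats::sd(d) < 1e-15) {
        tests$degenerate[i] <- TRUE
        tests$p[i] <- if (abs(mean(d)) < 1e-15) 1 else 0
      } else {
        tests$p[i] <- stats::t.test(mg$value.x, mg$value.y,
                                    paired = TRUE)$p.value
      }
    } else {
      if (nrow(a) < 3 || nrow(b) < 3) next
      tests$p[i] <- stats::t.test(a$value, b$value)$p.value
    }
  }
  done <- !is.na(tests$p)
  tests$q[done] <- stats::p.adjust(tests$p[done], method = "BH")
  list(embryo_means = em, summary = summ, tests = tests)
}
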