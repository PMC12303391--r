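#' @include NucleiSet-methods.R
NULL

# colData columns with fixed roles; anything else in a CSV is either a
# channel (numeric, unprefixed) or preserved metadata
.known_meta_cols <- c("nucleus_id", "id", "embryo_id", "condition", "stage",
                      "x", "y", "z", "tissue", "is_node", "is_ps_tip",
                      "ap_um", "lr_um", "dv_um", "ap_rel", "lr_rel",
                      "lr_scaled", "folded", "side", "pseudospace",
                      "in_roi", "in_graph", "bin_id")

.assay_prefixes <- c(raw = "raw_", nfi = "nfi_", smooth = "smooth_",
                     cv = "cv_", nr = "nr_", nr_synthetic = "nrsyn_",
                     steepness = "steep_", grad_x = "gradx_",
                     grad_y = "grady_", grad_z = "gradz_",
                     raw_ring = "ring_")

#' Read a nuclei table from delimited text
#'
#' Reads a per-nucleus CSV (one row per nucleus) with columns
#' \code{id} (or \code{nucleus_id}), \code{x}, \code{y}, \code{z}, one
#' column per channel, and optional metadata columns (\code{embryo_id},
#' \code{condition}, \code{stage}, \code{tissue}, landmark flags).
#' Columns written by \code{\link{writeNucleiTable}} with assay prefixes
#' (\code{raw_}, \code{nfi_}, \code{smooth_}, ...) are restored into the
#' corresponding assays, so read/write round-trips are lossless.
#'
#' @param path CSV file path.
#' @param channels channel column names; \code{NULL} = infer (prefixed
#'   \code{raw_} columns if present, otherwise unrecognized numeric
#'   columns).
#' @param voxel_size length-3 micrometers per voxel in (depth, row, col) =
#'   (z, y, x) order; used only when \code{unit = "voxel"}.
#' @param unit \code{"um"} (default) or \code{"voxel"}; voxel coordinates
#'   are converted to micrometers with \code{voxel_size}.
#' @return a \linkS4class{NucleiSet}.
#' @export
readNucleiTable <- function(path, channels = NULL, voxel_size = NULL,
                            unit = c("um", "voxel")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  idcol <- if ("nucleus_id" %in% names(df)) "nucleus_id" else "id"
  for (col in c(idcol, "x", "y", "z"))
    if (!col %in% names(df))
      stop("schema error: missing mandatory column '", col, "'")
  rawpref <- grep("^raw_", names(df), value = TRUE)
  if (is.null(channels)) {
    if (length(rawpref) > 0) {
      channels <- sub("^raw_", "", rawpref)
    } else {
      cand <- setdiff(names(df), .known_meta_cols)
      cand <- cand[!grepl(paste0("^(",
        paste(sub("_$", "_", unname(.assay_prefixes)), collapse = "|"),
        ")"), cand)]
      channels <- cand[vapply(df[cand], is.numeric, logical(1))]
    }
  }
  if (length(channels) == 0)
    stop("schema error: no channel columns found")
  chan_cols <- ifelse(paste0("raw_", channels) %in% names(df),
                      paste0("raw_", channels), channels)
  for (i in seq_along(channels))
    if (!chan_cols[i] %in% names(df))
      stop("schema error: missing channel column '", channels[i], "'")
  embryo <- if ("embryo_id" %in% names(df)) df$embryo_id else "embryo1"
  if (anyDuplicated(paste(embryo, df[[idcol]])))
    stop("integrity error: duplicate nucleus_id within embryo")
  xyz <- cbind(df$x, df$y, df$z)
  if (unit == "voxel") {
    if (is.null(voxel_size))
      stop("voxel_size is required when unit = 'voxel'")
    xyz <- cbind(xyz[, 1] * voxel_size[3], xyz[, 2] * voxel_size[2],
                 xyz[, 3] * voxel_size[1])
  }
  raw <- t(as.matrix(df[chan_cols]))
  rownames(raw) <- channels
  extra <- df[setdiff(names(df),
                      c(idcol, "x", "y", "z", chan_cols,
                        unlist(lapply(unname(.assay_prefixes),
                                      function(p)
                                        grep(paste0("^", p), names(df),
                                             value = TRUE)))))]
  ns <- NucleiSet(
    raw = raw, centroids = xyz,
    nucleus_id = df[[idcol]],
    embryo_id = embryo,
    condition = if ("condition" %in% names(df)) df$condition else "none",
    stage = if ("stage" %in% names(df)) df$stage else "NA",
    tissue = if ("tissue" %in% names(df)) df$tissue else "epiblast",
    is_node = if ("is_node" %in% names(df))
      as.logical(df$is_node) else FALSE,
    is_ps_tip = if ("is_ps_tip" %in% names(df))
      as.logical(df$is_ps_tip) else FALSE,
    colData = if (ncol(extra) > 0) extra else NULL)
  # restore any further assays written by writeNucleiTable
  for (an in setdiff(names(.assay_prefixes), "raw")) {
    pref <- .assay_prefixes[[an]]
    cols <- paste0(pref, channels)
    if (all(cols %in% names(df))) {
      m <- t(as.matrix(df[cols]))
      rownames(m) <- channels
      colnames(m) <- colnames(ns)
      SummarizedExperiment::assay(ns, an, withDimnames = FALSE) <- m
    }
  }
  methods::validObject(ns)
  ns
}

#' Write a nuclei table to CSV
#'
#' Writes one row per nucleus: identifiers, centroid, metadata, then one
#' column per assay per channel with the assay prefix (\code{raw_TBXT},
#' \code{nfi_TBXT}, ...). Numbers are written with 17 significant digits
#' so that \code{readNucleiTable(writeNucleiTable(ns))} reproduces every
#' double exactly; missing values are empty cells and NaN is literal.
#'
#' @param ns a \linkS4class{NucleiSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNucleiTable <- function(ns, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(ns))
  out <- cd
  for (an in SummarizedExperiment::assayNames(ns)) {
    pref <- if (an %in% names(.assay_prefixes))
      .assay_prefixes[[an]] else paste0(an, "_")
    a <- SummarizedExperiment::assay(ns, an)
    for (ch in rownames(a)) out[[paste0(pref, ch)]] <- a[ch, ]
  }
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) {
      s <- vapply(v, function(x) {
        if (is.na(x) && !is.nan(x)) "" else sprintf("%.17g", x)
      }, character(1))
      s
    } else {
      s <- as.character(v)
      s[is.na(s)] <- ""
      s
    }
  }
  chr <- vapply(out, fmt, character(nrow(out)))
  if (nrow(out) == 1) chr <- matrix(chr, nrow = 1,
                                    dimnames = list(NULL, names(out)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(colnames(chr), collapse = ","), con)
  writeLines(apply(chr, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a 3D image stack from TIFF
#'
#' Reads a multi-page TIFF (one page per z-plane) into a 3D array in
#' (depth, row, col) order, the layout \code{\link{quantifyFromLabels}}
#' expects. Label images are rounded to integers when
#' \code{integer = TRUE}.
#'
#' @param path TIFF file.
#' @param integer coerce to an integer label array.
#' @return 3D array (z, y, x).
#' @export
readImageStack <- function(path, integer = FALSE) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = integer)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3)
    p[, , 1] else p)  # first sample of multi-sample pages
  arr <- array(0, c(length(pages), nrow(pages[[1]]),
                    ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (integer) {
    storage.mode(arr) <- "integer"
  }
  arr
}
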