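#' @include io.R normalize.R neighbors.R pringle.R metrics.R pseudospace.R
#' @include compare.R synthgen.R
NULL

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable parameter at
#' its package default; amend and pass to \code{\link{runPipeline}}, or
#' serialize to YAML for the command-line interface.
#'
#' @param out_dir output directory.
#' @return a named list.
#' @export
defaultConfig <- function(out_dir = "pringle_out") {
  list(
    out_dir = out_dir,
    seed = 1,
    input = NULL,                      # nuclei CSV; NULL = simulate
    simulate = list(n_embryos = 2, conditions = "none",
                    n_nuclei = 1200),
    channels = NULL,                   # NULL = all channels in the table
    normalize = list(unmix = NULL,     # list of (source, target, c)
                     depth_correct = NULL),
    graph = list(tissue = "epiblast", prune_factor = 2.5,
                 monolayer = FALSE),
    smooth = list(iterations = 10),
    pringle = list(slab_width = NULL, midline_channel = "TBXT",
                   span_ap = 0.7, span_lr = 0.2),
    pseudospace = list(channels = NULL, anchor = NULL,
                       pseudocount = 0.01),
    metrics = list(channels = NULL, floor = 1e-3),
    compare = list(target_size = 100, channel = NULL, assay = "nfi"))
}

#' Read a YAML pipeline configuration
#'
#' Missing keys fall back to \code{\link{defaultConfig}} values.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  for (nm in names(usr)) {
    if (is.list(cfg[[nm]]) && is.list(usr[[nm]])) {
      for (k in names(usr[[nm]])) cfg[[nm]][[k]] <- usr[[nm]][[k]]
    } else cfg[[nm]] <- usr[[nm]]
  }
  cfg
}

.stage_file <- function(cfg, stage)
  file.path(cfg$out_dir, paste0("nuclei_", stage, ".csv"))

.log_line <- function(cfg, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  cat(msg, "\n", sep = "", file = file.path(cfg$out_dir, "pipeline.log"),
      append = TRUE)
  message(msg)
}

.dependency_error <- function(stage, needs) {
  stop("dependency error: stage '", stage, "' needs the output of '",
       needs, "'; run that stage first", call. = FALSE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the full workflow on a nuclei table (or a simulated
#' embryo set): normalization, neighbor graph + smoothing, PRINGLE
#' projection/alignment, pseudospace, neighborhood metrics, and the
#' binned condition comparison. Each stage writes its table into
#' \code{cfg$out_dir} and is skipped on re-runs when its output already
#' exists (unless \code{force}). The resolved configuration is always
#' written alongside the outputs.
#'
#' @param cfg configuration list (\code{\link{defaultConfig}} /
#'   \code{\link{readConfig}}).
#' @param stages subset of \code{c("simulate", "normalize", "graph",
#'   "pringle", "pseudospace", "metrics", "compare")} (default: all
#'   applicable).
#' @param force recompute even when outputs exist.
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(cfg, stages = c("simulate", "normalize",
                                        "graph", "pringle",
                                        "pseudospace", "metrics",
                                        "compare"),
                        force = FALSE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  stages <- match.arg(stages, several.ok = TRUE)

  load_stage <- function(stage)
    readNucleiTable(.stage_file(cfg, stage), channels = cfg$channels)

  if ("simulate" %in% stages && is.null(cfg$input)) {
    f <- .stage_file(cfg, "input")
    if (force || !file.exists(f)) {
      sims <- list()
      conds <- cfg$simulate$conditions
      for (ci in seq_along(conds)) {
        for (e in seq_len(cfg$simulate$n_embryos)) {
          spec <- syntheticSpec(
            n_nuclei = cfg$simulate$n_nuclei,
            embryo_id = sprintf("%s_e%d", conds[ci], e),
            condition = conds[ci],
            seed = .derive_seed(cfg$seed, sprintf("sim%d_%d", ci, e)))
          sims[[length(sims) + 1]] <- generateEmbryo(spec)
        }
      }
      writeNucleiTable(combineNucleiSets(sims), f)
      .log_line(cfg, "simulate: ", length(sims), " embryos -> ", f)
    } else .log_line(cfg, "simulate: up to date")
  } else if (!is.null(cfg$input)) {
    file.copy(cfg$input, .stage_file(cfg, "input"), overwrite = TRUE)
  }

  if ("normalize" %in% stages) {
    f <- .stage_file(cfg, "normalize")
    if (force || !file.exists(f)) {
      if (!file.exists(.stage_file(cfg, "input")))
        .dependency_error("normalize", "simulate/input")
      ns <- load_stage("input")
      for (um in cfg$normalize$unmix)
        ns <- unmixBleedthrough(ns, um$source, um$target,
                                if (is.null(um$c)) "auto" else um$c)
      for (ch in cfg$normalize$depth_correct)
        ns <- correctDepthAttenuation(ns, ch)
      ns <- computeNFI(ns, cfg$channels)
      writeNucleiTable(ns, f)
      .log_line(cfg, "normalize: ", ncol(ns), " nuclei -> ", f)
    } else .log_line(cfg, "normalize: up to date")
  }

  build_graph <- function(ns)
    buildNeighborGraph(ns, tissue = cfg$graph$tissue,
                       pruneFactor = cfg$graph$prune_factor,
                       monolayer = isTRUE(cfg$graph$monolayer))

  if ("graph" %in% stages) {
    f <- .stage_file(cfg, "graph")
    if (force || !file.exists(f)) {
      if (!file.exists(.stage_file(cfg, "normalize")))
        .dependency_error("graph", "normalize")
      ns <- load_stage("normalize")
      g <- build_graph(ns)
      writeEdgeList(g, file.path(cfg$out_dir, "edges.csv"))
      ns <- smoothIntensities(ns, g, iterations =
                                cfg$smooth$iterations)
      writeNucleiTable(ns, f)
      .log_line(cfg, "graph: ", numEdges(g), " edges -> ", f)
    } else .log_line(cfg, "graph: up to date")
  }

  if ("pringle" %in% stages) {
    f <- .stage_file(cfg, "pringle")
    if (force || !file.exists(f)) {
      if (!file.exists(.stage_file(cfg, "graph")))
        .dependency_error("pringle", "graph")
      ns <- load_stage("graph")
      ns <- pringleProject(ns, tissue = cfg$graph$tissue,
                           slab_width_um = cfg$pringle$slab_width,
                           span_ap = cfg$pringle$span_ap,
                           span_lr = cfg$pringle$span_lr)
      ns <- detectMidline(ns, channel = cfg$pringle$midline_channel)
      ns <- normalizeAlign(ns)
      writeNucleiTable(ns, f)
      .log_line(cfg, "pringle: aligned -> ", f)
    } else .log_line(cfg, "pringle: up to date")
  }

  if ("pseudospace" %in% stages) {
    f <- .stage_file(cfg, "pseudospace")
    if (force || !file.exists(f)) {
      if (!file.exists(.stage_file(cfg, "pringle")))
        .dependency_error("pseudospace", "pringle")
      ns <- load_stage("pringle")
      chs <- cfg$pseudospace$channels
      if (is.null(chs)) chs <- rownames(ns)
      anchor <- cfg$pseudospace$anchor
      if (is.null(anchor)) anchor <- chs[1]
      fit <- fitPseudospace(ns, channels = chs,
                            pseudocount = cfg$pseudospace$pseudocount,
                            anchor = anchor)
      writeNucleiTable(fit$ns, f)
      .log_line(cfg, "pseudospace: fitted -> ", f)
    } else .log_line(cfg, "pseudospace: up to date")
  }

  if ("metrics" %in% stages) {
    f <- .stage_file(cfg, "metrics")
    if (force || !file.exists(f)) {
      if (!file.exists(.stage_file(cfg, "pseudospace")))
        .dependency_error("metrics", "pseudospace")
      ns <- load_stage("pseudospace")
      g <- build_graph(ns)
      chs <- cfg$metrics$channels
      if (is.null(chs)) chs <- rownames(ns)
      for (ch in chs) {
        ns <- gradientField(ns, g, ch)
        ns <- localCV(ns, g, ch)
        ns <- neighborRatio(ns, g, ch, floor = cfg$metrics$floor)
        ns <- simulateNullNR(ns, g, ch, seed = cfg$seed,
                             floor = cfg$metrics$floor)
        prof <- nrProfile(ns, ch, axis = "pseudospace")
        utils::write.csv(prof,
                         file.path(cfg$out_dir,
                                   paste0("nr_profile_", ch, ".csv")),
                         row.names = FALSE)
      }
      writeNucleiTable(ns, f)
      .log_line(cfg, "metrics: ", paste(chs, collapse = ","), " -> ", f)
    } else .log_line(cfg, "metrics: up to date")
  }

  if ("compare" %in% stages) {
    f <- file.path(cfg$out_dir, "bin_tests.csv")
    if (force || !file.exists(f)) {
      if (!file.exists(.stage_file(cfg, "metrics")))
        .dependency_error("compare", "metrics")
      ns <- load_stage("metrics")
      ns <- foldAtMidline(ns)
      part <- kmeansBins(ns, target_size = cfg$compare$target_size,
                         seed = cfg$seed)
      ch <- cfg$compare$channel
      if (is.null(ch)) ch <- rownames(ns)[1]
      vals <- stats::setNames(
        .channel_values(ns, ch, cfg$compare$assay), colnames(ns))
      part <- binConditionTest(part, ns, vals)
      utils::write.csv(part@stats, f, row.names = FALSE)
      .log_line(cfg, "compare: ", part@k, " bins -> ", f)
    } else .log_line(cfg, "compare: up to date")
  }

  invisible(cfg$out_dir)
}
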