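#' Run a pipeline stage from a configuration
#'
#' Reproducible entry point tying the stages together; the thin
#' command-line script shipped in `inst/cli/isletrace.R` calls straight
#' into this function. Each subcommand reads its inputs, writes CSV
#' outputs into `out_dir`, and drops a JSON manifest recording the full
#' configuration, the seed, the package version and MD5 checksums of
#' every input and output file -- identical config and seed therefore
#' reproduce byte-identical tables and an identical manifest.
#'
#' Subcommands and their config fields (defaults in parentheses):
#' \describe{
#'   \item{simulate}{`seed`; optional `growth`, `recomb`, `noise` lists
#'     overriding [growthConfig()], [recombinationConfig()],
#'     [noiseConfig()] arguments; optional `islet_id`, `render` (FALSE),
#'     `voxel_size` (1). Writes `cells.csv`, `truth.csv`, `traces.csv`,
#'     `protocol.json` and, when rendering, per-channel TIFFs.}
#'   \item{clones}{`cells` path; `tost` list (`margin_pct` 10, `alpha`
#'     0.05, `bonferroni` FALSE); optional `truth` path for clone-recovery
#'     scoring (adjusted Rand index, reported in the manifest). Writes
#'     `clone_table.csv` and `clone_summary.csv`.}
#'   \item{volumes}{`stack` path (all-channel composite), optional
#'     `stack_gb` (green+blue composite for single-cell volumes);
#'     `voxel_size` (1), `threshold` ("otsu"), `connectivity` (26),
#'     `single_cell_window` (c(50, 500)). Writes `objects.csv` and
#'     `volume_summary.csv`.}
#'   \item{calcium}{`traces` and `protocol` paths; `k_sd_qc` (3),
#'     `k_sd_responder` (3), `dwell` (0.1); optional `regions` path
#'     (cell_id, islet_id, region\[, stage\]) to add regional statistics.
#'     Writes `calcium_calls.csv` and optionally `regional_summary.csv`.}
#'   \item{spatial}{`cells` path; optional `anterior_tip`,
#'     `posterior_tip` (estimated when absent). Writes
#'     `ap_assignment.csv` and `ap_summary.csv`.}
#' }
#'
#' @param config named list (see [readRunConfig()]) or path to a
#'   YAML/JSON config file. Must contain `seed`.
#' @param subcommand one of `"simulate"`, `"clones"`, `"volumes"`,
#'   `"calcium"`, `"spatial"`.
#' @param outDir output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, subcommand = c("simulate", "clones",
                                               "volumes", "calcium",
                                               "spatial"),
                        outDir = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must contain a seed", call. = FALSE)
  outDir <- outDir %||% config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  inputs <- character()
  outputs <- character()
  extra <- list()

  if (subcommand == "simulate") {
    growth <- do.call(growthConfig, config$growth %||% list())
    recomb <- do.call(recombinationConfig, config$recomb %||% list())
    noise <- do.call(noiseConfig, config$noise %||% list())
    isl <- simulateIslet(growth, recomb, noise, seed = config$seed,
                         isletId = config$islet_id %||% "islet_1")
    protocol <- glucoseRampProtocol()
    ca <- simulateCalciumTraces(isl$truth, protocol,
                                seed = config$seed + 1L)
    outputs <- c(writeCellTable(isl$cells, file.path(outDir, "cells.csv")),
                 writeTruthTable(ca$truth, file.path(outDir, "truth.csv")),
                 writeTraceTable(ca$traces, file.path(outDir, "traces.csv")),
                 writeProtocol(protocol, file.path(outDir, "protocol.json")))
    if (isTRUE(config$render)) {
      st <- renderStack(isl$truth, voxelSize = config$voxel_size %||% 1,
                        seed = config$seed + 2L)
      for (ch in names(st$channels))
        outputs <- c(outputs,
                     writeStack(st$channels[[ch]],
                                file.path(outDir,
                                          sprintf("stack_%s.tif", ch))))
      outputs <- c(outputs, writeStack(st$composite,
                                       file.path(outDir,
                                                 "stack_composite.tif")))
    }
    extra$n_cells <- nrow(isl$cells)
  } else if (subcommand == "clones") {
    inputs <- config$cells
    cells <- readCellTable(config$cells)
    tp <- config$tost %||% list()
    params <- tostParams(marginPct = tp$margin_pct %||% 10,
                         alpha = tp$alpha %||% 0.05,
                         bonferroni = isTRUE(tp$bonferroni))
    byIslet <- lapply(split(cells, cells$islet_id), clusterClones,
                      params = params)
    cloneTab <- do.call(rbind, lapply(byIslet, function(cs) {
      if (nClones(cs) == 0L) return(NULL)
      data.frame(islet_id = cs@isletId,
                 clone_id = rep(names(clones(cs)), cloneSizes(cs)),
                 cell_id = unlist(clones(cs), use.names = FALSE),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cloneTab))
      cloneTab <- data.frame(islet_id = character(),
                             clone_id = character(),
                             cell_id = character())
    summaryTab <- do.call(rbind, lapply(byIslet, function(cs) {
      if (nClones(cs) == 0L) return(NULL)
      s <- clonalitySummary(cs)
      data.frame(islet_id = cs@isletId, n_clones = s$n_clones,
                 n_single = s$n_single, n_multi = s$n_multi,
                 pct_single = round(s$pct_single, 1L),
                 pct_multi = round(s$pct_multi, 1L),
                 margin_pct = params@marginPct, alpha = params@alpha,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(summaryTab))
      summaryTab <- data.frame(islet_id = character())
    utils::write.csv(cloneTab, file.path(outDir, "clone_table.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(summaryTab, file.path(outDir, "clone_summary.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    outputs <- file.path(outDir, c("clone_table.csv", "clone_summary.csv"))
    if (!is.null(config$truth) &&
        requireNamespace("mclust", quietly = TRUE)) {
      truth <- readTruthTable(config$truth)
      m <- merge(cloneTab, truth[, c("cell_id", "clone_id")],
                 by = "cell_id", suffixes = c("_called", "_true"))
      if (nrow(m))
        extra$clone_recovery_ari <-
          mclust::adjustedRandIndex(m$clone_id_called, m$clone_id_true)
      inputs <- c(inputs, config$truth)
    }
    extra$margin_pct <- params@marginPct
    extra$alpha <- params@alpha
  } else if (subcommand == "volumes") {
    inputs <- config$stack
    stack <- readStack(config$stack)
    objs <- labelObjects3d(stack, threshold = config$threshold %||% "otsu",
                           voxelSize = config$voxel_size %||% 1,
                           connectivity = config$connectivity %||% 26)
    utils::write.csv(objs, file.path(outDir, "objects.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    outputs <- file.path(outDir, "objects.csv")
    total <- totalBetaVolume(objs)
    summ <- data.frame(total_volume_um3 = total,
                       n_objects = nrow(objs),
                       threshold = attr(objs, "threshold"))
    if (!is.null(config$stack_gb)) {
      inputs <- c(inputs, config$stack_gb)
      gb <- labelObjects3d(readStack(config$stack_gb),
                           threshold = config$threshold %||% "otsu",
                           voxelSize = config$voxel_size %||% 1,
                           connectivity = config$connectivity %||% 26)
      sc <- singleCellVolumes(gb, window = unlist(
        config$single_cell_window %||% c(50, 500)))
      summ$mean_single_cell_volume_um3 <- sc$mean_volume
      summ$n_single_cells <- length(sc$volumes)
      if (is.finite(sc$mean_volume)) {
        est <- estimateCellNumber(total, sc$mean_volume)
        summ$estimated_cell_number_raw <- est$raw
        summ$estimated_cell_number <- est$count
      }
    }
    utils::write.csv(summ, file.path(outDir, "volume_summary.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    outputs <- c(outputs, file.path(outDir, "volume_summary.csv"))
  } else if (subcommand == "calcium") {
    inputs <- c(config$traces, config$protocol)
    traces <- readTraceTable(config$traces)
    protocol <- readProtocol(config$protocol)
    calls <- classifyTraces(traces, protocol,
                            kSdQc = config$k_sd_qc %||% 3,
                            kSdResponder = config$k_sd_responder %||% 3,
                            dwell = config$dwell %||% 0.1)
    utils::write.csv(calls, file.path(outDir, "calcium_calls.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    outputs <- file.path(outDir, "calcium_calls.csv")
    if (!is.null(config$regions)) {
      inputs <- c(inputs, config$regions)
      regions <- .readCsvChecked(config$regions,
                                 c("cell_id", "islet_id", "region"))
      merged <- merge(calls, regions, by = "cell_id")
      rs <- regionalResponderStats(merged)
      utils::write.csv(rs$summary,
                       file.path(outDir, "regional_summary.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
      outputs <- c(outputs, file.path(outDir, "regional_summary.csv"))
    }
    extra$k_sd_qc <- config$k_sd_qc %||% 3
    extra$k_sd_responder <- config$k_sd_responder %||% 3
    extra$dwell <- config$dwell %||% 0.1
  } else if (subcommand == "spatial") {
    inputs <- config$cells
    cells <- readCellTable(config$cells)
    part <- splitAp(cells,
                    anteriorTip = config$anterior_tip,
                    posteriorTip = config$posterior_tip)
    assign <- data.frame(cell_id = names(part@assignment),
                         half = as.character(part@assignment),
                         stringsAsFactors = FALSE)
    utils::write.csv(assign, file.path(outDir, "ap_assignment.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    counts <- regionalCounts(part, cells)
    ratio <- labelingRatio(part, cells)
    summ <- data.frame(n_anterior = counts[["n_anterior"]],
                       n_posterior = counts[["n_posterior"]],
                       labeling_ratio_post_over_ant = ratio)
    utils::write.csv(summ, file.path(outDir, "ap_summary.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    outputs <- file.path(outDir, c("ap_assignment.csv", "ap_summary.csv"))
  }

  manifest <- writeManifest(outDir, subcommand, config, inputs, outputs,
                            extra)
  invisible(manifest)
}

#' @rdname runPipeline
#' @param inputs,outputs file paths to checksum into the manifest.
#' @param extra named list of extra quantities to record.
#' @export
writeManifest <- function(outDir, subcommand, config, inputs = character(),
                          outputs = character(), extra = list()) {
  checksum <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (!length(paths)) return(stats::setNames(list(), character()))
    md5 <- tools::md5sum(paths)
    stats::setNames(as.list(md5), basename(paths))
  }
  manifest <- c(list(
    subcommand = subcommand,
    package = "isletrace",
    version = as.character(utils::packageVersion("isletrace")),
    seed = config$seed,
    config = config,
    input_checksums = checksum(as.character(inputs)),
    output_checksums = checksum(as.character(outputs))), extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
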