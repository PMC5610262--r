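## File I/O: CSV tables, protocol JSON, multi-page TIFF stacks, YAML/JSON
## config. All tables are UTF-8 CSV with header; TIFF stacks are 16-bit
## grayscale, one file per channel, pages = z-planes.

.readCsvChecked <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read and write the per-cell measurement table
#'
#' CSV schema: `cell_id, islet_id, stage_dpf, r_mean, g_mean, b_mean,
#' r_sd, g_sd, b_sd, n_pixels, x, y, z`. Readers fail with a schema error
#' naming any missing column; writers emit a header and UTF-8 text, and
#' write-then-read round-trips are lossless field-for-field.
#'
#' @param path file path.
#' @return `readCellTable()` returns the data.frame; writers return the
#'   path invisibly.
#' @export
readCellTable <- function(path) .readCsvChecked(path, .cellCols)

#' @rdname readCellTable
#' @param cells measurement data.frame.
#' @export
writeCellTable <- function(cells, path) {
  .checkCellTable(cells)
  utils::write.csv(cells, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname readCellTable
#' @details Truth sidecars carry the simulator's ground-truth labels; the
#' reader only requires the identifier and clone columns so downstream
#' tools accept trimmed tables.
#' @export
readTruthTable <- function(path)
  .readCsvChecked(path, c("cell_id", "islet_id", "clone_id", "lineage"))

#' @rdname readCellTable
#' @param truth ground-truth data.frame from [simulateIslet()].
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write long-format calcium traces
#'
#' CSV schema: `cell_id, t_seconds, fluorescence`.
#'
#' @param path file path.
#' @export
readTraceTable <- function(path)
  .readCsvChecked(path, c("cell_id", "t_seconds", "fluorescence"))

#' @rdname readTraceTable
#' @param traces long-format trace data.frame.
#' @export
writeTraceTable <- function(traces, path) {
  .checkCellTable(traces, need = c("cell_id", "t_seconds", "fluorescence"))
  utils::write.csv(traces, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write a stimulus protocol as JSON
#'
#' The protocol is stored as a JSON array of phase objects with fields
#' `label`, `concentration_mM`, `t_start`, `t_end`.
#'
#' @param path file path.
#' @return A [StimulusProtocol-class].
#' @export
readProtocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ph <- tryCatch(jsonlite::fromJSON(path),
                 error = function(e)
                   stop("parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  stimulusProtocol(as.data.frame(ph))
}

#' @rdname readProtocol
#' @param protocol a [StimulusProtocol-class].
#' @export
writeProtocol <- function(protocol, path) {
  stopifnot(is(protocol, "StimulusProtocol"))
  jsonlite::write_json(phases(protocol), path, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write 3D stacks as multi-page 16-bit TIFF
#'
#' One grayscale file per channel; TIFF pages are z-planes and each page
#' holds the (x,y) plane of the stack. Intensities are stored on the
#' 16-bit integer scale.
#'
#' @param path file path.
#' @return `readStack()` returns a 3D numeric array (x, y, z) on the
#'   0..65535 scale.
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("parse error in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages))
    if (is.null(dim(pages[[i]])) || length(dim(pages[[i]])) != 2L)
      stop("parse error in ", path, ", page ", i,
           ": expected a single-channel grayscale page", call. = FALSE)
  arr <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  round(arr * 65535)
}

#' @rdname readStack
#' @param stack 3D numeric array on the 0..65535 scale.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  pages <- lapply(seq_len(dim(stack)[3L]),
                  function(z) stack[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Configurations drive [runPipeline()]. YAML is the native format; JSON
#' is accepted (every JSON file is valid YAML). A `seed` field is
#' mandatory: every stochastic run must record its seed.
#'
#' @param path file path to a `.yaml`/`.yml`/`.json` config.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(cfg$seed))
    stop("schema error in ", path, ": missing required field 'seed'",
         call. = FALSE)
  cfg
}
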