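#' Split an islet into anterior and posterior halves
#'
#' Implements the A/P half-split used for all regional comparisons: on the
#' (x,y) projection plane, the islet center is the midpoint of the segment
#' from the anterior tip to the posterior tip, and the divider is the line
#' through that midpoint perpendicular to the tip segment. A cell is
#' anterior when its signed projection onto the tip axis falls on the
#' anterior side of the midpoint; cells exactly on the divider are
#' assigned anterior (fixed, documented tie-break).
#'
#' @param cells data.frame with `cell_id`, `x`, `y`.
#' @param anteriorTip,posteriorTip length-2 (x,y) points; must be
#'   distinct. When both are NULL they are estimated with
#'   [estimateTips()].
#' @return An [ApPartition-class].
#' @examples
#' cells <- data.frame(cell_id = c("a", "b"), x = c(-5, 5), y = 0)
#' splitAp(cells, anteriorTip = c(-10, 0), posteriorTip = c(10, 0))
#' @export
splitAp <- function(cells, anteriorTip = NULL, posteriorTip = NULL) {
  .checkCellTable(cells, need = c("cell_id", "x", "y"))
  if (is.null(anteriorTip) && is.null(posteriorTip)) {
    tips <- estimateTips(cells)
    anteriorTip <- tips$anterior
    posteriorTip <- tips$posterior
  }
  anteriorTip <- as.numeric(anteriorTip)
  posteriorTip <- as.numeric(posteriorTip)
  stopifnot(length(anteriorTip) == 2L, length(posteriorTip) == 2L)
  axis <- anteriorTip - posteriorTip
  if (sum(axis^2) == 0)
    stop("anterior and posterior tips must be distinct", call. = FALSE)
  mid <- (anteriorTip + posteriorTip) / 2
  # signed distance toward the anterior tip; >= 0 (divider included) is
  # anterior
  s <- (cells$x - mid[1L]) * axis[1L] + (cells$y - mid[2L]) * axis[2L]
  side <- factor(ifelse(s >= 0, "anterior", "posterior"),
                 levels = c("anterior", "posterior"))
  names(side) <- cells$cell_id
  new("ApPartition", anteriorTip = anteriorTip,
      posteriorTip = posteriorTip, midpoint = mid, assignment = side)
}

#' @rdname splitAp
#' @details `estimateTips()` picks the two mutually most distant cell
#' centroids on the projection plane as the axis tips (the original
#' procedure placed them manually on a maximum-intensity projection).
#' Orientation is resolved by convention: the tip with the smaller x
#' coordinate is called anterior, matching the simulator's geometry;
#' supply tips explicitly when the convention does not apply.
#' @export
estimateTips <- function(cells) {
  .checkCellTable(cells, need = c("x", "y"))
  if (nrow(cells) < 2L)
    stop("need at least 2 cells to estimate axis tips", call. = FALSE)
  xy <- as.matrix(cells[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
  p1 <- xy[ij[1L], ]; p2 <- xy[ij[2L], ]
  if (p1[1L] <= p2[1L]) list(anterior = p1, posterior = p2)
  else list(anterior = p2, posterior = p1)
}

#' Posterior/anterior labeling ratio
#'
#' Ratio of summed recombination-channel (green + blue) intensity in the
#' posterior half over the anterior half, the measure of where
#' multicolor-labeled (pre-existing) beta-cells sit along the A/P axis.
#' Values above 1 indicate posterior enrichment of labeled cells.
#'
#' @param partition an [ApPartition-class].
#' @param cells data.frame with `cell_id`, `g_mean`, `b_mean` (per-cell
#'   intensity aggregation; per-pixel sums work the same way).
#' @return The ratio; `Inf`, with a warning, when the anterior half has
#'   zero labeled intensity.
#' @export
labelingRatio <- function(partition, cells) {
  stopifnot(is(partition, "ApPartition"))
  .checkCellTable(cells, need = c("cell_id", "g_mean", "b_mean"))
  side <- partition@assignment[match(cells$cell_id,
                                     names(partition@assignment))]
  if (anyNA(side))
    stop("cells missing from the partition: ",
         paste(utils::head(cells$cell_id[is.na(side)], 5L),
               collapse = ", "), call. = FALSE)
  lab <- cells$g_mean + cells$b_mean
  ant <- sum(lab[side == "anterior"])
  post <- sum(lab[side == "posterior"])
  if (ant == 0) {
    warning("zero anterior labeled intensity: ratio flagged infinite")
    return(Inf)
  }
  post / ant
}

#' Regional cell counts
#'
#' Counts cells satisfying a predicate in each half of the partition,
#' e.g. lineage-traced cells per half. Across islets such paired counts
#' are compared with a paired two-tailed t test (see
#' [compareRegionalCounts()]).
#'
#' @param partition an [ApPartition-class].
#' @param cells data.frame with `cell_id` (other columns are available to
#'   the predicate).
#' @param predicate function of the cell data.frame returning a logical
#'   vector, or NULL to count all cells.
#' @return Named integer vector `c(n_anterior, n_posterior)`.
#' @examples
#' cells <- data.frame(cell_id = letters[1:4], x = c(-2, -1, 1, 2), y = 0)
#' p <- splitAp(cells, c(-3, 0), c(3, 0))
#' regionalCounts(p, cells)
#' @export
regionalCounts <- function(partition, cells, predicate = NULL) {
  stopifnot(is(partition, "ApPartition"))
  .checkCellTable(cells, need = "cell_id")
  if (nrow(cells) == 0L)
    return(c(n_anterior = 0L, n_posterior = 0L))
  keep <- if (is.null(predicate)) rep(TRUE, nrow(cells))
          else as.logical(predicate(cells))
  side <- partition@assignment[match(cells$cell_id,
                                     names(partition@assignment))]
  if (anyNA(side))
    stop("cells missing from the partition", call. = FALSE)
  c(n_anterior = sum(keep & side == "anterior", na.rm = TRUE),
    n_posterior = sum(keep & side == "posterior", na.rm = TRUE))
}

#' @rdname regionalCounts
#' @details `compareRegionalCounts()` runs the paired two-tailed Welch
#' t test on per-islet (anterior, posterior) count pairs, the test used
#' for all A/P comparisons.
#' @param counts data.frame or matrix with columns `n_anterior`,
#'   `n_posterior`, one row per islet.
#' @export
compareRegionalCounts <- function(counts) {
  counts <- as.data.frame(counts)
  .checkCellTable(counts, need = c("n_anterior", "n_posterior"))
  stats::t.test(counts$n_anterior, counts$n_posterior, paired = TRUE,
                alternative = "two.sided")$p.value
}
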