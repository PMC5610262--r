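#' Threshold a stack and label 3D connected components
#'
#' The volumetry front end: thresholds a grayscale stack and labels the
#' foreground into connected components (26-connectivity by default, i.e.
#' voxels touching by face, edge or corner belong to the same object),
#' returning one row per object with its voxel count, volume, bounding box
#' and centroid. Object ids are assigned in raster-scan order of each
#' component's first voxel, so labeling is deterministic. The default
#' threshold is Otsu's method computed on the 8-bit-converted intensity
#' histogram of the whole stack (via EBImage); an explicit numeric
#' threshold can be supplied instead. An all-background stack yields an
#' empty table, not an error.
#'
#' @param stack 3D numeric array (x, y, z).
#' @param threshold `"otsu"` or a numeric intensity cutoff; voxels with
#'   intensity strictly above the cutoff are foreground.
#' @param voxelSize voxel edge length in micrometers (scalar, isotropic).
#' @param connectivity 26 (default) or 6 (face neighbors only).
#' @return data.frame with columns `object_id`, `voxel_count`,
#'   `volume_um3`, `x0`, `x1`, `y0`, `y1`, `z0`, `z1` (0-based, half-open
#'   bounding box) and `cx`, `cy`, `cz` (centroid, voxel units). The
#'   threshold used is attached as attribute `threshold`.
#' @examples
#' a <- array(0, c(8, 8, 8)); a[2:4, 2:4, 2:4] <- 100
#' labelObjects3d(a, threshold = 50, voxelSize = 1)
#' @export
labelObjects3d <- function(stack, threshold = "otsu", voxelSize = 1,
                           connectivity = 26) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be a 3D array", call. = FALSE)
  if (length(stack) == 0L) stop("stack must be nonempty", call. = FALSE)
  if (!is.numeric(voxelSize) || length(voxelSize) != 1L || voxelSize <= 0)
    stop("voxelSize must be a single positive number", call. = FALSE)
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26", call. = FALSE)

  thr <- if (identical(threshold, "otsu")) otsuThreshold(stack)
         else {
           stopifnot(is.numeric(threshold), length(threshold) == 1L)
           threshold
         }
  fg <- stack > thr
  dims <- dim(stack)
  lab <- .labelForeground(fg, dims, connectivity)
  voxVol <- voxelSize^3

  idx <- which(fg)
  if (length(idx) == 0L) {
    out <- data.frame(object_id = integer(), voxel_count = integer(),
                      volume_um3 = numeric(), x0 = integer(),
                      x1 = integer(), y0 = integer(), y1 = integer(),
                      z0 = integer(), z1 = integer(), cx = numeric(),
                      cy = numeric(), cz = numeric())
    attr(out, "threshold") <- thr
    return(out)
  }
  coords <- arrayInd(idx, dims)
  comp <- lab[idx]
  # relabel so ids follow the raster order of each component's first voxel
  first <- tapply(idx, comp, min)
  newId <- match(comp, names(sort(first)))
  byObj <- split(seq_along(idx), newId)
  out <- do.call(rbind, lapply(seq_along(byObj), function(i) {
    rows <- byObj[[i]]
    cc <- coords[rows, , drop = FALSE]
    data.frame(object_id = i, voxel_count = length(rows),
               volume_um3 = length(rows) * voxVol,
               x0 = min(cc[, 1L]) - 1L, x1 = max(cc[, 1L]),
               y0 = min(cc[, 2L]) - 1L, y1 = max(cc[, 2L]),
               z0 = min(cc[, 3L]) - 1L, z1 = max(cc[, 3L]),
               cx = mean(cc[, 1L]) - 1, cy = mean(cc[, 2L]) - 1,
               cz = mean(cc[, 3L]) - 1)
  }))
  attr(out, "threshold") <- thr
  out
}

#' @rdname labelObjects3d
#' @details `otsuThreshold()` converts the stack to the 8-bit scale the
#' original analysis used and returns Otsu's threshold mapped back to the
#' input intensity scale. The stack is flattened before calling EBImage so
#' a single global threshold is computed (EBImage's `otsu` is per-frame on
#' multi-frame images).
#' @export
otsuThreshold <- function(stack) {
  v <- as.numeric(stack)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)            # constant stack: everything background
  scaled <- (v - lo) / (hi - lo)
  img <- EBImage::Image(matrix(scaled, ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  lo + thr * (hi - lo)
}

# Vectorized connected-component labeling: foreground voxels become graph
# vertices, adjacency is built by shifting the index grid along each
# half-neighborhood offset, and components come from igraph.
.labelForeground <- function(fg, dims, connectivity) {
  offsets6 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  offsets26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets26 <- offsets26[offsets26[, 3] > 0 |
                           (offsets26[, 3] == 0 & offsets26[, 2] > 0) |
                           (offsets26[, 3] == 0 & offsets26[, 2] == 0 &
                              offsets26[, 1] > 0), , drop = FALSE]
  offs <- if (connectivity == 6) offsets6 else offsets26

  idx <- which(fg)
  lab <- array(0L, dims)
  if (length(idx) == 0L) return(lab)
  vid <- array(0L, dims)
  vid[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)

  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[k, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    if (!any(ok)) next
    nbLin <- nb[ok, 1L] + dims[1L] * (nb[ok, 2L] - 1L) +
      dims[1L] * dims[2L] * (nb[ok, 3L] - 1L)
    nbId <- vid[nbLin]
    hit <- nbId > 0L
    if (any(hit))
      edges[[k]] <- rbind(which(ok)[hit], nbId[hit])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_graph(if (is.null(em)) integer() else as.vector(em),
                          n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Total labeled volume of an object table
#'
#' Sums the per-object volumes of a labeled stack. Applied to the
#' all-channel composite this is the total beta-cell volume of the islet.
#'
#' @param objects object table from [labelObjects3d()].
#' @return Total volume in cubic micrometers (0 for an empty table).
#' @export
totalBetaVolume <- function(objects) {
  .checkCellTable(objects, need = "volume_um3")
  sum(objects$volume_um3)
}

#' Isolated single-cell volumes
#'
#' Filters a green+blue-channel object table down to objects whose volume
#' lies within a plausible single-cell window, excluding fused objects
#' (adjacent cells with similar color profiles that the threshold cannot
#' separate) and sub-cellular fragments. Returns the retained volumes and
#' their mean, the denominator of the cell-number estimate.
#'
#' @param objects object table from [labelObjects3d()] run on the
#'   green+blue composite.
#' @param window length-2 numeric, inclusive single-cell volume window in
#'   cubic micrometers. The default reflects a mean single-cell volume
#'   around 185 um^3.
#' @return A list with `volumes` (numeric vector) and `mean_volume`
#'   (NA, with a warning, when nothing passes the filter).
#' @export
singleCellVolumes <- function(objects, window = c(50, 500)) {
  .checkCellTable(objects, need = "volume_um3")
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  keep <- objects$volume_um3 >= window[1L] &
    objects$volume_um3 <= window[2L]
  vols <- objects$volume_um3[keep]
  if (length(vols) == 0L) {
    warning("no objects pass the single-cell isolation window")
    return(list(volumes = numeric(), mean_volume = NA_real_))
  }
  list(volumes = vols, mean_volume = mean(vols))
}

#' Estimate beta-cell number from a volume ratio
#'
#' Estimates the number of beta-cells in an islet as the ratio of the
#' total beta-cell volume to the mean single-cell volume. With the
#' published worked example, 151337.80 / 184.70 gives a raw estimate of
#' about 819.4, i.e. roughly 820 cells.
#'
#' @param totalVolume total beta-cell volume, um^3 (> 0, or 0 for an
#'   empty islet).
#' @param meanSingleCellVolume mean single-cell volume, um^3 (> 0).
#' @return A list with `raw` (the unrounded ratio) and `count`
#'   (`round(raw)`).
#' @examples
#' estimateCellNumber(151337.80, 184.70)
#' @export
estimateCellNumber <- function(totalVolume, meanSingleCellVolume) {
  stopifnot(is.numeric(totalVolume), is.numeric(meanSingleCellVolume))
  if (meanSingleCellVolume <= 0)
    stop("mean single-cell volume must be positive", call. = FALSE)
  if (totalVolume < 0)
    stop("total volume must be nonnegative", call. = FALSE)
  raw <- totalVolume / meanSingleCellVolume
  list(raw = raw, count = round(raw))
}

#' Background recombination probability arithmetic
#'
#' Estimates the per-cell probability of a spontaneous (leaky) single
#' recombination event as `events / (cells_per_islet * islets)`, and the
#' probability of a spontaneous trichromatic cell -- which requires two
#' independent recombination events -- as its square. Following the
#' published convention the single-event probability is rounded to
#' `sigFigs` significant figures before squaring (4 leaky events over 10
#' islets of ~820 cells gives 0.0005, hence 2.5e-7); the unrounded values
#' are reported alongside.
#'
#' @param nEvents number of observed leaky recombination events.
#' @param nCellsPerIslet estimated beta-cells per islet (>= 1).
#' @param nIslets number of islets scored (>= 1).
#' @param sigFigs significant figures for the round-then-square
#'   convention.
#' @return A list with `p_single`, `p_trichromatic` (round-then-square),
#'   `p_single_raw`, `p_trichromatic_raw`, and the inputs.
#' @examples
#' backgroundRecombination(4, 820, 10)
#' @export
backgroundRecombination <- function(nEvents, nCellsPerIslet, nIslets,
                                    sigFigs = 1) {
  if (nEvents < 0 || nEvents != round(nEvents))
    stop("nEvents must be a nonnegative integer", call. = FALSE)
  if (nCellsPerIslet < 1 || nIslets < 1)
    stop("need at least one cell per islet and one islet", call. = FALSE)
  pRaw <- nEvents / (nCellsPerIslet * nIslets)
  pRound <- .sigfig(pRaw, sigFigs)
  list(p_single = pRound, p_trichromatic = pRound^2,
       p_single_raw = pRaw, p_trichromatic_raw = pRaw^2,
       n_events = nEvents, n_cells_per_islet = nCellsPerIslet,
       n_islets = nIslets)
}
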