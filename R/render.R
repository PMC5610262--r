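#' Render a synthetic islet as 3D image stacks
#'
#' Voxelizes the ground-truth cells of a simulated islet into one 16-bit
#' grayscale stack per color channel plus an all-channel composite, the
#' input format of the volumetry stage. Each cell becomes a compact blob
#' of `round(volume / voxelVolume)` voxels grown outward from its centroid
#' voxel (candidates ordered by distance, ties broken in raster order), so
#' the rendered volume matches the true volume to within one voxel. Cells
#' are mutually exclusive in space: when a blob would overlap an earlier
#' neighbor it deforms into the nearest unclaimed voxels instead, so the
#' total foreground volume is conserved even in crowded islets. A cell
#' is rendered into a channel when its true intensity in that channel is
#' positive; the composite takes the voxelwise maximum. Gaussian intensity
#' noise is added everywhere and values are clamped to the 16-bit range.
#'
#' @param truth ground-truth data.frame from [simulateIslet()] (needs
#'   `x`, `y`, `z`, `volume_um3`, `true_r`, `true_g`, `true_b`).
#' @param voxelSize isotropic voxel edge length, micrometers.
#' @param seed integer seed for the intensity noise.
#' @param fgLevel,bgLevel mean foreground / background intensity (a.u. on
#'   the 16-bit scale).
#' @param noiseSd additive Gaussian intensity noise sd.
#' @param overlapTol warn when more than this fraction of foreground
#'   voxels had to be displaced from a cell's ideal compact shape by
#'   overlapping neighbors (crowded islet); crowding deforms cells, it
#'   never rejects them.
#' @return A list with `channels` (named list of 3D arrays `r`, `g`, `b`),
#'   `composite` (3D array), `voxelSize`, `origin` (xyz of the voxel-grid
#'   origin, micrometers), and `nForegroundVoxels` per cell.
#' @examples
#' isl <- simulateIslet(growthConfig(nFounders = 5, stages = c(3.5, 15),
#'                                   neogenesisRate = 0),
#'                      recombinationConfig(pRecomb = 0.5),
#'                      noiseConfig(), seed = 1)
#' st <- renderStack(isl$truth, voxelSize = 1, seed = 2)
#' dim(st$composite)
#' @export
renderStack <- function(truth, voxelSize = 1, seed, fgLevel = 3000,
                        bgLevel = 200, noiseSd = 100, overlapTol = 0.05) {
  stopifnot(is.data.frame(truth))
  if (!is.numeric(voxelSize) || length(voxelSize) != 1L || voxelSize <= 0)
    stop("voxelSize must be a single positive number", call. = FALSE)
  voxVol <- voxelSize^3
  n <- nrow(truth)

  if (n == 0L) {
    dims <- c(16L, 16L, 16L)
    empty <- .withSeed(seed, {
      lapply(1:4, function(i)
        .clamp16(array(stats::rnorm(prod(dims), bgLevel, noiseSd), dims)))
    })
    return(list(channels = list(r = empty[[1L]], g = empty[[2L]],
                                b = empty[[3L]]),
                composite = empty[[4L]], voxelSize = voxelSize,
                origin = c(0, 0, 0), nForegroundVoxels = integer()))
  }

  need <- c("x", "y", "z", "volume_um3", "true_r", "true_g", "true_b")
  missing <- setdiff(need, names(truth))
  if (length(missing))
    stop("truth is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  kVox <- pmax(1L, as.integer(round(truth$volume_um3 / voxVol)))
  rMax <- ceiling((3 * max(kVox) / (4 * pi))^(1 / 3)) + 2L
  margin <- (rMax + 2L) * voxelSize
  origin <- c(min(truth$x), min(truth$y), min(truth$z)) - margin
  dims <- as.integer(ceiling((c(max(truth$x), max(truth$y), max(truth$z)) -
                                origin + margin) / voxelSize)) + 1L

  # Which channels each cell expresses.
  expr <- cbind(r = truth$true_r > 0, g = truth$true_g > 0,
                b = truth$true_b > 0)

  # Cells are solid bodies: each voxel belongs to exactly one cell, and a
  # blob crowded by earlier neighbors deforms outward into the nearest
  # unclaimed voxels so its rendered volume is conserved.
  owner <- integer(prod(dims))          # 0 = background, else cell index
  chanFg <- list(r = logical(prod(dims)), g = logical(prod(dims)),
                 b = logical(prod(dims)))
  overlap <- 0L
  for (i in seq_len(n)) {
    ctr <- as.integer(round((c(truth$x[i], truth$y[i], truth$z[i]) -
                               origin) / voxelSize)) + 1L
    cand <- .blobCandidates(ctr, kVox[i], dims)
    lin <- cand[, 1L] + dims[1L] * (cand[, 2L] - 1L) +
      dims[1L] * dims[2L] * (cand[, 3L] - 1L)
    ideal <- lin[seq_len(min(kVox[i], length(lin)))]
    overlap <- overlap + sum(owner[ideal] != 0L)
    free <- lin[owner[lin] == 0L]
    take <- free[seq_len(min(kVox[i], length(free)))]
    owner[take] <- i
    for (ch in c("r", "g", "b"))
      if (expr[i, ch]) chanFg[[ch]][take] <- TRUE
  }
  totalFg <- sum(kVox)
  if (overlap / totalFg > overlapTol)
    warning(sprintf(paste("%.1f%% of foreground voxels were displaced by",
                          "overlapping cells"),
                    100 * overlap / totalFg))

  channels <- .withSeed(seed, {
    lapply(chanFg, function(fg) {
      v <- stats::rnorm(prod(dims), bgLevel, noiseSd)
      v[fg] <- stats::rnorm(sum(fg), fgLevel, noiseSd)
      .clamp16(array(v, dims))
    })
  })
  composite <- pmax(channels$r, pmax(channels$g, channels$b))

  list(channels = channels, composite = composite, voxelSize = voxelSize,
       origin = origin,
       nForegroundVoxels = as.integer(tabulate(owner[owner != 0L], n)))
}

.clamp16 <- function(x) {
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  round(x)
}

# Candidate voxels around ctr ordered by squared euclidean distance
# (raster-order tie-break), clipped to the array bounds. The search cube
# is wider than the ideal blob radius so a crowded cell can still find
# k unclaimed voxels nearby.
.blobCandidates <- function(ctr, k, dims) {
  r <- ceiling((3 * k / (4 * pi))^(1 / 3)) + 6L
  sx <- max(1L, ctr[1L] - r):min(dims[1L], ctr[1L] + r)
  sy <- max(1L, ctr[2L] - r):min(dims[2L], ctr[2L] + r)
  sz <- max(1L, ctr[3L] - r):min(dims[3L], ctr[3L] + r)
  g <- expand.grid(x = sx, y = sy, z = sz, KEEP.OUT.ATTRS = FALSE)
  d2 <- (g$x - ctr[1L])^2 + (g$y - ctr[2L])^2 + (g$z - ctr[3L])^2
  ord <- order(d2, g$z, g$y, g$x)
  as.matrix(g[ord, , drop = FALSE])
}
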