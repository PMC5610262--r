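#' Estimate channel background from unlabeled cells
#'
#' Averages the green and blue mean intensities of at least three
#' unlabeled reference cells. Only green and blue backgrounds are
#' estimated because only those channels are background-subtracted before
#' normalization; red is used as measured (the red channel reports the
#' default, unrecombined cassette state and was treated as-is in the
#' original procedure).
#'
#' @param unlabeled data.frame of unlabeled reference cells with columns
#'   `g_mean` and `b_mean` (>= 3 rows).
#' @return A list with `g_background`, `b_background` and `n_reference`.
#' @examples
#' estimateBackground(data.frame(g_mean = c(3, 4, 5), b_mean = c(2, 2, 2)))
#' @export
estimateBackground <- function(unlabeled) {
  .checkCellTable(unlabeled, need = c("g_mean", "b_mean"))
  if (nrow(unlabeled) < 3L)
    stop("background estimation needs at least 3 unlabeled reference cells",
         call. = FALSE)
  list(g_background = mean(unlabeled$g_mean),
       b_background = mean(unlabeled$b_mean),
       n_reference = nrow(unlabeled))
}

#' Subtract channel background from color measurements
#'
#' Subtracts the estimated green and blue backgrounds from the per-cell
#' channel means, clamping at zero. Red means and all channel sds are left
#' unchanged: the procedure subtracts background from the recombination
#' channels (green, blue) only.
#'
#' @param cells measurement data.frame (see [simulateIslet()] for the
#'   schema).
#' @param bg a background estimate from [estimateBackground()], or a named
#'   list/vector with `g_background` and `b_background`.
#' @return The data.frame with `g_mean` and `b_mean` background-subtracted.
#' @examples
#' cells <- data.frame(g_mean = c(50, 5), b_mean = c(20, 30))
#' subtractBackground(cells, list(g_background = 10, b_background = 0))
#' @export
subtractBackground <- function(cells, bg) {
  .checkCellTable(cells, need = c("g_mean", "b_mean"))
  g0 <- bg[["g_background"]]; b0 <- bg[["b_background"]]
  if (is.null(g0) || is.null(b0) || g0 < 0 || b0 < 0)
    stop("bg must provide nonnegative g_background and b_background",
         call. = FALSE)
  cells$g_mean <- pmax(0, cells$g_mean - g0)
  cells$b_mean <- pmax(0, cells$b_mean - b0)
  cells
}

#' Normalize a color measurement to a percentage signature
#'
#' Computes the color signature of each cell,
#' `C_normalized = C_mean / (R_mean + G_mean + B_mean) * 100` for C in
#' R, G, B, so that the three components sum to 100. The signature is the
#' barcode compared between cells by the equivalence test.
#'
#' @param cells measurement data.frame with `r_mean`, `g_mean`, `b_mean`
#'   (background-subtracted).
#' @return data.frame with columns `r_pct`, `g_pct`, `b_pct` (and
#'   `cell_id` when present in the input).
#' @examples
#' normalizeSignature(data.frame(r_mean = 2, g_mean = 1, b_mean = 1))
#' @export
normalizeSignature <- function(cells) {
  .checkCellTable(cells, need = c("r_mean", "g_mean", "b_mean"))
  s <- cells$r_mean + cells$g_mean + cells$b_mean
  if (any(s <= 0))
    stop("degenerate signal: channel sum is zero for cell(s) ",
         paste(utils::head(which(s <= 0), 5L), collapse = ", "),
         call. = FALSE)
  out <- data.frame(r_pct = 100 * cells$r_mean / s,
                    g_pct = 100 * cells$g_mean / s,
                    b_pct = 100 * cells$b_mean / s)
  if ("cell_id" %in% names(cells))
    out <- cbind(cell_id = cells$cell_id, out, stringsAsFactors = FALSE)
  out
}

#' Triple-positive criterion
#'
#' A cell is carried into clonal clustering only when all three channels
#' are confidently above zero: `C_mean - 2.58 * C_sd > 0` for each of R,
#' G, B (strict inequality). The multiplier 2.58 is the two-sided standard
#' normal critical distance at p = 0.01, so a channel whose true signal is
#' zero passes by chance at most about 1% of the time.
#'
#' @param cells background-subtracted measurement data.frame with channel
#'   means and sds.
#' @param k critical multiplier (default 2.58).
#' @return Logical vector, one entry per row.
#' @examples
#' isTriplePositive(data.frame(r_mean = 10, g_mean = 10, b_mean = 10,
#'                             r_sd = 1, g_sd = 1, b_sd = 1))
#' @export
isTriplePositive <- function(cells, k = 2.58) {
  .checkCellTable(cells, need = c("r_mean", "g_mean", "b_mean",
                                  "r_sd", "g_sd", "b_sd"))
  (cells$r_mean - k * cells$r_sd > 0) &
    (cells$g_mean - k * cells$g_sd > 0) &
    (cells$b_mean - k * cells$b_sd > 0)
}

# Normalized signature of one measurement row plus the delta-method
# variance of each normalized channel mean. Raw channel sds are pixel
# sds; the variance of the channel mean is sd^2 / n_pixels, propagated
# through p_C = 100 * C / (R + G + B) assuming independent channels.
.normWithVar <- function(m) {
  C <- c(m$r_mean, m$g_mean, m$b_mean)
  v <- c(m$r_sd, m$g_sd, m$b_sd)^2 / m$n_pixels
  S <- sum(C)
  if (S <= 0) stop("degenerate signal: channel sum is zero", call. = FALSE)
  p <- 100 * C / S
  varP <- vapply(1:3, function(i) {
    grad <- -100 * C[i] / S^2 + c(i == 1, i == 2, i == 3) * 100 / S
    sum(grad^2 * v)
  }, numeric(1))
  list(p = p, varP = varP)
}

#' Pairwise TOST equivalence of two color signatures
#'
#' Tests whether two triple-positive cells carry the same color barcode
#' using the two one-sided tests (TOST) procedure per channel on the
#' normalized scale. For each channel the difference in normalized means
#' is tested against the equivalence margin with two one-sided Welch-type
#' t tests; the per-cell pixel sds are propagated to the normalized scale
#' by the delta method and degrees of freedom follow Welch-Satterthwaite
#' with `n_pixels - 1` per cell. The pair is equivalent when both
#' one-sided tests reject at `alpha` in every channel. The decision is
#' symmetric in its two arguments.
#'
#' @param a,b single-row measurement data.frames (background-subtracted,
#'   triple-positive), each with channel means, sds and `n_pixels`.
#' @param params a [TostParams-class].
#' @param detail if TRUE, return per-channel p-values instead of a single
#'   logical.
#' @return Logical scalar (or, with `detail = TRUE`, a list with
#'   `equivalent`, `p_channel` -- the larger of the two one-sided p-values
#'   per channel -- and `delta`, the normalized mean differences).
#' @examples
#' a <- data.frame(r_mean = 50, g_mean = 25, b_mean = 25,
#'                 r_sd = 3, g_sd = 3, b_sd = 3, n_pixels = 50)
#' tostPair(a, a, tostParams(marginPct = 10))
#' @export
tostPair <- function(a, b, params = tostParams(), detail = FALSE) {
  stopifnot(is(params, "TostParams"))
  validObject(params)
  need <- c("r_mean", "g_mean", "b_mean", "r_sd", "g_sd", "b_sd",
            "n_pixels")
  .checkCellTable(as.data.frame(a), need = need)
  .checkCellTable(as.data.frame(b), need = need)
  if (a$n_pixels < 2L || b$n_pixels < 2L)
    stop("insufficient data: n_pixels must be >= 2 for both cells",
         call. = FALSE)
  na <- .normWithVar(a); nb <- .normWithVar(b)
  margin <- params@marginPct
  pCh <- numeric(3)
  delta <- na$p - nb$p
  for (i in 1:3) {
    se2 <- na$varP[i] + nb$varP[i]
    if (se2 == 0) {
      # noise-free channel: decide on the raw difference
      pCh[i] <- if (abs(delta[i]) < margin) 0 else 1
      next
    }
    se <- sqrt(se2)
    df <- se2^2 / (na$varP[i]^2 / (a$n_pixels - 1) +
                     nb$varP[i]^2 / (b$n_pixels - 1))
    pLower <- stats::pt((delta[i] + margin) / se, df, lower.tail = FALSE)
    pUpper <- stats::pt((delta[i] - margin) / se, df, lower.tail = TRUE)
    pCh[i] <- max(pLower, pUpper)
  }
  equivalent <- all(pCh < params@alpha)
  if (detail)
    list(equivalent = equivalent, p_channel = pCh, delta = delta)
  else equivalent
}

#' Cluster the triple-positive cells of an islet into clones
#'
#' Runs the full clonal-analysis clustering: cells failing the
#' triple-positive criterion are excluded, every remaining pair is tested
#' with [tostPair()], and clones are the connected components of the
#' resulting equivalence graph -- when a cell falls in more than one
#' equivalent pair, all of the linked cells are merged into one clone
#' (transitive-union rule). Singleton components are single, quiescent
#' cells; larger components are multicellular clones.
#'
#' @param cells background-subtracted measurement data.frame from one
#'   islet (unique `cell_id`s).
#' @param params a [TostParams-class]. With `bonferroni = TRUE` the
#'   per-pair alpha is divided by the number of pairs tested.
#' @return A [CloneSet-class].
#' @examples
#' isl <- simulateIslet(growthConfig(nFounders = 6, stages = c(3.5, 15)),
#'                      recombinationConfig(pRecomb = 0.6),
#'                      noiseConfig(), seed = 1)
#' clusterClones(isl$cells, tostParams(marginPct = 10))
#' @export
clusterClones <- function(cells, params = tostParams()) {
  stopifnot(is(params, "TostParams"))
  if (nrow(cells) == 0L)
    return(new("CloneSet", isletId = "empty", clones = list(),
               excluded = character(), params = params))
  .checkCellTable(cells)
  if (length(unique(cells$islet_id)) != 1L)
    stop("clusterClones expects cells from a single islet; split by ",
         "islet_id first", call. = FALSE)
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell_id in input", call. = FALSE)

  tp <- isTriplePositive(cells)
  kept <- cells[tp, , drop = FALSE]
  excluded <- cells$cell_id[!tp]
  n <- nrow(kept)
  if (n == 0L)
    return(new("CloneSet", isletId = as.character(cells$islet_id[1L]),
               clones = list(), excluded = excluded, params = params))

  pairAlpha <- params@alpha
  if (params@bonferroni && n > 1L)
    pairAlpha <- params@alpha / choose(n, 2L)
  effParams <- tostParams(marginPct = params@marginPct, alpha = pairAlpha,
                          bonferroni = params@bonferroni)

  edges <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L))
      for (j in seq(i + 1L, n))
        if (tostPair(kept[i, ], kept[j, ], effParams))
          edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  cloneList <- split(kept$cell_id, comp)
  # stable order: clones by first (raster-order) member
  cloneList <- cloneList[order(vapply(cloneList,
                                      function(ids) match(ids[1L],
                                                          kept$cell_id),
                                      numeric(1)))]
  names(cloneList) <- sprintf("clone_%03d", seq_along(cloneList))
  new("CloneSet", isletId = as.character(cells$islet_id[1L]),
      clones = cloneList, excluded = excluded, params = params)
}

#' Summarize clonality of a clone set
#'
#' Percentages of tracked trichromatic events (clones) that remained
#' single cells versus formed multicellular clones, plus the clone-size
#' histogram. The denominator is the number of clones, i.e. the number of
#' tracked events, not the number of cells.
#'
#' @param cs a [CloneSet-class] with at least one clone.
#' @return A list with `n_clones`, `n_single`, `n_multi`, `pct_single`,
#'   `pct_multi` (summing to 100) and `size_histogram` (a table of clone
#'   sizes).
#' @examples
#' cs <- new("CloneSet", isletId = "i", params = tostParams(),
#'           clones = list(c("a"), c("b"), c("c", "d")),
#'           excluded = character())
#' clonalitySummary(cs)
#' @export
clonalitySummary <- function(cs) {
  stopifnot(is(cs, "CloneSet"))
  sz <- cloneSizes(cs)
  if (length(sz) == 0L)
    stop("undefined percentage: clone set has zero clones", call. = FALSE)
  nSingle <- sum(sz == 1L)
  nMulti <- sum(sz > 1L)
  list(n_clones = length(sz), n_single = nSingle, n_multi = nMulti,
       pct_single = 100 * nSingle / length(sz),
       pct_multi = 100 * nMulti / length(sz),
       size_histogram = table(size = sz))
}

#' Compare single-vs-multicellular clone counts between stages
#'
#' Two-sided Fisher's exact test on the 2x2 table of (single,
#' multicellular) clone counts at two stages, the test used to compare
#' clonality across developmental timepoints.
#'
#' @param a,b integer vectors `c(n_single, n_multi)` for the two stages,
#'   or `a` may be the full 2x2 matrix (stages in columns).
#' @return The two-sided p-value. The degenerate all-zero table returns
#'   p = 1 by convention, with a warning.
#' @examples
#' compareClonality(c(32, 2), c(18, 27))
#' @export
compareClonality <- function(a, b = NULL) {
  tab <- if (is.matrix(a)) a else cbind(a, b)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("expected a 2x2 table of (single, multi) x (stage A, stage B)",
         call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(tab) == 0) {
    warning("all-zero table: returning p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Ternary-plot coordinates of color signatures
#'
#' Maps normalized signatures onto the unit equilateral triangle by
#' barycentric interpolation: the red vertex is at (0, 0), green at
#' (1, 0) and blue at (1/2, sqrt(3)/2). Pure colors map to the vertices
#' and the uniform signature to the centroid; the map is invertible on
#' the simplex.
#'
#' @param sig data.frame with `r_pct`, `g_pct`, `b_pct` (summing to 100
#'   per row), or a numeric length-3 vector.
#' @return data.frame with columns `u`, `v`.
#' @examples
#' ternaryCoordinates(data.frame(r_pct = 100, g_pct = 0, b_pct = 0))
#' @export
ternaryCoordinates <- function(sig) {
  if (is.numeric(sig) && length(sig) == 3L)
    sig <- data.frame(r_pct = sig[1L], g_pct = sig[2L], b_pct = sig[3L])
  .checkCellTable(sig, need = c("r_pct", "g_pct", "b_pct"))
  w <- as.matrix(sig[, c("r_pct", "g_pct", "b_pct")]) / 100
  vert <- rbind(r = c(0, 0), g = c(1, 0), b = c(0.5, sqrt(3) / 2))
  uv <- w %*% vert
  data.frame(u = uv[, 1L], v = uv[, 2L])
}
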