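#' Simulate stochastic cassette recombination
#'
#' Draws per-cell cassette states under the Cre-lox model: each of the
#' `nCassettes` independent cassettes expresses red unless it recombines
#' (with probability `pRecomb` during induction, or `pLeaky`
#' spontaneously), in which case it switches to green with probability
#' `pGreen`, otherwise blue. The derived color class of a cell follows from
#' the set of colors expressed across its cassettes; a cell is trichromatic
#' exactly when that set is \{red, green, blue\}, which requires at least
#' two independent recombination events and is therefore rare at low
#' recombination probability -- the basis for sparse clonal labeling.
#'
#' @param cfg a [RecombinationConfig-class].
#' @param nCells number of cells to draw (>= 0).
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return A list with `cassettes`, an `nCells` x `nCassettes` character
#'   matrix with entries "R", "G" or "B", and `colorClass`, a factor with
#'   levels `red_only`, `monochromatic`, `dichromatic`, `trichromatic`
#'   (`monochromatic` marks the fully-recombined single-color case).
#' @examples
#' sim <- simulateRecombination(recombinationConfig(pRecomb = 0.5), 10, seed = 1)
#' table(sim$colorClass)
#' @export
simulateRecombination <- function(cfg, nCells, seed) {
  stopifnot(is(cfg, "RecombinationConfig"))
  validObject(cfg)
  if (!is.numeric(nCells) || length(nCells) != 1L || nCells < 0)
    stop("nCells must be a single nonnegative integer", call. = FALSE)
  nCells <- as.integer(nCells)
  k <- cfg@nCassettes
  cassettes <- .withSeed(seed, {
    pAny <- 1 - (1 - cfg@pRecomb) * (1 - cfg@pLeaky)
    recombined <- matrix(stats::runif(nCells * k) < pAny, nCells, k)
    green <- matrix(stats::runif(nCells * k) < cfg@pGreen, nCells, k)
    m <- matrix("R", nrow = nCells, ncol = k)
    m[recombined & green] <- "G"
    m[recombined & !green] <- "B"
    m
  })
  list(cassettes = cassettes, colorClass = classifyColor(cassettes))
}

#' @rdname simulateRecombination
#' @param cassettes character matrix of cassette states ("R"/"G"/"B").
#' @export
classifyColor <- function(cassettes) {
  cassettes <- as.matrix(cassettes)
  cls <- apply(cassettes, 1L, function(s) {
    colors <- unique(s)
    if (length(colors) == 3L) "trichromatic"
    else if (length(colors) == 2L) "dichromatic"
    else if (colors == "R") "red_only"
    else "monochromatic"
  })
  factor(cls, levels = c("red_only", "monochromatic", "dichromatic",
                         "trichromatic"))
}

# Per-founder channel intensities: each cassette carries a lognormal
# expression level; a channel's true intensity is the summed level of the
# cassettes expressing that color. This gives continuous, heritable
# barcodes, matching the continuous spread of signatures on ternary plots.
.founderIntensities <- function(cassettes, meanlog = log(60), sdlog = 0.35) {
  n <- nrow(cassettes); k <- ncol(cassettes)
  lev <- matrix(stats::rlnorm(n * k, meanlog, sdlog), n, k)
  out <- sapply(c("R", "G", "B"), function(col)
    rowSums(lev * (cassettes == col)))
  matrix(out, nrow = n, dimnames = list(NULL, c("R", "G", "B")))
}

.normSig <- function(intensity) {
  s <- rowSums(intensity)
  100 * intensity / s
}

# Well-separated signature targets on the color simplex: greedy
# farthest-point selection (Linf metric) over a coarse grid with every
# channel at least 10%, starting from a red-dominant corner. Used when a
# caller asks for separable founder barcodes.
.separatedTargets <- function(k) {
  g <- expand.grid(r = seq(10, 80, by = 5), g = seq(10, 80, by = 5))
  g$b <- 100 - g$r - g$g
  g <- as.matrix(g[g$b >= 10, , drop = FALSE])
  chosen <- matrix(c(80, 10, 10), 1L, dimnames = list(NULL, c("r", "g", "b")))
  while (nrow(chosen) < k) {
    dmin <- apply(g, 1L, function(p)
      min(apply(chosen, 1L, function(q) max(abs(p - q)))))
    chosen <- rbind(chosen, g[which.max(dmin), ])
  }
  unname(chosen[seq_len(k), , drop = FALSE])
}

# Smallest pairwise Linf distance between normalized signatures.
.minSep <- function(intensity) {
  if (nrow(intensity) < 2L) return(Inf)
  sig <- .normSig(intensity)
  d <- Inf
  for (i in seq_len(nrow(sig) - 1L))
    for (j in seq(i + 1L, nrow(sig)))
      d <- min(d, max(abs(sig[i, ] - sig[j, ])))
  d
}

#' Simulate a multicolor-labeled islet with ground truth
#'
#' Builds one islet the way the clonal-tracing experiment sees it. Founder
#' beta-cells recombine at the first stage; a quiescent fraction never
#' divides while the rest proliferate as a discrete-generation branching
#' process (each proliferative cell gains `Poisson(divisionRate)` daughters
#' per inter-stage interval), daughters inheriting the mother's cassette
#' states and expression levels exactly. Per interval, `neogenesisRate`
#' unrecombined (red-only) post-embryonic cells join the islet. Cells are
#' placed in a prolate ellipsoid whose long axis is the A/P axis;
#' embryonic-lineage cells are biased to the posterior half and
#' post-embryonic cells to the anterior half, reproducing the hourglass
#' age polarity of the growing islet. Measured channel statistics are the
#' empirical mean and sd of simulated ROI pixels (`n_pixels` drawn from
#' the configured range) around the true channel intensities.
#'
#' @param growth a [GrowthConfig-class].
#' @param recomb a [RecombinationConfig-class].
#' @param noise a [NoiseConfig-class].
#' @param seed integer seed.
#' @param isletId islet identifier written into both tables.
#' @param apBias probability that a cell lands in the half of the islet
#'   its lineage prefers (posterior for embryonic, anterior for
#'   post-embryonic).
#' @param responderProb length-2 named numeric, probability that a cell is
#'   a true glucose responder by half (`anterior`, `posterior`); defaults
#'   to the 25 dpf-like asymmetry (0.34 anterior, 0.67 posterior).
#' @param minSignatureSep if > 0, founder expression levels are redrawn
#'   until all pairs of trichromatic founders differ by at least this many
#'   percentage points (Linf on the normalized scale). Use to generate
#'   well-separated barcode cohorts for recovery benchmarks; 0 disables.
#' @param fillFraction packing fraction of total cell volume inside the
#'   ellipsoid; controls crowding.
#' @return A list with `cells`, the measurement data.frame (columns
#'   `cell_id`, `islet_id`, `stage_dpf`, `r_mean`, `g_mean`, `b_mean`,
#'   `r_sd`, `g_sd`, `b_sd`, `n_pixels`, `x`, `y`, `z`), and `truth`, the
#'   per-cell ground-truth data.frame (`clone_id`, `lineage`,
#'   `birth_stage`, `responder`, `h2b_retained`, true intensities, volume,
#'   cassette states, `color_class`).
#' @examples
#' isl <- simulateIslet(growthConfig(nFounders = 10, stages = c(3.5, 15)),
#'                      recombinationConfig(pRecomb = 0.5),
#'                      noiseConfig(), seed = 1)
#' head(isl$cells)
#' @export
simulateIslet <- function(growth, recomb, noise, seed, isletId = "islet_1",
                          apBias = 0.9, responderProb = c(anterior = 0.34,
                                                          posterior = 0.67),
                          minSignatureSep = 0, fillFraction = 0.12) {
  stopifnot(is(growth, "GrowthConfig"), is(recomb, "RecombinationConfig"),
            is(noise, "NoiseConfig"))
  validObject(growth); validObject(recomb); validObject(noise)
  .checkProb(apBias, "apBias")
  .withSeed(seed, {
    nf <- growth@nFounders
    k <- recomb@nCassettes
    pAny <- 1 - (1 - recomb@pRecomb) * (1 - recomb@pLeaky)
    recombined <- matrix(stats::runif(nf * k) < pAny, nf, k)
    green <- matrix(stats::runif(nf * k) < recomb@pGreen, nf, k)
    cass <- matrix("R", nf, k)
    cass[recombined & green] <- "G"
    cass[recombined & !green] <- "B"

    intensity <- .founderIntensities(cass)
    if (minSignatureSep > 0 && nf > 0L) {
      tri <- which(classifyColor(cass) == "trichromatic")
      if (length(tri) > 1L) {
        targets <- .separatedTargets(length(tri))
        targets <- targets + matrix(stats::runif(length(targets), -1, 1),
                                    nrow(targets))
        targets <- 100 * targets / rowSums(targets)
        if (.minSep(targets) < minSignatureSep)
          warning("achieved founder signature separation ",
                  round(.minSep(targets), 1), " is below the requested ",
                  minSignatureSep)
        total <- stats::rlnorm(length(tri), log(180), 0.15)
        intensity[tri, ] <- targets * total / 100
      }
    }

    quiescent <- stats::runif(nf) < growth@quiescentFraction

    # Cell ledger grown interval by interval; daughters inherit founder row.
    founder <- seq_len(nf)
    birth <- rep(growth@stages[1L], nf)
    lineage <- rep("embryonic", nf)
    proliferative <- !quiescent
    nextNeo <- nf
    for (iv in seq_along(growth@stages)[-1L]) {
      stage <- growth@stages[iv]
      idx <- which(proliferative)
      if (length(idx) && growth@divisionRate > 0) {
        extra <- stats::rpois(length(idx), growth@divisionRate)
        rep_idx <- rep(idx, extra)
        if (length(rep_idx)) {
          founder <- c(founder, founder[rep_idx])
          birth <- c(birth, rep(stage, length(rep_idx)))
          lineage <- c(lineage, lineage[rep_idx])
          proliferative <- c(proliferative, rep(TRUE, length(rep_idx)))
        }
      }
      nNeo <- stats::rpois(1L, growth@neogenesisRate)
      if (nNeo > 0L) {
        founder <- c(founder, seq.int(nextNeo + 1L, nextNeo + nNeo))
        nextNeo <- nextNeo + nNeo
        birth <- c(birth, rep(stage, nNeo))
        lineage <- c(lineage, rep("post_embryonic", nNeo))
        proliferative <- c(proliferative, rep(FALSE, nNeo))
      }
    }
    nCell <- length(founder)
    isNeo <- lineage == "post_embryonic"

    # Founder rows for neogenesis cells: unrecombined, pure red.
    neoIds <- unique(founder[isNeo])
    if (length(neoIds)) {
      neoCass <- matrix("R", length(neoIds), k)
      cass <- rbind(cass, neoCass)
      intensity <- rbind(intensity, .founderIntensities(neoCass))
    }

    # Geometry: prolate ellipsoid, long (A/P) axis = x, anterior = x < 0.
    totalVol <- nCell * growth@meanCellVolume
    a <- (3 * totalVol / fillFraction / pi)^(1 / 3)
    b <- a / 2
    u <- matrix(stats::runif(3L * nCell, -1, 1), ncol = 3L)
    bad <- rowSums(u^2) > 1
    while (any(bad)) {
      u[bad, ] <- stats::runif(3L * sum(bad), -1, 1)
      bad <- rowSums(u^2) > 1
    }
    pos <- cbind(x = u[, 1L] * a, y = u[, 2L] * b, z = u[, 3L] * b)
    # Posterior = x > 0. Flip each cell into its lineage's preferred half
    # with probability apBias.
    wantPosterior <- ifelse(isNeo, stats::runif(nCell) > apBias,
                            stats::runif(nCell) < apBias)
    flip <- (pos[, "x"] > 0) != wantPosterior
    pos[flip, "x"] <- -pos[flip, "x"]

    volume <- pmax(stats::rnorm(nCell, growth@meanCellVolume,
                                growth@sdCellVolume),
                   growth@meanCellVolume / 4)

    posterior <- pos[, "x"] > 0
    pResp <- ifelse(posterior, responderProb[["posterior"]],
                    responderProb[["anterior"]])
    responder <- stats::runif(nCell) < pResp

    trueInt <- intensity[founder, , drop = FALSE]
    nPix <- sample.int(noise@pixelsPerCellRange[2L] -
                         noise@pixelsPerCellRange[1L] + 1L,
                       nCell, replace = TRUE) +
      noise@pixelsPerCellRange[1L] - 1L

    meas <- matrix(0, nCell, 6L)
    for (ch in 1:3) {
      level <- trueInt[, ch] + noise@backgroundMean[ch]
      for (i in seq_len(nCell)) {
        px <- stats::rnorm(nPix[i], level[i], noise@pixelSd[ch])
        meas[i, ch] <- max(0, mean(px))
        meas[i, ch + 3L] <- stats::sd(px)
      }
    }

    cellId <- sprintf("%s_c%04d", isletId, seq_len(nCell))
    stageFinal <- growth@stages[length(growth@stages)]
    cells <- data.frame(
      cell_id = cellId, islet_id = isletId, stage_dpf = stageFinal,
      r_mean = meas[, 1L], g_mean = meas[, 2L], b_mean = meas[, 3L],
      r_sd = meas[, 4L], g_sd = meas[, 5L], b_sd = meas[, 6L],
      n_pixels = nPix, x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
      stringsAsFactors = FALSE)
    truth <- data.frame(
      cell_id = cellId, islet_id = isletId,
      clone_id = sprintf("%s_f%04d", isletId, founder),
      lineage = lineage, birth_stage = birth,
      responder = responder, h2b_retained = lineage == "embryonic",
      x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
      volume_um3 = volume,
      true_r = trueInt[, "R"], true_g = trueInt[, "G"],
      true_b = trueInt[, "B"],
      cassette_states = apply(cass[founder, , drop = FALSE], 1L, paste,
                              collapse = ""),
      color_class = as.character(classifyColor(cass[founder, ,
                                                    drop = FALSE])),
      stringsAsFactors = FALSE)
    list(cells = cells, truth = truth)
  })
}

#' Simulate GCaMP calcium traces with known responder status
#'
#' Phenomenological trace model for a cohort with ground truth: every cell
#' sits at a baseline fluorescence during the basal phase; true responders
#' add a sustained plateau during glucose phases; all cells except a
#' configurable QC-fail fraction show their trace maximum after KCl
#' depolarization. No biophysical calcium dynamics are modeled.
#'
#' @param truth data.frame with at least `cell_id` and logical `responder`;
#'   optional logical `qc_fail` (drawn from `qcFailFraction` when absent)
#'   and `region`. Use [calciumCohortTruth()] for a standalone cohort.
#' @param protocol a [StimulusProtocol-class].
#' @param noiseSd additive Gaussian noise sd on the raw trace (a.u.).
#' @param seed integer seed.
#' @param dt sampling interval, seconds.
#' @param baseline,glucoseAmp,kclAmp raw-scale levels: basal fluorescence,
#'   responder plateau height during glucose, and KCl peak height.
#' @param qcFailFraction probability a cell shows no KCl enhancement (used
#'   only when `truth` lacks a `qc_fail` column).
#' @return A list with `traces`, a long data.frame (`cell_id`,
#'   `t_seconds`, `fluorescence`), and `truth`, the input truth augmented
#'   with `qc_fail`.
#' @examples
#' tr <- simulateCalciumTraces(calciumCohortTruth(5, 0.6, seed = 1),
#'                             glucoseRampProtocol(), noiseSd = 1, seed = 2)
#' head(tr$traces)
#' @export
simulateCalciumTraces <- function(truth, protocol, noiseSd = 2, seed,
                                  dt = 2, baseline = 50, glucoseAmp = 30,
                                  kclAmp = 80, qcFailFraction = 0.05) {
  stopifnot(is.data.frame(truth), is(protocol, "StimulusProtocol"),
            all(c("cell_id", "responder") %in% names(truth)),
            noiseSd >= 0)
  validObject(protocol)
  ph <- phases(protocol)
  .withSeed(seed, {
    if (!"qc_fail" %in% names(truth))
      truth$qc_fail <- stats::runif(nrow(truth)) < qcFailFraction
    tGrid <- seq(min(ph$t_start), max(ph$t_end) - dt / 2, by = dt)
    glucose <- ph$label != "basal" & ph$label != "kcl"
    inGlucose <- rep(FALSE, length(tGrid))
    for (i in which(glucose))
      inGlucose <- inGlucose | (tGrid >= ph$t_start[i] & tGrid < ph$t_end[i])
    kclRow <- which(ph$label == "kcl")
    inKcl <- tGrid >= ph$t_start[kclRow] & tGrid < ph$t_end[kclRow]
    traces <- lapply(seq_len(nrow(truth)), function(i) {
      f <- rep(baseline, length(tGrid))
      if (!truth$qc_fail[i]) {
        if (truth$responder[i]) f[inGlucose] <- f[inGlucose] + glucoseAmp
        f[inKcl] <- f[inKcl] + kclAmp
      }
      f <- f + stats::rnorm(length(tGrid), 0, noiseSd)
      data.frame(cell_id = truth$cell_id[i], t_seconds = tGrid,
                 fluorescence = f, stringsAsFactors = FALSE)
    })
    list(traces = do.call(rbind, traces), truth = truth)
  })
}

#' @rdname simulateCalciumTraces
#' @param nCells cohort size.
#' @param responderProb probability a cell is a true glucose responder.
#' @param regionSplit fraction of cells assigned to the posterior half.
#' @export
calciumCohortTruth <- function(nCells, responderProb = 0.6, seed,
                               regionSplit = 0.5,
                               qcFailFraction = 0.05) {
  .checkProb(responderProb, "responderProb")
  .withSeed(seed, {
    region <- ifelse(stats::runif(nCells) < regionSplit, "posterior",
                     "anterior")
    data.frame(
      cell_id = sprintf("cell_%04d", seq_len(nCells)),
      region = region,
      responder = stats::runif(nCells) < responderProb,
      qc_fail = stats::runif(nCells) < qcFailFraction,
      stringsAsFactors = FALSE)
  })
}
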