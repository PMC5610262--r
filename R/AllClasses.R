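#' @import methods
NULL

## Central S4 containers. Tables (per-cell measurements, object tables,
## long-format traces) stay plain data.frames matching the CSV schemas in
## the I/O layer; S4 is reserved for objects with invariants worth guarding.

#' Recombination configuration for the cassette simulator
#'
#' Parameters of the stochastic Cre-lox recombination model. A cell carries
#' `nCassettes` independent cassettes, each expressing red by default.
#' During induction each cassette recombines with probability `pRecomb`,
#' switching its expression to green (probability `pGreen` given
#' recombination) or blue. `pLeaky` is the per-cassette probability of a
#' spontaneous (non-induced) recombination event, the quantity behind
#' background recombination estimates.
#'
#' @slot nCassettes integer, number of independent cassettes per cell.
#' @slot pRecomb numeric in \[0,1\], induced per-cassette recombination
#'   probability.
#' @slot pGreen numeric in \[0,1\], probability a recombined cassette
#'   switches to green (otherwise blue).
#' @slot pLeaky numeric in \[0,1\], per-cassette leaky recombination
#'   probability.
#' @export
setClass("RecombinationConfig",
  representation(nCassettes = "integer", pRecomb = "numeric",
                 pGreen = "numeric", pLeaky = "numeric"),
  prototype(nCassettes = 3L, pRecomb = 0.15, pGreen = 0.5, pLeaky = 0))

setValidity("RecombinationConfig", function(object) {
  msg <- character()
  if (length(object@nCassettes) != 1L || is.na(object@nCassettes) ||
      object@nCassettes < 1L)
    msg <- c(msg, "nCassettes must be a single integer >= 1")
  for (p in c("pRecomb", "pGreen", "pLeaky")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single probability in [0,1]", p))
  }
  if (length(msg)) msg else TRUE
})

#' @param nCassettes,pRecomb,pGreen,pLeaky see slot documentation.
#' @return A validated `RecombinationConfig`.
#' @rdname RecombinationConfig-class
#' @examples
#' recombinationConfig(nCassettes = 3, pRecomb = 0.5)
#' @export
recombinationConfig <- function(nCassettes = 3, pRecomb = 0.15,
                                pGreen = 0.5, pLeaky = 0) {
  new("RecombinationConfig", nCassettes = as.integer(nCassettes),
      pRecomb = pRecomb, pGreen = pGreen, pLeaky = pLeaky)
}

#' Growth configuration for the islet simulator
#'
#' Describes clonal proliferation across developmental stages. Founders are
#' the recombination-labeled embryonic beta-cells present at the first
#' stage; a `quiescentFraction` of them never divide (they remain single
#' cells, the quiescent population seen in clonal tracing), the rest divide
#' as a discrete-generation branching process with `divisionRate` expected
#' divisions per cell per inter-stage interval. `neogenesisRate` unlabeled
#' (red-only) cells differentiate per interval and are placed anteriorly,
#' emulating the post-embryonic progenitor contribution that polarizes the
#' islet along its A/P axis.
#'
#' @slot nFounders integer, number of embryonic founder cells.
#' @slot quiescentFraction numeric in \[0,1\].
#' @slot divisionRate numeric >= 0, expected divisions per proliferative
#'   cell per interval.
#' @slot stages numeric vector of timepoints in days post-fertilization.
#' @slot neogenesisRate numeric >= 0, new unlabeled cells per interval.
#' @slot meanCellVolume,sdCellVolume numeric, cell volume distribution in
#'   cubic micrometers.
#' @export
setClass("GrowthConfig",
  representation(nFounders = "integer", quiescentFraction = "numeric",
                 divisionRate = "numeric", stages = "numeric",
                 neogenesisRate = "numeric", meanCellVolume = "numeric",
                 sdCellVolume = "numeric"),
  prototype(nFounders = 30L, quiescentFraction = 0.4, divisionRate = 0.5,
            stages = c(3.5, 15, 30), neogenesisRate = 50,
            meanCellVolume = 185, sdCellVolume = 35))

setValidity("GrowthConfig", function(object) {
  msg <- character()
  if (object@nFounders < 0L) msg <- c(msg, "nFounders must be >= 0")
  if (object@quiescentFraction < 0 || object@quiescentFraction > 1)
    msg <- c(msg, "quiescentFraction must be in [0,1]")
  if (object@divisionRate < 0) msg <- c(msg, "divisionRate must be >= 0")
  if (length(object@stages) < 1L || is.unsorted(object@stages, strictly = TRUE))
    msg <- c(msg, "stages must be strictly increasing timepoints")
  if (object@neogenesisRate < 0) msg <- c(msg, "neogenesisRate must be >= 0")
  if (object@meanCellVolume <= 0 || object@sdCellVolume < 0)
    msg <- c(msg, "cell volumes must be positive (sd >= 0)")
  if (length(msg)) msg else TRUE
})

#' @param nFounders,quiescentFraction,divisionRate,stages,neogenesisRate
#'   see slot documentation.
#' @param meanCellVolume,sdCellVolume cell volume distribution, um^3.
#' @return A validated `GrowthConfig`.
#' @rdname GrowthConfig-class
#' @export
growthConfig <- function(nFounders = 30, quiescentFraction = 0.4,
                         divisionRate = 0.5, stages = c(3.5, 15, 30),
                         neogenesisRate = 50, meanCellVolume = 185,
                         sdCellVolume = 35) {
  new("GrowthConfig", nFounders = as.integer(nFounders),
      quiescentFraction = quiescentFraction, divisionRate = divisionRate,
      stages = as.numeric(stages), neogenesisRate = neogenesisRate,
      meanCellVolume = meanCellVolume, sdCellVolume = sdCellVolume)
}

#' Measurement-noise configuration
#'
#' Controls the simulated imaging noise: additive Gaussian pixel noise per
#' channel, background offsets, and the per-cell ROI size range from which
#' the pixel count `n_pixels` (the TOST sample size) is drawn.
#'
#' @slot pixelSd numeric length 3 (R,G,B), additive pixel noise sd (a.u.).
#' @slot backgroundMean numeric length 3, channel background means (a.u.).
#' @slot pixelsPerCellRange integer length 2, inclusive ROI size range;
#'   minimum at least 3 so a pixel sd is always defined.
#' @export
setClass("NoiseConfig",
  representation(pixelSd = "numeric", backgroundMean = "numeric",
                 pixelsPerCellRange = "integer"),
  prototype(pixelSd = c(4, 4, 4), backgroundMean = c(2, 2, 2),
            pixelsPerCellRange = c(30L, 80L)))

setValidity("NoiseConfig", function(object) {
  msg <- character()
  if (length(object@pixelSd) != 3L || any(object@pixelSd < 0))
    msg <- c(msg, "pixelSd must be 3 nonnegative values (R,G,B)")
  if (length(object@backgroundMean) != 3L || any(object@backgroundMean < 0))
    msg <- c(msg, "backgroundMean must be 3 nonnegative values (R,G,B)")
  r <- object@pixelsPerCellRange
  if (length(r) != 2L || r[1] > r[2] || r[1] < 3L)
    msg <- c(msg, "pixelsPerCellRange must be a nonempty range with min >= 3")
  if (length(msg)) msg else TRUE
})

#' @param pixelSd,backgroundMean,pixelsPerCellRange see slot documentation.
#' @return A validated `NoiseConfig`.
#' @rdname NoiseConfig-class
#' @export
noiseConfig <- function(pixelSd = c(4, 4, 4), backgroundMean = c(2, 2, 2),
                        pixelsPerCellRange = c(30, 80)) {
  new("NoiseConfig", pixelSd = rep_len(as.numeric(pixelSd), 3L),
      backgroundMean = rep_len(as.numeric(backgroundMean), 3L),
      pixelsPerCellRange = as.integer(pixelsPerCellRange))
}

#' TOST equivalence-test parameters
#'
#' The equivalence margin and significance level used when testing whether
#' two cells share a color barcode. The margin is expressed in percentage
#' points on the normalized (r+g+b = 100) scale and applied per channel.
#' The margin is a mandatory analysis choice: it is echoed into every clone
#' table and manifest this package writes.
#'
#' @slot marginPct numeric > 0, equivalence half-width per channel in
#'   percentage points.
#' @slot alpha numeric in (0,1), per-test significance level.
#' @slot bonferroni logical; if TRUE, alpha is divided by the number of
#'   pairs tested within an islet. Off by default: the original procedure
#'   tests each pair at p < 0.05 without correction.
#' @export
setClass("TostParams",
  representation(marginPct = "numeric", alpha = "numeric",
                 bonferroni = "logical"),
  prototype(marginPct = 10, alpha = 0.05, bonferroni = FALSE))

setValidity("TostParams", function(object) {
  msg <- character()
  if (length(object@marginPct) != 1L || object@marginPct <= 0)
    msg <- c(msg, "marginPct must be a single positive number")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @param marginPct,alpha,bonferroni see slot documentation.
#' @return A validated `TostParams`.
#' @rdname TostParams-class
#' @examples
#' tostParams(marginPct = 10, alpha = 0.05)
#' @export
tostParams <- function(marginPct = 10, alpha = 0.05, bonferroni = FALSE) {
  new("TostParams", marginPct = marginPct, alpha = alpha,
      bonferroni = bonferroni)
}

#' Clone clustering result
#'
#' Partition of the triple-positive cells of one islet into clones:
#' connected components of the pairwise TOST-equivalence graph. Cells that
#' failed the triple-positive criterion are excluded from clustering and
#' kept in `excluded`.
#'
#' @slot isletId character scalar.
#' @slot clones list of character vectors of cell ids; disjoint.
#' @slot excluded character vector of non-triple-positive cell ids.
#' @slot params the `TostParams` used.
#' @export
setClass("CloneSet",
  representation(isletId = "character", clones = "list",
                 excluded = "character", params = "TostParams"))

setValidity("CloneSet", function(object) {
  ids <- unlist(object@clones, use.names = FALSE)
  msg <- character()
  if (anyDuplicated(ids))
    msg <- c(msg, "clones must be disjoint sets of cell ids")
  if (any(lengths(object@clones) == 0L))
    msg <- c(msg, "clones must be nonempty")
  if (length(intersect(ids, object@excluded)))
    msg <- c(msg, "a cell cannot be both clustered and excluded")
  if (length(msg)) msg else TRUE
})

#' @rdname CloneSet-class
#' @param object,x a `CloneSet`.
#' @export
setMethod("show", "CloneSet", function(object) {
  sz <- cloneSizes(object)
  cat("CloneSet for islet", object@isletId, "\n")
  cat("  ", length(sz), "clones (", sum(sz == 1L), "single-cell,",
      sum(sz > 1L), "multicellular ),", sum(sz), "cells\n")
  cat("  ", length(object@excluded), "cells excluded (not triple-positive)\n")
  cat("   margin =", object@params@marginPct, "pct, alpha =",
      object@params@alpha, "\n")
})

#' @rdname CloneSet-class
#' @export
nClones <- function(x) length(x@clones)

#' @rdname CloneSet-class
#' @export
cloneSizes <- function(x) lengths(x@clones)

#' @rdname CloneSet-class
#' @export
clones <- function(x) x@clones

#' @rdname CloneSet-class
#' @export
excludedCells <- function(x) x@excluded

#' Stimulus protocol for calcium imaging
#'
#' Ordered, non-overlapping stimulation phases: exactly one basal phase
#' first (5 mM glucose in the standard ramp) and exactly one KCl
#' depolarization phase last; glucose steps in between.
#'
#' @slot phases data.frame with columns `label` (one of basal, glucose_7.5,
#'   glucose_10, glucose_20, kcl), `concentration_mM`, `t_start`, `t_end`
#'   (seconds).
#' @export
setClass("StimulusProtocol", representation(phases = "data.frame"))

setValidity("StimulusProtocol", function(object) {
  ph <- object@phases
  msg <- character()
  need <- c("label", "concentration_mM", "t_start", "t_end")
  if (!all(need %in% names(ph)))
    return(paste("phases must have columns:", paste(need, collapse = ", ")))
  if (nrow(ph) < 2L) msg <- c(msg, "need at least a basal and a kcl phase")
  if (any(ph$t_end <= ph$t_start)) msg <- c(msg, "phases must have t_end > t_start")
  if (nrow(ph) > 1L && any(ph$t_start[-1L] < ph$t_end[-nrow(ph)]))
    msg <- c(msg, "phases must be ordered and non-overlapping")
  if (sum(ph$label == "basal") != 1L || ph$label[1L] != "basal")
    msg <- c(msg, "exactly one basal phase, and it must come first")
  if (sum(ph$label == "kcl") != 1L || ph$label[nrow(ph)] != "kcl")
    msg <- c(msg, "exactly one kcl phase, and it must come last")
  if (length(msg)) msg else TRUE
})

#' @param phases data.frame of phases; see slot documentation.
#' @return A validated `StimulusProtocol`.
#' @rdname StimulusProtocol-class
#' @examples
#' glucoseRampProtocol()
#' @export
stimulusProtocol <- function(phases) {
  new("StimulusProtocol", phases = as.data.frame(phases))
}

#' @rdname StimulusProtocol-class
#' @export
phases <- function(x) x@phases

#' @rdname StimulusProtocol-class
#' @details `glucoseRampProtocol()` builds the standard ex vivo ramp:
#' 5 mM basal, then 10 and 20 mM glucose, then 30 mM KCl depolarization.
#' @param basalLen,phaseLen phase durations in seconds.
#' @export
glucoseRampProtocol <- function(basalLen = 120, phaseLen = 120) {
  t0 <- c(0, basalLen, basalLen + phaseLen, basalLen + 2 * phaseLen)
  stimulusProtocol(data.frame(
    label = c("basal", "glucose_10", "glucose_20", "kcl"),
    concentration_mM = c(5, 10, 20, 30),
    t_start = t0, t_end = t0 + c(basalLen, phaseLen, phaseLen, phaseLen)))
}

#' @rdname StimulusProtocol-class
#' @export
setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol with", nrow(object@phases), "phases:\n")
  print(object@phases, row.names = FALSE)
})

#' Baseline-normalized calcium trace
#'
#' Result of normalizing a raw GCaMP trace against its basal-glucose
#' baseline: `fNorm = (F - F0) / (Fmax - F0)` where `F0` is the mean raw
#' fluorescence over the basal phase and `Fmax` the global trace maximum.
#' Flat traces (`Fmax <= F0`) are flagged rather than rejected so cohort
#' processing never stops on a degenerate cell.
#'
#' @slot cellId character scalar.
#' @slot t,f,fNorm numeric vectors: time (s), raw and normalized
#'   fluorescence.
#' @slot f0,fMax numeric scalars; `basalSd` is the sd of raw F over the
#'   basal phase (used by QC and responder thresholds).
#' @slot flat logical flag for degenerate traces.
#' @export
setClass("NormalizedTrace",
  representation(cellId = "character", t = "numeric", f = "numeric",
                 fNorm = "numeric", f0 = "numeric", fMax = "numeric",
                 basalSd = "numeric", flat = "logical"))

setValidity("NormalizedTrace", function(object) {
  if (length(object@t) != length(object@f) ||
      length(object@t) != length(object@fNorm))
    return("t, f and fNorm must have equal length")
  if (is.unsorted(object@t, strictly = TRUE))
    return("t must be strictly increasing")
  TRUE
})

#' @rdname NormalizedTrace-class
#' @param object a `NormalizedTrace`.
#' @export
setMethod("show", "NormalizedTrace", function(object) {
  cat("NormalizedTrace for cell", object@cellId, ":", length(object@t),
      "samples, F0 =", signif(object@f0, 4), ", Fmax =",
      signif(object@fMax, 4), if (object@flat) "[flat]" else "", "\n")
})

#' Anterior/posterior islet partition
#'
#' Split of an islet into anterior and posterior halves on the (x,y)
#' maximum-intensity-projection plane: the divider is the line
#' perpendicular to the anterior-posterior tip segment at its midpoint.
#' Cells exactly on the divider are assigned anterior (fixed tie-break).
#'
#' @slot anteriorTip,posteriorTip,midpoint numeric length-2 (x,y) points.
#' @slot assignment factor with levels anterior/posterior, named by cell id.
#' @export
setClass("ApPartition",
  representation(anteriorTip = "numeric", posteriorTip = "numeric",
                 midpoint = "numeric", assignment = "factor"))

setValidity("ApPartition", function(object) {
  msg <- character()
  if (isTRUE(all.equal(object@anteriorTip, object@posteriorTip)))
    msg <- c(msg, "anterior and posterior tips must be distinct")
  mid <- (object@anteriorTip + object@posteriorTip) / 2
  if (max(abs(object@midpoint - mid)) > 1e-8)
    msg <- c(msg, "midpoint must be the midpoint of the tip segment")
  if (!identical(levels(object@assignment), c("anterior", "posterior")))
    msg <- c(msg, "assignment levels must be anterior, posterior")
  if (length(msg)) msg else TRUE
})

#' @rdname ApPartition-class
#' @param object a `ApPartition`.
#' @export
setMethod("show", "ApPartition", function(object) {
  tab <- table(object@assignment)
  cat("ApPartition:", tab[["anterior"]], "anterior /", tab[["posterior"]],
      "posterior cells\n")
  cat("  A tip (", paste(signif(object@anteriorTip, 4), collapse = ", "),
      ") -> P tip (", paste(signif(object@posteriorTip, 4), collapse = ", "),
      ")\n")
})

#' @rdname ApPartition-class
#' @param x a `ApPartition`.
#' @export
halfAssignment <- function(x) x@assignment
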