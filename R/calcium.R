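#' Normalize a calcium trace against its basal baseline
#'
#' Computes the standard GCaMP normalization: the baseline `F0` is the
#' mean raw fluorescence over the basal (5 mM glucose) phase, and the
#' trace is rescaled as `(F - F0) / (Fmax - F0)` with `Fmax` the global
#' trace maximum, so the basal mean maps to 0 and the peak (reached after
#' KCl depolarization in a healthy cell) maps to 1. A strictly flat trace
#' (`Fmax <= F0`) cannot be normalized; it is flagged, not an error, so a
#' cohort run continues past degenerate cells.
#'
#' @param t,f numeric vectors: time (seconds, strictly increasing) and raw
#'   fluorescence. Irregularly sampled traces are used as-is; resample
#'   with [resampleTrace()] first if a common grid is needed.
#' @param protocol a [StimulusProtocol-class]; the basal phase must
#'   contain at least 3 samples.
#' @param cellId identifier carried into the result.
#' @return A [NormalizedTrace-class].
#' @examples
#' pr <- glucoseRampProtocol()
#' tt <- seq(0, 479, by = 2)
#' normalizeTrace(tt, 10 + (tt > 360) * 100, pr)
#' @export
normalizeTrace <- function(t, f, protocol, cellId = "cell") {
  stopifnot(is(protocol, "StimulusProtocol"), length(t) == length(f),
            all(is.finite(f)))
  validObject(protocol)
  if (is.unsorted(t, strictly = TRUE))
    stop("t must be strictly increasing", call. = FALSE)
  ph <- phases(protocol)
  basal <- ph[ph$label == "basal", ]
  inBasal <- t >= basal$t_start & t < basal$t_end
  if (sum(inBasal) < 3L)
    stop("basal phase must contain at least 3 samples", call. = FALSE)
  f0 <- mean(f[inBasal])
  basalSd <- stats::sd(f[inBasal])
  fMax <- max(f)
  flat <- fMax <= f0
  fNorm <- if (flat) rep(0, length(f)) else (f - f0) / (fMax - f0)
  new("NormalizedTrace", cellId = as.character(cellId), t = as.numeric(t),
      f = as.numeric(f), fNorm = fNorm, f0 = f0, fMax = fMax,
      basalSd = basalSd, flat = flat)
}

#' @rdname normalizeTrace
#' @details `resampleTrace()` linearly interpolates a trace onto a regular
#' grid; only needed when acquisition timing was irregular.
#' @param dt target sampling interval, seconds.
#' @export
resampleTrace <- function(t, f, dt) {
  stopifnot(length(t) == length(f), dt > 0)
  grid <- seq(min(t), max(t), by = dt)
  data.frame(t = grid, f = stats::approx(t, f, xout = grid)$y)
}

#' KCl quality-control gate
#'
#' Cells that fail to show fluorescence enhancement upon KCl
#' depolarization are excluded from all downstream quantification: the
#' gate passes a cell only when its mean raw fluorescence during the KCl
#' phase exceeds the basal mean by more than `kSd` basal standard
#' deviations (raw scale). Flat traces always fail.
#'
#' @param trace a [NormalizedTrace-class].
#' @param protocol the [StimulusProtocol-class] used to normalize it.
#' @param kSd threshold multiplier on the basal sd.
#' @return TRUE (pass) or FALSE (fail).
#' @export
qcKcl <- function(trace, protocol, kSd = 3) {
  stopifnot(is(trace, "NormalizedTrace"), is(protocol, "StimulusProtocol"),
            kSd >= 0)
  if (trace@flat) return(FALSE)
  ph <- phases(protocol)
  kcl <- ph[ph$label == "kcl", ]
  inKcl <- trace@t >= kcl$t_start & trace@t < kcl$t_end
  if (!any(inKcl)) return(FALSE)
  mean(trace@f[inKcl]) > trace@f0 + kSd * trace@basalSd
}

#' Classify a cell as glucose responder or non-responder
#'
#' A QC-passed cell is a responder when its raw fluorescence exceeds the
#' basal mean by more than `kSd` basal standard deviations for at least a
#' `dwell` fraction of the samples within some glucose phase, while not
#' being active within the basal phase itself (a cell already
#' "responding" at basal glucose is not glucose-stimulated). Basal
#' activity is judged against a separate, fixed multiplier `kSdBasal`, so
#' tightening or loosening the responder threshold `kSd` never changes
#' which cells the basal filter removes: the responder set shrinks
#' monotonically as `kSd` grows. Because all thresholds are built from
#' the trace's own basal statistics, the call is invariant to affine
#' rescaling (gain/offset) of the raw trace.
#'
#' @param trace a [NormalizedTrace-class] that passed [qcKcl()].
#' @param protocol the [StimulusProtocol-class].
#' @param kSd threshold multiplier on the basal sd for the glucose-phase
#'   response.
#' @param dwell minimum fraction of above-threshold samples within a
#'   glucose phase.
#' @param kSdBasal multiplier for the basal-activity exclusion.
#' @return `"responder"` or `"non_responder"`.
#' @export
classifyResponder <- function(trace, protocol, kSd = 3, dwell = 0.1,
                              kSdBasal = 3) {
  stopifnot(is(trace, "NormalizedTrace"), is(protocol, "StimulusProtocol"),
            kSd >= 0, dwell > 0, dwell <= 1, kSdBasal >= 0)
  ph <- phases(protocol)
  basal <- ph[ph$label == "basal", ]
  inBasal <- trace@t >= basal$t_start & trace@t < basal$t_end
  basalActive <- trace@f[inBasal] >
    trace@f0 + kSdBasal * trace@basalSd
  if (mean(basalActive) >= dwell) return("non_responder")
  above <- trace@f > trace@f0 + kSd * trace@basalSd
  glu <- ph[!ph$label %in% c("basal", "kcl"), , drop = FALSE]
  for (i in seq_len(nrow(glu))) {
    inPhase <- trace@t >= glu$t_start[i] & trace@t < glu$t_end[i]
    if (any(inPhase) && mean(above[inPhase]) >= dwell)
      return("responder")
  }
  "non_responder"
}

#' Classify calcium traces of a cohort
#'
#' Convenience wrapper running [normalizeTrace()], [qcKcl()] and
#' [classifyResponder()] over a long-format trace table.
#'
#' @param traces data.frame with `cell_id`, `t_seconds`, `fluorescence`.
#' @param protocol a [StimulusProtocol-class].
#' @param kSdQc,kSdResponder,dwell thresholds passed through to the QC
#'   gate and the responder criterion.
#' @return data.frame with one row per cell: `cell_id`, `qc_pass`,
#'   `call` (`responder` / `non_responder` / `NA` for QC failures),
#'   `f0`, `fmax`, `flat`.
#' @examples
#' sim <- simulateCalciumTraces(calciumCohortTruth(4, 0.5, seed = 1),
#'                              glucoseRampProtocol(), noiseSd = 1, seed = 2)
#' classifyTraces(sim$traces, glucoseRampProtocol())
#' @export
classifyTraces <- function(traces, protocol, kSdQc = 3, kSdResponder = 3,
                           dwell = 0.1) {
  .checkCellTable(traces, need = c("cell_id", "t_seconds", "fluorescence"))
  byCell <- split(traces, traces$cell_id)
  rows <- lapply(byCell, function(tr) {
    tr <- tr[order(tr$t_seconds), ]
    nt <- normalizeTrace(tr$t_seconds, tr$fluorescence, protocol,
                         cellId = tr$cell_id[1L])
    pass <- qcKcl(nt, protocol, kSd = kSdQc)
    data.frame(cell_id = tr$cell_id[1L], qc_pass = pass,
               call = if (pass) classifyResponder(nt, protocol,
                                                  kSd = kSdResponder,
                                                  dwell = dwell)
                      else NA_character_,
               f0 = nt@f0, fmax = nt@fMax, flat = nt@flat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[match(unique(traces$cell_id), out$cell_id), , drop = FALSE]
}

#' Regional responder fractions and posterior/anterior ratio
#'
#' Aggregates per-cell responder calls into the regional statistics used
#' to quantify islet functional asymmetry: the percentage of QC-passed
#' beta-cells responding to glucose in the anterior and posterior halves
#' (per islet, summarized as mean +/- SEM), and the per-islet
#' posterior/anterior responsiveness ratio. When a `stage` column is
#' present the ratios are compared across stages with a Kruskal-Wallis
#' test followed by pairwise two-sided Wilcoxon rank-sum tests. Islets
#' with zero anterior responders get an infinite ratio; they are flagged
#' and excluded from the rank tests with a warning.
#'
#' @param calls data.frame with `cell_id`, `islet_id`, `region`
#'   (`anterior` / `posterior`), `qc_pass`, `call` (from
#'   [classifyTraces()]), and optionally `stage`.
#' @return A list with `per_islet` (islet, stage, pct_anterior,
#'   pct_posterior, ratio_post_over_ant), `summary` (per-stage or overall
#'   mean +/- SEM of the regional percentages), and, when stages are
#'   present, `kruskal_p` and `pairwise_wilcox` on the ratios.
#' @export
regionalResponderStats <- function(calls) {
  .checkCellTable(calls, need = c("cell_id", "islet_id", "region",
                                  "qc_pass", "call"))
  if (!all(calls$region %in% c("anterior", "posterior")))
    stop("region must be 'anterior' or 'posterior'", call. = FALSE)
  keep <- calls[calls$qc_pass, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no QC-passed cells", call. = FALSE)
  hasStage <- "stage" %in% names(keep)
  if (!hasStage) keep$stage <- "all"

  pct <- function(d) 100 * mean(d$call == "responder")
  perIslet <- do.call(rbind, lapply(split(keep, keep$islet_id), function(d) {
    ant <- d[d$region == "anterior", ]
    post <- d[d$region == "posterior", ]
    if (nrow(ant) == 0L || nrow(post) == 0L)
      stop("islet ", d$islet_id[1L],
           " lacks QC-passed cells in one region", call. = FALSE)
    pa <- pct(ant); pp <- pct(post)
    data.frame(islet_id = d$islet_id[1L], stage = d$stage[1L],
               pct_anterior = pa, pct_posterior = pp,
               ratio_post_over_ant = if (pa == 0) Inf else pp / pa,
               stringsAsFactors = FALSE)
  }))
  rownames(perIslet) <- NULL

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- do.call(rbind, lapply(split(perIslet, perIslet$stage),
                                   function(d) data.frame(
    stage = d$stage[1L], n_islets = nrow(d),
    mean_pct_anterior = mean(d$pct_anterior),
    sem_pct_anterior = sem(d$pct_anterior),
    mean_pct_posterior = mean(d$pct_posterior),
    sem_pct_posterior = sem(d$pct_posterior),
    mean_ratio = mean(d$ratio_post_over_ant[
      is.finite(d$ratio_post_over_ant)]),
    stringsAsFactors = FALSE)))
  rownames(summary) <- NULL

  out <- list(per_islet = perIslet, summary = summary)
  if (any(!is.finite(perIslet$ratio_post_over_ant)))
    warning("islet(s) with zero anterior responders: infinite ratio ",
            "flagged and excluded from rank tests")
  if (hasStage && length(unique(perIslet$stage)) > 1L) {
    fin <- perIslet[is.finite(perIslet$ratio_post_over_ant), ]
    out$kruskal_p <- stats::kruskal.test(
      fin$ratio_post_over_ant, factor(fin$stage))$p.value
    stages <- unique(fin$stage)
    pw <- t(utils::combn(stages, 2L))
    out$pairwise_wilcox <- data.frame(
      stage_a = pw[, 1L], stage_b = pw[, 2L],
      p_value = apply(pw, 1L, function(s)
        stats::wilcox.test(
          fin$ratio_post_over_ant[fin$stage == s[1L]],
          fin$ratio_post_over_ant[fin$stage == s[2L]])$p.value),
      stringsAsFactors = FALSE)
  }
  out
}

#' Classify nuclear-label (H2B) retention status
#'
#' Label-dilution call: a cell is H2B-negative when its mean nuclear
#' fluorescence is similar to background, operationalized as
#' `mean_intensity <= background_mean + k * background_sd`. Cells above
#' the band retain the label, i.e. are early-born / low-division cells.
#'
#' @param meanIntensity numeric vector of per-cell mean label intensity.
#' @param backgroundMean,backgroundSd background statistics estimated from
#'   at least 3 unlabeled reference regions.
#' @param k band width in background sds.
#' @return character vector, `"positive"` or `"negative"` per cell.
#' @examples
#' classifyH2bStatus(c(10, 100), backgroundMean = 10, backgroundSd = 2)
#' @export
classifyH2bStatus <- function(meanIntensity, backgroundMean, backgroundSd,
                              k = 2) {
  stopifnot(is.numeric(meanIntensity), backgroundSd >= 0, k >= 0)
  ifelse(meanIntensity <= backgroundMean + k * backgroundSd,
         "negative", "positive")
}
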