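test_that("recombination color classes follow the cassette model", {
  # no recombination: every cell keeps the default red state
  sim0 <- simulateRecombination(recombinationConfig(pRecomb = 0), 50,
                                seed = 1)
  expect_true(all(sim0$colorClass == "red_only"))
  expect_true(all(sim0$cassettes == "R"))

  # one green, one blue, one unrecombined cassette: all three colors
  # expressed -> trichromatic
  expect_equal(as.character(classifyColor(rbind(c("G", "B", "R")))),
               "trichromatic")
  expect_equal(as.character(classifyColor(rbind(c("G", "R", "R")))),
               "dichromatic")
  expect_equal(as.character(classifyColor(rbind(c("G", "G", "G")))),
               "monochromatic")

  # trichromatic iff expressed set is exactly {R,G,B}
  sim <- simulateRecombination(recombinationConfig(pRecomb = 0.5), 500,
                               seed = 2)
  nColors <- apply(sim$cassettes, 1L,
                   function(s) length(unique(s)))
  expect_equal(sim$colorClass == "trichromatic", nColors == 3L)
})

test_that("trichromatic frequency matches exhaustive enumeration", {
  for (k in c(2L, 3L)) {
    cfg <- recombinationConfig(nCassettes = k, pRecomb = 0.5,
                               pGreen = 0.5)
    n <- 1e5
    sim <- simulateRecombination(cfg, n, seed = 7)
    pHat <- mean(sim$colorClass == "trichromatic")
    pTrue <- trichromatic_prob_oracle(k, 0.5, 0.5)
    if (k == 2L) {
      # two cassettes cannot express three colors
      expect_identical(pTrue, 0)
      expect_identical(pHat, 0)
    } else {
      tol <- 3 * sqrt(pTrue * (1 - pTrue) / n)
      expect_lt(abs(pHat - pTrue), tol)
    }
  }
})

test_that("invalid recombination configs are rejected", {
  expect_error(recombinationConfig(pRecomb = 1.2), "probability")
  expect_error(recombinationConfig(nCassettes = 0), "nCassettes")
  expect_error(simulateRecombination(recombinationConfig(), -1, seed = 1),
               "nonnegative")
})

test_that("simulated islets honor inheritance, quiescence and determinism", {
  gAll <- growthConfig(nFounders = 15, quiescentFraction = 1,
                       stages = c(3.5, 15, 30), neogenesisRate = 0)
  rc <- recombinationConfig(pRecomb = 0.6)
  isl <- simulateIslet(gAll, rc, noiseConfig(), seed = 3)
  # quiescent_fraction = 1: every founder stays a singleton clone
  expect_equal(nrow(isl$truth), 15L)
  expect_equal(max(table(isl$truth$clone_id)), 1L)

  gDiv <- growthConfig(nFounders = 40, quiescentFraction = 0,
                       divisionRate = 1, stages = c(3.5, 15),
                       neogenesisRate = 0)
  isl2 <- simulateIslet(gDiv, rc, noiseConfig(), seed = 4)
  expect_gt(max(table(isl2$truth$clone_id)), 1L)
  # all cells of one clone carry the founder cassette states
  states <- tapply(isl2$truth$cassette_states, isl2$truth$clone_id,
                   function(s) length(unique(s)))
  expect_true(all(states == 1L))

  # seed determinism, byte-for-byte at the table level
  islA <- simulateIslet(gDiv, rc, noiseConfig(), seed = 11)
  islB <- simulateIslet(gDiv, rc, noiseConfig(), seed = 11)
  expect_identical(islA, islB)
  islC <- simulateIslet(gDiv, rc, noiseConfig(), seed = 12)
  expect_false(identical(islA$cells, islC$cells))
})

test_that("zero pixel noise gives sisters identical signatures", {
  g <- growthConfig(nFounders = 10, quiescentFraction = 0,
                    divisionRate = 1, stages = c(3.5, 15),
                    neogenesisRate = 0)
  isl <- simulateIslet(g, recombinationConfig(pRecomb = 0.6),
                       noiseConfig(pixelSd = c(0, 0, 0),
                                   backgroundMean = c(0, 0, 0)),
                       seed = 5)
  sig <- normalizeSignature(isl$cells)
  byClone <- split(sig[, c("r_pct", "g_pct", "b_pct")],
                   isl$truth$clone_id)
  multi <- byClone[vapply(byClone, nrow, integer(1)) > 1L]
  expect_gt(length(multi), 0L)
  for (cl in multi)
    expect_lt(max(apply(cl, 2L, function(x) diff(range(x)))), 1e-9)
})

test_that("lineage placement is A/P polarized", {
  g <- growthConfig(nFounders = 50, quiescentFraction = 1,
                    stages = c(3.5, 15, 30), neogenesisRate = 50)
  isl <- simulateIslet(g, recombinationConfig(pRecomb = 0.5),
                       noiseConfig(), seed = 6, apBias = 0.9)
  tr <- isl$truth
  # posterior = x > 0 in the simulator's frame
  expect_gt(mean(tr$x[tr$lineage == "embryonic"] > 0), 0.7)
  expect_gt(mean(tr$x[tr$lineage == "post_embryonic"] < 0), 0.7)
  expect_true(all(tr$lineage %in% c("embryonic", "post_embryonic")))
  # clone ids partition the cells
  expect_false(anyNA(tr$clone_id))
})

test_that("simulated calcium traces encode responder truth", {
  pr <- glucoseRampProtocol()
  truth <- data.frame(cell_id = c("r1", "n1"),
                      responder = c(TRUE, FALSE),
                      qc_fail = c(FALSE, FALSE))
  sim <- simulateCalciumTraces(truth, pr, noiseSd = 0, seed = 1)
  tr <- split(sim$traces, sim$traces$cell_id)
  ph <- phases(pr)
  kclStart <- ph$t_start[ph$label == "kcl"]
  # noise-free non-responder is flat until KCl onset
  pre <- tr$n1[tr$n1$t_seconds < kclStart, "fluorescence"]
  expect_equal(diff(range(pre)), 0)
  # responder: glucose-phase mean strictly above basal mean
  basal <- ph[ph$label == "basal", ]
  g10 <- ph[ph$label == "glucose_10", ]
  inB <- tr$r1$t_seconds >= basal$t_start & tr$r1$t_seconds < basal$t_end
  inG <- tr$r1$t_seconds >= g10$t_start & tr$r1$t_seconds < g10$t_end
  expect_gt(mean(tr$r1$fluorescence[inG]), mean(tr$r1$fluorescence[inB]))
  # every non-QC-fail trace peaks during KCl
  for (d in tr) {
    expect_gte(d$t_seconds[which.max(d$fluorescence)], kclStart)
  }
})
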