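pr <- glucoseRampProtocol()   # basal 0-120, glucose 120-240/240-360, kcl 360-480

test_that("trace normalization follows the (F - F0)/(Fmax - F0) formula", {
  tt <- seq(0, 478, by = 2)
  f <- 10 + (tt >= 360) * 100           # basal 10, peak 110 at KCl
  nt <- normalizeTrace(tt, f, pr)
  expect_equal(nt@f0, 10)
  expect_equal(nt@fMax, 110)
  expect_equal(max(nt@fNorm), 1)
  expect_equal(mean(nt@fNorm[tt < 120]), 0)

  # pointwise equality with the closed formula on a sinusoid
  f2 <- 50 + 20 * sin(tt / 40)
  nt2 <- normalizeTrace(tt, f2, pr)
  f0 <- mean(f2[tt < 120])
  expect_equal(nt2@fNorm, (f2 - f0) / (max(f2) - f0))

  # strictly constant trace: flagged flat, not an error
  flat <- normalizeTrace(tt, rep(5, length(tt)), pr)
  expect_true(flat@flat)
  expect_true(all(flat@fNorm == 0))

  expect_error(normalizeTrace(c(0, 60, 130, 400), c(1, 2, 3, 4), pr),
               "at least 3 samples")
})

test_that("normalization is idempotent on normalized traces", {
  tt <- seq(0, 478, by = 2)
  f <- 10 + 90 * (tt >= 360) + 30 * (tt >= 120 & tt < 360)
  nt <- normalizeTrace(tt, f, pr)
  again <- normalizeTrace(tt, nt@fNorm, pr)
  expect_equal(again@f0, 0)
  expect_equal(again@fMax, 1)
  expect_equal(again@fNorm, nt@fNorm)
})

test_that("KCl QC passes depolarization responses and fails flat cells", {
  tt <- seq(0, 478, by = 2)
  set.seed(9)
  basalNoise <- rnorm(sum(tt < 120), 0, 1)
  f <- rep(50, length(tt)); f[tt < 120] <- 50 + basalNoise
  sdB <- sd(f[tt < 120])
  fPass <- f; fPass[tt >= 360] <- 50 + 10 * sdB
  expect_true(qcKcl(normalizeTrace(tt, fPass, pr), pr, kSd = 3))
  fFlat <- rep(50, length(tt)) + rnorm(length(tt), 0, 0.5)
  nt <- normalizeTrace(tt, fFlat, pr)
  expect_false(qcKcl(nt, pr, kSd = 3))
  expect_false(qcKcl(normalizeTrace(tt, rep(5, length(tt)), pr), pr))
})

test_that("responder calls separate glucose responses from basal activity", {
  sim <- simulateCalciumTraces(
    data.frame(cell_id = c("resp", "non"), responder = c(TRUE, FALSE),
               qc_fail = c(FALSE, FALSE)), pr, noiseSd = 0.5, seed = 10)
  calls <- classifyTraces(sim$traces, pr)
  expect_equal(calls$call[calls$cell_id == "resp"], "responder")
  expect_equal(calls$call[calls$cell_id == "non"], "non_responder")
})

test_that("responder calls are invariant to affine rescaling", {
  sim <- simulateCalciumTraces(calciumCohortTruth(20, 0.5, seed = 11),
                               pr, noiseSd = 2, seed = 12)
  calls <- classifyTraces(sim$traces, pr)
  scaled <- sim$traces
  scaled$fluorescence <- 3.7 * scaled$fluorescence + 120
  calls2 <- classifyTraces(scaled, pr)
  expect_equal(calls$call, calls2$call)
  expect_equal(calls$qc_pass, calls2$qc_pass)
})

test_that("responder calls are monotone in the threshold multiplier", {
  sim <- simulateCalciumTraces(calciumCohortTruth(30, 0.5, seed = 13),
                               pr, noiseSd = 8, seed = 14)
  byCell <- split(sim$traces, sim$traces$cell_id)
  nCalls <- sapply(c(0, 1, 3, 6, 1e6), function(k) {
    sum(sapply(byCell, function(d) {
      nt <- normalizeTrace(d$t_seconds, d$fluorescence, pr)
      qcKcl(nt, pr, kSd = 3) &&
        classifyResponder(nt, pr, kSd = k) == "responder"
    }))
  })
  expect_true(all(diff(nCalls) <= 0))
  expect_equal(nCalls[length(nCalls)], 0L)  # k -> Inf: nobody responds
})

test_that("cohort responder fraction is recovered within binomial error", {
  n <- 200
  truth <- calciumCohortTruth(n, responderProb = 0.6, seed = 15,
                              qcFailFraction = 0.05)
  sim <- simulateCalciumTraces(truth, pr, noiseSd = 2, seed = 16)
  calls <- classifyTraces(sim$traces, pr)
  # QC-fail recovery
  expect_equal(sum(!calls$qc_pass), sum(truth$qc_fail))
  est <- mean(calls$call[calls$qc_pass] == "responder")
  expect_lt(abs(est - 0.6), 3 * sqrt(0.6 * 0.4 / sum(calls$qc_pass)))
})

test_that("regional statistics compute percentages and P/A ratios", {
  calls <- data.frame(
    cell_id = sprintf("c%02d", 1:20),
    islet_id = rep(c("i1", "i2"), each = 10),
    region = rep(rep(c("anterior", "posterior"), each = 5), 2),
    qc_pass = TRUE,
    call = c(rep(c("responder", "non_responder"), c(3, 2)),  # i1 A: 60%
             rep(c("responder", "non_responder"), c(3, 2)),  # i1 P: 60%
             rep(c("responder", "non_responder"), c(1, 4)),  # i2 A: 20%
             rep(c("responder", "non_responder"), c(2, 3)))) # i2 P: 40%
  rs <- regionalResponderStats(calls)
  expect_equal(rs$per_islet$ratio_post_over_ant, c(1, 2))
  expect_equal(rs$summary$mean_pct_anterior, mean(c(60, 20)))
  expect_equal(rs$summary$mean_pct_posterior, mean(c(60, 40)))

  # zero anterior responders: infinite ratio flagged
  calls$call[calls$islet_id == "i2" & calls$region == "anterior"] <-
    "non_responder"
  expect_warning(rs2 <- regionalResponderStats(calls), "infinite")
  expect_true(is.infinite(rs2$per_islet$ratio_post_over_ant[2]))
})

test_that("regional recovery matches the simulated 25 dpf-like asymmetry", {
  # 6 islets x 60 cells, posterior p = 0.67, anterior p = 0.34
  set.seed(17)
  allCalls <- do.call(rbind, lapply(1:6, function(i) {
    truth <- calciumCohortTruth(60, responderProb = 0.5,
                                seed = 100 + i, qcFailFraction = 0)
    truth$responder <- runif(60) <
      ifelse(truth$region == "posterior", 0.67, 0.34)
    sim <- simulateCalciumTraces(truth, pr, noiseSd = 2, seed = 200 + i)
    calls <- classifyTraces(sim$traces, pr)
    out <- merge(calls, truth[, c("cell_id", "region")], by = "cell_id")
    out$islet_id <- paste0("isl", i)
    out
  }))
  rs <- regionalResponderStats(allCalls)
  ratio <- rs$summary$mean_ratio
  # Monte-Carlo spread of the per-islet mean ratio around 0.67/0.34
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})

test_that("H2B status thresholds against the background band", {
  expect_equal(classifyH2bStatus(10, 10, 2), "negative")
  expect_equal(classifyH2bStatus(10 + 10 * 2, 10, 2), "positive")
  # label-diluted cohort at SNR >= 4: misclassification <= 5%
  set.seed(18)
  n <- 400
  retained <- runif(n) < 0.5
  bgMean <- 50; bgSd <- 10
  intensity <- ifelse(retained, rnorm(n, bgMean + 8 * bgSd, bgSd),
                      rnorm(n, bgMean, bgSd))
  call <- classifyH2bStatus(intensity, bgMean, bgSd, k = 2)
  err <- mean((call == "positive") != retained)
  expect_lte(err, 0.05)
})
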