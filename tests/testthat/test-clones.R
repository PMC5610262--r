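test_that("background subtraction clamps green/blue and spares red", {
  cells <- make_cell("a", means = c(30, 50, 5))
  bg <- list(g_background = 10, b_background = 10)
  out <- subtractBackground(cells, bg)
  expect_equal(out$g_mean, 40)
  expect_equal(out$b_mean, 0)        # clamped, not negative
  expect_equal(out$r_mean, 30)       # red untouched
  expect_equal(out$g_sd, cells$g_sd) # sds untouched
  # zero background is the identity
  expect_equal(subtractBackground(cells, list(g_background = 0,
                                              b_background = 0)), cells)
  expect_error(estimateBackground(data.frame(g_mean = 1, b_mean = 1)),
               "at least 3")
})

test_that("signature normalization sums to 100 and guards zero signal", {
  expect_equal(
    unlist(normalizeSignature(data.frame(r_mean = 2, g_mean = 1,
                                         b_mean = 1))),
    c(r_pct = 50, g_pct = 25, b_pct = 25))
  expect_equal(
    normalizeSignature(data.frame(r_mean = 10, g_mean = 0,
                                  b_mean = 0))$r_pct, 100)
  expect_error(normalizeSignature(data.frame(r_mean = 0, g_mean = 0,
                                             b_mean = 0)),
               "degenerate")
  # conservation property over random draws
  set.seed(1)
  cells <- data.frame(r_mean = runif(200, 0.1, 100),
                      g_mean = runif(200, 0, 100),
                      b_mean = runif(200, 0, 100))
  sig <- normalizeSignature(cells)
  expect_lt(max(abs(sig$r_pct + sig$g_pct + sig$b_pct - 100)), 1e-9)
})

test_that("triple-positive criterion is strict in every channel", {
  tp <- function(means, sds = c(1, 1, 1))
    isTriplePositive(make_cell("x", means, sds))
  expect_true(tp(c(10, 10, 10)))
  expect_false(tp(c(10, 10, 2)))     # 2 - 2.58 <= 0 in blue
  expect_false(tp(c(2.58, 10, 10)))  # boundary: strict inequality
})

test_that("a channel with zero true signal is rarely called positive", {
  # measurement model of the simulator: ROI pixel mean and sd with the
  # blue channel truly dark; the 2.58-sd gate should pass it at most
  # about 1% of the time per channel
  set.seed(10)
  n <- 400
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    px <- matrix(rnorm(30 * 3, mean = rep(c(60, 60, 0), each = 30),
                       sd = 5), ncol = 3)
    make_cell(paste0("c", i),
              means = pmax(0, colMeans(px)), sds = apply(px, 2, sd),
              n = 30)
  }))
  falseRate <- mean(isTriplePositive(rows))
  expect_lte(falseRate, 0.01 + 3 * sqrt(0.01 * 0.99 / n))
})

test_that("tostPair matches a CI-based textbook TOST oracle", {
  params <- tostParams(marginPct = 10, alpha = 0.05)
  # identical records are equivalent within any positive margin
  a <- make_cell("a", c(50, 25, 25), sds = c(2, 2, 2), n = 100)
  expect_true(tostPair(a, a, params))
  # orthogonal signatures are never equivalent
  b1 <- make_cell("b1", c(90, 5, 5), sds = c(3, 3, 3))
  b2 <- make_cell("b2", c(5, 90, 5), sds = c(3, 3, 3))
  expect_false(tostPair(b1, b2, tostParams(marginPct = 5)))

  # randomized comparison against the independent oracle
  set.seed(2)
  mismatches <- 0L
  for (rep in 1:60) {
    m1 <- runif(3, 1, 100); m2 <- m1 + rnorm(3, 0, 15)
    m2 <- pmax(m2, 0.5)
    c1 <- make_cell("p", m1, sds = runif(3, 0.5, 8),
                    n = sample(10:120, 1))
    c2 <- make_cell("q", m2, sds = runif(3, 0.5, 8),
                    n = sample(10:120, 1))
    got <- tostPair(c1, c2, params)
    want <- tost_oracle(c1, c2, margin = 10, alpha = 0.05)
    mismatches <- mismatches + (got != want)
  }
  expect_equal(mismatches, 0L)
})

test_that("tostPair is symmetric and monotone in the margin", {
  set.seed(3)
  for (rep in 1:40) {
    c1 <- make_cell("p", runif(3, 1, 100), sds = runif(3, 0.5, 6),
                    n = sample(5:100, 1))
    c2 <- make_cell("q", runif(3, 1, 100), sds = runif(3, 0.5, 6),
                    n = sample(5:100, 1))
    m <- runif(1, 2, 25)
    lo <- tostPair(c1, c2, tostParams(marginPct = m))
    expect_identical(lo, tostPair(c2, c1, tostParams(marginPct = m)))
    # enlarging the margin can only add equivalences
    if (lo)
      expect_true(tostPair(c1, c2, tostParams(marginPct = m * 2)))
  }
  expect_error(tostPair(make_cell("a", c(5, 5, 5), n = 1),
                        make_cell("b", c(5, 5, 5))),
               "insufficient")
})

test_that("equivalent pairs merge transitively into one clone", {
  # A~B and B~C equivalent, A~C not: the transitive-union rule puts all
  # three in one clone
  params <- tostParams(marginPct = 10)
  A <- make_cell("A", c(40, 30, 30), sds = c(1.5, 1.5, 1.5), n = 100)
  B <- make_cell("B", c(47, 26.5, 26.5), sds = c(1.5, 1.5, 1.5), n = 100)
  C <- make_cell("C", c(54, 23, 23), sds = c(1.5, 1.5, 1.5), n = 100)
  expect_true(tostPair(A, B, params))
  expect_true(tostPair(B, C, params))
  expect_false(tostPair(A, C, params))
  cs <- clusterClones(rbind(A, B, C), params)
  expect_equal(nClones(cs), 1L)
  expect_setequal(clones(cs)[[1]], c("A", "B", "C"))
})

test_that("non-equivalent cells stay singletons and empty input is empty", {
  params <- tostParams(marginPct = 5)
  cells <- rbind(make_cell("a", c(90, 5, 5), sds = c(1, 1, 1)),
                 make_cell("b", c(5, 90, 5), sds = c(1, 1, 1)),
                 make_cell("c", c(5, 5, 90), sds = c(1, 1, 1)),
                 make_cell("d", c(34, 33, 33), sds = c(1, 1, 1)))
  cs <- clusterClones(cells, params)
  expect_equal(nClones(cs), 4L)
  expect_true(all(cloneSizes(cs) == 1L))

  empty <- clusterClones(data.frame(), params)
  expect_equal(nClones(empty), 0L)
  # non-triple-positive cells are excluded and reported
  dark <- rbind(make_cell("ok", c(50, 25, 25), sds = c(1, 1, 1)),
                make_cell("dark", c(50, 25, 1), sds = c(1, 1, 1)))
  cs2 <- clusterClones(dark, params)
  expect_equal(excludedCells(cs2), "dark")
  expect_equal(unlist(clones(cs2), use.names = FALSE), "ok")
})

test_that("clusterClones equals the brute-force transitive-closure oracle", {
  params <- tostParams(marginPct = 10)
  set.seed(4)
  for (n in c(5L, 15L, 30L, 50L)) {
    base <- matrix(runif(3 * 6, 5, 95), ncol = 3)   # 6 archetype colors
    cells <- do.call(rbind, lapply(seq_len(n), function(i) {
      m <- base[sample(6, 1), ] + rnorm(3, 0, 4)
      make_cell(sprintf("c%02d", i), pmax(m, 0.5),
                sds = runif(3, 0.5, 5), n = sample(10:80, 1))
    }))
    got <- lapply(clones(clusterClones(cells, params)), sort)
    want <- clone_oracle(cells, params)
    canon <- function(sets) sets[order(vapply(sets, `[`, "", 1L))]
    expect_identical(unname(canon(got)), unname(canon(want)))
  }
})

test_that("clone recovery on well-separated barcodes is near-perfect", {
  params <- tostParams(marginPct = 10)
  aris <- vapply(1:20, function(seed) {
    isl <- make_separated_islet(seed)
    cs <- clusterClones(isl$cells, params)
    called <- rep(names(clones(cs)), cloneSizes(cs))
    names(called) <- unlist(clones(cs), use.names = FALSE)
    truth <- isl$truth$clone_id[match(names(called),
                                      isl$truth$cell_id)]
    ari_safe(called, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("clonality summaries use clones as the denominator", {
  cs <- new("CloneSet", isletId = "i", params = tostParams(),
            clones = list(c("A"), c("B"), c("C", "D")),
            excluded = character())
  s <- clonalitySummary(cs)
  expect_equal(s$pct_single, 100 * 2 / 3)
  expect_equal(s$pct_multi, 100 * 1 / 3)
  expect_equal(s$pct_single + s$pct_multi, 100)

  allSingle <- new("CloneSet", isletId = "i", params = tostParams(),
                   clones = list("A", "B"), excluded = character())
  expect_equal(clonalitySummary(allSingle)$pct_single, 100)

  sizes <- new("CloneSet", isletId = "i", params = tostParams(),
               clones = list("A", "B", c("C", "D"),
                             c("E", "F", "G", "H")),
               excluded = character())
  h <- clonalitySummary(sizes)$size_histogram
  expect_equal(as.integer(h), c(2L, 1L, 1L))
  expect_equal(names(h), c("1", "2", "4"))

  empty <- new("CloneSet", isletId = "i", params = tostParams(),
               clones = list(), excluded = character())
  expect_error(clonalitySummary(empty), "zero clones")
})

test_that("stage comparisons use the two-sided Fisher exact test", {
  expect_equal(compareClonality(c(10, 10), c(10, 10)), 1.0)
  tab <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(compareClonality(tab), fisher_oracle(tab),
               tolerance = 1e-10)
  set.seed(5)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(compareClonality(tab), fisher_oracle(tab),
                 tolerance = 1e-8)
  }
  expect_warning(p0 <- compareClonality(matrix(0, 2, 2)), "convention")
  expect_equal(p0, 1)
  expect_error(compareClonality(c(-1, 2), c(3, 4)), "nonnegative")
})

test_that("ternary coordinates are barycentric on the simplex", {
  vR <- c(0, 0); vG <- c(1, 0); vB <- c(0.5, sqrt(3) / 2)
  expect_equal(unlist(ternaryCoordinates(c(100, 0, 0))),
               c(u = vR[1], v = vR[2]))
  cen <- ternaryCoordinates(c(100, 100, 100) / 3)
  expect_equal(unlist(cen), c(u = mean(c(0, 1, 0.5)),
                              v = mean(c(0, 0, sqrt(3) / 2))))
  mix <- ternaryCoordinates(c(50, 25, 25))
  expect_equal(unlist(mix),
               c(u = 0.5 * vR[1] + 0.25 * vG[1] + 0.25 * vB[1],
                 v = 0.5 * vR[2] + 0.25 * vG[2] + 0.25 * vB[2]))
})
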