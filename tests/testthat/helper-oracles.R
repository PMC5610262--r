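# Independent oracles used across the suite. Each reimplements the checked
# computation along a different route than the package code.

# Textbook TOST via the confidence-interval inclusion rule: two cells are
# equivalent iff the (1 - 2*alpha) Welch CI of the normalized-mean
# difference lies inside (-margin, margin), per channel. Standard errors
# are propagated with a *numeric* gradient of the normalization map
# (central differences), independent of the package's analytic delta
# method.
tost_oracle <- function(a, b, margin, alpha) {
  norm_se <- function(m) {
    C <- c(m$r_mean, m$g_mean, m$b_mean)
    vmean <- c(m$r_sd, m$g_sd, m$b_sd)^2 / m$n_pixels
    p <- 100 * C / sum(C)
    h <- 1e-6 * max(1, sum(C))
    varP <- sapply(1:3, function(i) {
      g <- sapply(1:3, function(j) {
        up <- C; up[j] <- up[j] + h
        dn <- C; dn[j] <- dn[j] - h
        (100 * up[i] / sum(up) - 100 * dn[i] / sum(dn)) / (2 * h)
      })
      sum(g^2 * vmean)
    })
    list(p = p, varP = varP)
  }
  na <- norm_se(a); nb <- norm_se(b)
  for (i in 1:3) {
    d <- na$p[i] - nb$p[i]
    v <- na$varP[i] + nb$varP[i]
    if (v == 0) {
      if (abs(d) >= margin) return(FALSE)
      next
    }
    df <- v^2 / (na$varP[i]^2 / (a$n_pixels - 1) +
                   nb$varP[i]^2 / (b$n_pixels - 1))
    tcrit <- qt(1 - alpha, df)
    ci <- d + c(-1, 1) * tcrit * sqrt(v)
    if (ci[1] <= -margin || ci[2] >= margin) return(FALSE)
  }
  TRUE
}

# Brute-force clone clustering: all-pairs equivalence matrix, then
# transitive closure by repeated merging of overlapping sets (no graph
# library).
clone_oracle <- function(cells, params) {
  tp <- isTriplePositive(cells)
  kept <- cells[tp, , drop = FALSE]
  n <- nrow(kept)
  if (n == 0L) return(list())
  sets <- lapply(kept$cell_id, function(id) id)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (tostPair(kept[i, ], kept[j, ], params)) {
          si <- which(vapply(sets, function(s) kept$cell_id[i] %in% s,
                             logical(1)))
          sj <- which(vapply(sets, function(s) kept$cell_id[j] %in% s,
                             logical(1)))
          if (si != sj) {
            sets[[si]] <- c(sets[[si]], sets[[sj]])
            sets[[sj]] <- NULL
          }
        }
      }
    }
  }
  lapply(sets, sort)
}

# Queue-based 3D flood fill, one component at a time.
flood_fill_3d <- function(fg, connectivity = 26) {
  dims <- dim(fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ,
                                      drop = FALSE]
  lab <- array(0L, dims)
  nextLab <- 0L
  for (start in which(fg & lab == 0L)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      cc <- arrayInd(cur, dims)
      for (k in seq_len(nrow(offs))) {
        nb <- cc + offs[k, ]
        if (any(nb < 1L) || any(nb > dims)) next
        lin <- nb[1L] + dims[1L] * (nb[2L] - 1L) +
          dims[1L] * dims[2L] * (nb[3L] - 1L)
        if (fg[lin] && lab[lin] == 0L) {
          lab[lin] <- nextLab
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Two-sided Fisher p-value by exhaustive enumeration of all 2x2 tables
# with the observed margins.
fisher_oracle <- function(tab) {
  r <- rowSums(tab); c1 <- colSums(tab)[1L]; n <- sum(tab)
  support <- max(0L, c1 - r[2L]):min(r[1L], c1)
  probs <- dhyper(support, r[1L], r[2L], c1)
  pObs <- dhyper(tab[1L, 1L], r[1L], r[2L], c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exhaustive enumeration of the cassette outcome space: probability that
# the expressed color set is exactly {R, G, B}.
trichromatic_prob_oracle <- function(nCassettes, pRecomb, pGreen,
                                     pLeaky = 0) {
  pAny <- 1 - (1 - pRecomb) * (1 - pLeaky)
  pState <- c(R = 1 - pAny, G = pAny * pGreen, B = pAny * (1 - pGreen))
  states <- expand.grid(rep(list(c("R", "G", "B")), nCassettes),
                        stringsAsFactors = FALSE)
  prob <- apply(states, 1L, function(s) prod(pState[s]))
  tri <- apply(states, 1L, function(s) length(unique(s)) == 3L)
  sum(prob[tri])
}

# Small well-separated barcode cohort for recovery tests. A recovery
# benchmark needs clones to recover, so islets are drawn (deterministic
# sub-seed sequence) until at least two trichromatic founder clones are
# present.
make_separated_islet <- function(seed, nFounders = 10) {
  for (k in 0:49) {
    isl <- suppressWarnings(simulateIslet(
      growthConfig(nFounders = nFounders, quiescentFraction = 0.3,
                   divisionRate = 0.8, stages = c(3.5, 15),
                   neogenesisRate = 0),
      recombinationConfig(nCassettes = 3, pRecomb = 0.65),
      noiseConfig(pixelSd = c(2, 2, 2), pixelsPerCellRange = c(40, 80)),
      seed = seed * 53 + k, minSignatureSep = 40))
    tri <- isl$truth$color_class == "trichromatic"
    if (length(unique(isl$truth$clone_id[tri])) >= 2L) return(isl)
  }
  stop("no islet with >= 2 trichromatic clones found")
}

# ARI with the degenerate cases defined: when the two partitions agree
# exactly in pairwise co-membership the recovery is perfect and the score
# is 1 (mclust returns NaN there -- all-singleton or single-cluster
# partitions make the ARI numerator and denominator both zero).
ari_safe <- function(a, b) {
  co <- function(x) unname(outer(unname(x), unname(x), `==`))
  if (identical(co(a), co(b))) return(1)
  mclust::adjustedRandIndex(a, b)
}

# Measurement row builder for hand-constructed TOST/clustering cases.
make_cell <- function(id, means, sds = c(2, 2, 2), n = 50,
                      islet = "isl1") {
  data.frame(cell_id = id, islet_id = islet, stage_dpf = 30,
             r_mean = means[1], g_mean = means[2], b_mean = means[3],
             r_sd = sds[1], g_sd = sds[2], b_sd = sds[3],
             n_pixels = n, x = 0, y = 0, z = 0,
             stringsAsFactors = FALSE)
}
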