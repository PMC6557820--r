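wloops <- function(sides, g = NULL, w = NULL, s = NULL) {
  m <- length(sides)
  data.frame(side = sides, weight = if (is.null(w)) rep(1, m) else w,
             g = if (is.null(g)) rep(1.5, m) else g,
             s = if (is.null(s)) rep(1L, m) else s)
}

test_that("side fractions are weighted counts with binomial errors", {
  st <- sideFractions(wloops(c(rep("N", 6), rep("C", 4))))
  expect_equal(st$fracN, 0.6)
  expect_equal(st$fracC, 0.4)
  expect_equal(st$nEff, 10)
  expect_equal(st$stderr, sqrt(0.6 * 0.4 / 10))
  # weights move the fraction
  st2 <- sideFractions(wloops(c("N", "C"), w = c(0.25, 0.75)))
  expect_equal(st2$fracN, 0.25)
  expect_equal(sideFractions(wloops(character(0)))$nEff, 0)
})

test_that("random-reference sampling matches exhaustive enumeration", {
  # brute-force enumeration of admissible segments on both sides
  enumSides <- function(i1, i2, n, m0 = 10L, smin = 1L) {
    cnt <- c(N = 0L, C = 0L)
    for (j1 in 1:n) for (j2 in j1:n) {
      if (j2 - j1 < m0) next
      if (j2 <= i1 - smin) cnt["N"] <- cnt["N"] + 1L
      else if (j1 >= i2 + smin) cnt["C"] <- cnt["C"] + 1L
    }
    cnt
  }
  cases <- list(c(30, 45, 100), c(15, 40, 60), c(12, 30, 80),
                c(40, 60, 75))
  for (cs in cases) {
    cnt <- enumSides(cs[1], cs[2], cs[3])
    probs <- referenceSideProbs(data.frame(i1 = cs[1], i2 = cs[2],
                                           n = cs[3]))
    expect_equal(unname(probs[1, 1]), unname(cnt["N"] / sum(cnt)))
  }
  # chi-square agreement of 10000 seeded draws with enumeration
  lp <- data.frame(i1 = 30, i2 = 45, n = 100)
  draws <- vapply(1:10000, function(s)
    randomReferenceSide(lp, seed = s), character(1))
  cnt <- enumSides(30, 45, 100)
  chisq <- stats::chisq.test(table(factor(draws, c("N", "C"))),
                             p = cnt / sum(cnt))
  expect_gt(chisq$p.value, 0.01)
  # no room on the N side: always C
  lpN <- data.frame(i1 = 5, i2 = 20, n = 100)
  expect_true(all(vapply(1:20, function(s)
    randomReferenceSide(lpN, seed = s), character(1)) == "C"))
  # no admissible segment at all
  lp0 <- data.frame(i1 = 5, i2 = 20, n = 25)
  expect_true(is.na(randomReferenceSide(lp0, seed = 1)))
})

test_that("separation histograms are normalized with effective-count errors", {
  h <- separationDistribution(wloops(rep("N", 5), s = rep(1L, 5)))
  expect_equal(h$s, 1L)
  expect_equal(h$freq, 1)
  h2 <- separationDistribution(wloops(rep("N", 4), s = c(1L, 1L, 2L, 5L),
                                      w = c(0.5, 0.5, 1, 1)))
  expect_equal(sum(h2$freq), 1, tolerance = 1e-9)
  expect_equal(h2$freq[1], 1 / 3)
  expect_equal(h2$err, sqrt(h2$freq * (1 - h2$freq) / 3))
  expect_equal(separationDistribution(wloops(character(0)))$nEff, 0)
})

test_that("identical samples give KS statistic 0 and p = 1", {
  h <- separationDistribution(wloops(rep("N", 30), s = rep(1:6, 5)))
  cmp <- compareDistributions(h, h)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p.value, 1)
})

test_that("KS null calibration: same-generator draws are rarely rejected", {
  pvals <- vapply(1:100, function(s) {
    set.seed(s)
    h1 <- list(values = rgeom(300, 0.3) + 1L, weights = rep(1, 300))
    h2 <- list(values = rgeom(300, 0.3) + 1L, weights = rep(1, 300))
    compareDistributions(h1, h2)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("KS detects a planted shift at large effective counts", {
  set.seed(42)
  h1 <- list(values = rgeom(5000, 0.3) + 1L, weights = rep(1, 5000))
  h2 <- list(values = rgeom(5000, 0.3) + 2L, weights = rep(1, 5000))
  expect_lt(compareDistributions(h1, h2)$p.value, 1e-6)
  # the seeded resampling route agrees qualitatively
  expect_lt(compareDistributions(h1, h2, method = "resample",
                                 seed = 3)$p.value, 1e-6)
  expect_error(compareDistributions(list(values = integer(0),
                                         weights = numeric(0)), h1),
               "non-empty")
})

test_that("chirality bias is a weighted sign fraction with mirror symmetry", {
  lp <- wloops(c("N", "N", "N", "C"), g = c(2, 1.5, -1.2, 1.1))
  expect_equal(chiralityBias(lp)$fracPositive, 0.75)
  expect_equal(chiralityBias(lp, side = "N")$fracPositive, 2 / 3)
  allPos <- wloops(rep("N", 4), g = c(1, 2, 3, 1.2))
  expect_equal(chiralityBias(allPos)$fracPositive, 1)
  # mirroring flips every score sign: fractions map f -> 1 - f
  mirrored <- lp; mirrored$g <- -lp$g
  expect_equal(chiralityBias(mirrored)$fracPositive,
               1 - chiralityBias(lp)$fracPositive)
  expect_equal(chiralityBias(mirrored, side = "N")$fracPositive,
               1 - chiralityBias(lp, side = "N")$fracPositive)
})

test_that("planted side ratios are recovered by the weighted fractions", {
  # deterministic 70/30 N/C split of wrap fixtures
  sides <- rep(c("N", "C"), c(21, 9))
  lt <- do.call(rbind, lapply(seq_along(sides), function(k)
    scanLoops(makeHelixWrap(2, sides[k], seed = 300 + k))))
  cl <- clusterEnsemble(lt)
  st <- sideFractions(cl)
  expect_lt(abs(st$fracN - 0.7), 2 * st$stderr + 1e-9)
})
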