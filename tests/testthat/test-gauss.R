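test_that("direct double sum matches the explicit brute-force oracle", {
  # 4-bond vs 3-bond random configuration, explicit loops as the oracle
  set.seed(7)
  xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  tr <- ChainTrace(xyz)
  expect_equal(gaussPairScore(tr, c(1, 5), c(7, 10)),
               bruteGauss(xyz, c(1, 5), c(7, 10)), tolerance = 1e-12)
  expect_equal(gaussPairScore(tr, c(6, 10), c(1, 4)),
               bruteGauss(xyz, c(6, 10), c(1, 4)), tolerance = 1e-12)
})

test_that("prefix-sum kernel reproduces direct summation on all range pairs", {
  worst <- 0
  for (seed in 1:5) {
    tr <- randomTrace(15, seed)
    K <- bruteKernel(calpha(tr))
    kern <- buildKernel(tr)
    for (a1 in 1:12) for (a2 in (a1 + 1):13) for (b1 in (a2 + 1):14)
      for (b2 in (b1 + 1):15) {
        direct <- sum(K[a1:(a2 - 1), b1:(b2 - 1)])
        worst <- max(worst, abs(rangeScore(kern, c(a1, a2),
                                           c(b1, b2)) - direct))
      }
  }
  expect_lt(worst, 1e-10)
})

test_that("kernel structure: symmetry, zero diagonal, mirror negation, n=2", {
  tr <- randomTrace(12, 3)
  K <- buildKernel(tr)@pair
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_true(all(diag(K) == 0))
  Km <- buildKernel(mirrorTrace(tr))@pair
  expect_equal(Km, -K, tolerance = 1e-12)
  k2 <- buildKernel(ChainTrace(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3,
                                      byrow = TRUE)))
  expect_equal(dim(k2@pair), c(1L, 1L))
  expect_equal(k2@pair[1, 1], 0)
})

test_that("score symmetries: exchange, rigid motion, mirror antisymmetry", {
  tr <- randomTrace(20, 11)
  a <- c(2, 8); b <- c(11, 19)
  g <- gaussPairScore(tr, a, b)
  expect_equal(gaussPairScore(tr, b, a), g, tolerance = 1e-12)
  moved <- ChainTrace(rigidMotion(calpha(tr), 5))
  expect_lt(abs(gaussPairScore(moved, a, b) - g), 1e-9)
  gm <- gaussPairScore(mirrorTrace(tr), a, b)
  expect_equal(gm, -g, tolerance = 1e-12)
  # reversing one subchain's orientation flips the sign
  rev_xyz <- calpha(tr)
  rev_xyz[a[1]:a[2], ] <- rev_xyz[a[2]:a[1], ]
  expect_equal(gaussPairScore(ChainTrace(rev_xyz), a, b), -g,
               tolerance = 1e-9)
})

test_that("overlapping or invalid ranges are rejected", {
  tr <- randomTrace(15, 2)
  expect_error(gaussPairScore(tr, c(1, 8), c(5, 12)), "overlap")
  expect_error(gaussPairScore(tr, c(5, 5), c(7, 10)), "range")
  expect_error(rangeScore(buildKernel(tr), c(1, 8), c(8, 12)), "overlap")
})

test_that("contact detection honors the cutoff and the atom mode", {
  # two residues with closest heavy atoms at 4.4 vs 4.6 Angstrom
  mk <- function(d) {
    ca <- matrix(c(0, 0, 0, 30, 0, 0), 2, 3, byrow = TRUE)
    calist <- list(rbind(c(0, 0, 0), c(1, 0, 0)),
                   rbind(c(30, 0, 0), c(1 + d, 0, 0)))
    sclist <- list(matrix(numeric(0), 0, 3), rbind(c(30, 0, 0)))
    ChainTrace(ca, heavyAtoms = calist, sidechainAtoms = sclist)
  }
  expect_equal(nrow(computeContacts(mk(4.4))), 1L)
  expect_equal(nrow(computeContacts(mk(4.6))), 0L)
  # sidechain mode: residue 1 has no side chain, falls back to heavy
  expect_equal(nrow(computeContacts(mk(4.4), mode = "sidechain_heavy")),
               0L)  # sidechain of residue 2 is at x=30, far from residue 1
})

test_that("loop enumeration applies the m0 separation threshold", {
  contacts <- rbind(c(1L, 10L), c(1L, 11L), c(5L, 30L))
  colnames(contacts) <- c("i1", "i2")
  loops <- enumerateLoops(contacts, m0 = 10L)
  expect_equal(nrow(loops), 2L)           # separation 9 excluded
  expect_equal(loops[1, ], c(i1 = 1L, i2 = 11L))  # boundary included
})

test_that("loops too close to both termini have no admissible thread", {
  tr <- makeHelixWrap(2, "N", seed = 1)
  kern <- buildKernel(tr)
  n <- length(tr)
  rec <- bestThread(kern, c(1, 11), m0 = max(20L, n))  # impossible m0
  expect_true(is.na(rec$g))
  expect_true(is.na(rec$side))
})

test_that("full-arm mode scores only the two terminal arms", {
  tr <- makeHelixWrap(2, "N", seed = 13)
  kern <- buildKernel(tr)
  lt <- scanLoops(tr)
  loop <- c(lt$i1[which.max(abs(lt$g))], lt$i2[which.max(abs(lt$g))])
  fa <- bestThread(kern, loop, fullArm = TRUE)
  expect_true(fa$j1 == 1L || fa$j2 == length(tr))
  # the free scan can only do at least as well in |g|
  free <- bestThread(kern, loop)
  expect_gte(abs(free$g), abs(fa$g) - 1e-12)
  # loop flush against both termini: no admissible arm
  n <- length(tr)
  fa0 <- bestThread(kern, c(2, n - 2), fullArm = TRUE)
  expect_true(is.na(fa0$g))
})

test_that("protein-level scores satisfy |L'| <= |G'c| and flag empty traces", {
  # straight extended chain: no contacts at separation >= m0
  straight <- ChainTrace(cbind(3.8 * (0:29), 0, 0))
  res <- proteinEntanglement(straight)
  expect_true(is.na(proteinGE(res)))
  expect_true(is.na(proteinLE(res)))
  expect_equal(nrow(loopTable(res)), 0L)
  # compact backbones: wherever both are defined, |L'| <= |G'c|
  for (s in 1:10) {
    tr <- makeRandomBackbone(50, confinement = 11, seed = 100 + s)
    r <- proteinEntanglement(tr)
    if (!is.na(proteinLE(r)))
      expect_lte(abs(proteinLE(r)), abs(proteinGE(r)) + 1e-12)
  }
})
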