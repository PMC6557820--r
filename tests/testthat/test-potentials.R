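test_that("generic pair counting enumerates separations >= m0", {
  # 12-residue chain: admissible pairs (1,11), (1,12), (2,12)
  tr <- ChainTrace(cbind(3.8 * (0:11), 0, 0),
                   residues = rep("A", 12))
  v <- countPairs(tr)
  expect_equal(sum(v), 3)
  idxAA <- which(v > 0)
  expect_equal(length(idxAA), 1L)
  # boundary: a 10-residue chain has no pair at separation >= 10
  tr10 <- ChainTrace(cbind(3.8 * (0:9), 0, 0), residues = rep("A", 10))
  expect_equal(sum(countPairs(tr10)), 0)
  # additivity over an ensemble of two identical chains
  expect_equal(countPairs(tr) + countPairs(tr), 2 * v)
  # unknown residues are excluded from counting
  trx <- ChainTrace(cbind(3.8 * (0:11), 0, 0),
                    residues = c("X", rep("A", 11)))
  expect_equal(sum(countPairs(trx)), 1)  # only (2,12) survives
})

test_that("contact counting is cutoff- and mode-faithful", {
  mk <- function(d) {
    n <- 12L
    ca <- cbind(3.8 * (0:(n - 1)), 0, 0)
    ca[12, ] <- c(0, d + 1, 0)  # residue 12 near residue 1
    heavy <- lapply(seq_len(n), function(i) ca[i, , drop = FALSE])
    side <- heavy
    side[[1]] <- rbind(c(0, 1, 0))  # side-chain atom of residue 1
    ChainTrace(ca, residues = c("A", rep("G", 10), "D"),
               heavyAtoms = heavy, sidechainAtoms = side)
  }
  cc <- countContacts(mk(4.2))
  expect_equal(sum(cc$counts), 1)
  aa <- aminoAcids()
  m <- matrix(0, 20, 20)
  m[aa == "A", aa == "D"] <- 1
  expect_equal(sum(cc$counts), 1)
  expect_equal(nrow(cc$pairs), 1L)
  expect_equal(unname(cc$pairs[1, ]), c(1L, 12L))
  expect_equal(sum(countContacts(mk(4.8))$counts), 0)
})

test_that("entangled-contact counting keys on the |g| >= 1 threshold", {
  tr <- makeHelixWrap(2, "N", seed = 6)
  lt <- scanLoops(tr)
  v <- countEntangledContacts(tr, lt)
  expect_equal(sum(v), 1)
  # force the loop below threshold: no entangled contacts
  lt0 <- lt; lt0$g <- 0.4
  expect_equal(sum(countEntangledContacts(tr, lt0)), 0)
  # PRO-GLY closure is attributed to the right cell
  trPG <- tr
  trPG@residues[lt$i1[which.max(abs(lt$g))]] <- "P"
  trPG@residues[lt$i2[which.max(abs(lt$g))]] <- "G"
  vPG <- countEntangledContacts(trPG, lt)
  m <- gentangle:::.pairVecToMatrix(vPG)
  expect_equal(m["P", "G"], 1)
  expect_equal(m["G", "P"], 1)
  expect_equal(sum(vPG), 1)
})

test_that("log-odds scores reproduce analytic fixed points", {
  ref <- numeric(210); ref[c(1, 25, 60)] <- c(50, 30, 20)
  # equal frequencies: score 0
  expect_equal(potentialValues(potentialFromCounts(ref, ref))[1, 1], 0)
  # frequency ratio e^-1: score +tau
  focal <- ref
  tot <- sum(ref)
  focal[1] <- exp(-1) * (ref[1] / tot) * tot  # scale numerator only
  # renormalize so only entry 1 changes its frequency ratio
  v <- potentialFromCounts(focal, ref, tau = 100)
  ratio <- (focal[1] / sum(focal)) / (ref[1] / tot)
  expect_equal(potentialValues(v)[1, 1], -100 * log(ratio),
               tolerance = 1e-9)
  # zero counts are undefined, empty counts error
  expect_true(is.na(potentialValues(potentialFromCounts(focal,
                                                        ref))[20, 20]))
  expect_error(potentialFromCounts(numeric(210), ref), "empty")
})

test_that("potential inference recovers planted contact composition", {
  # contact frequency doubled for (A,A) relative to the base pairing
  ens <- makePlantedSequenceEnsemble(400, nWraps = 0L, nHairpins = 6L,
                                     contactFactors = c(AA = 2),
                                     seed = 31)
  gen <- Reduce(`+`, lapply(ens$traces, countPairs))
  con <- Reduce(`+`, lapply(ens$traces, function(tr)
    countContacts(tr)$counts))
  eNorm <- potentialValues(potentialFromCounts(con, gen, tau = 100))
  idx <- gentangle:::.pairKeyIdx("AA")
  expected <- -100 * log(ens$groundTruth$pC[idx] /
                           ens$groundTruth$pBase[idx])
  # sampling error ~ tau/sqrt(Nc(AA)); allow 3 sigma
  nAA <- gentangle:::.pairVecToMatrix(con)["A", "A"]
  expect_lt(abs(eNorm["A", "A"] - expected), 3 * 100 / sqrt(nAA))
})

test_that("enrichment equals E_GE - E_norm and bootstrap errors behave", {
  ens <- makePlantedSequenceEnsemble(60, nWraps = 2L, nHairpins = 5L,
                                     seed = 8)
  lts <- lapply(ens$traces, scanLoops)
  pots <- inferPotentials(ens$traces, lts, nBoot = 31, seed = 2)
  dev <- abs(potentialValues(pots$enrichment) -
               (potentialValues(pots$ge) - potentialValues(pots$norm)))
  expect_lt(max(dev, na.rm = TRUE), 1e-9)
  expect_true(all(!is.na(potentialStderr(pots$norm)) ==
                    !is.na(potentialValues(pots$norm)) |
                    is.na(potentialValues(pots$norm))))
  # identical proteins: bootstrap stderr collapses to zero
  same <- rep(ens$traces[1], 8)
  sameLt <- rep(lts[1], 8)
  p0 <- inferPotentials(same, sameLt, nBoot = 15, seed = 1)
  expect_lt(max(potentialStderr(p0$norm), na.rm = TRUE), 1e-9)
  # doubling the ensemble shrinks stderr by about sqrt(2) on pairs with
  # healthy counts (asymptotic scaling does not hold for 1-2 counts)
  cf <- c(LL = 120, DK = 30, PD = 20)
  mkPots <- function(n) {
    e <- makePlantedSequenceEnsemble(n, nWraps = 2L, nHairpins = 5L,
                                     contactFactors = cf, seed = 8)
    inferPotentials(e$traces, lapply(e$traces, scanLoops),
                    nBoot = 101, seed = 2)
  }
  s1 <- potentialStderr(mkPots(80)$norm)
  s2 <- potentialStderr(mkPots(160)$norm)
  for (k in list(c("L", "L"), c("D", "K"), c("P", "D"))) {
    ratio <- s2[k[1], k[2]] / s1[k[1], k[2]]
    expect_lt(abs(ratio - 1 / sqrt(2)), 0.2)
  }
})

test_that("correlation analysis recovers a planted linear relation", {
  set.seed(99)
  aa <- aminoAcids()
  base <- matrix(rnorm(400, sd = 50), 20, 20)
  base <- (base + t(base)) / 2
  enrV <- -0.12 * base + matrix(rnorm(400, sd = 5), 20, 20)
  enrV <- (enrV + t(enrV)) / 2
  na20 <- matrix(NA_real_, 20, 20)
  mkPM <- function(v, kind) new("PotentialMatrix", values = v,
                                stderr = na20, mask = !is.na(v),
                                tau = 100, kind = kind)
  ca <- correlationAnalysis(mkPM(enrV, "enrichment"), mkPM(base, "norm"))
  expect_lt(abs(ca$slope + 0.12), 0.02)
  expect_lt(ca$pearson, -0.5)
  expect_equal(ca$nPairs, 210L)
  # too few defined pairs errors
  few <- matrix(NA_real_, 20, 20)
  few[cbind(1:5, 1:5)] <- 1
  expect_error(correlationAnalysis(mkPM(enrV, "enrichment"),
                                   mkPM(few, "norm")), "fewer than 10")
})
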