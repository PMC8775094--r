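test_that("countDifferences matches the examples and the brute-force oracle", {
  expect_identical(countDifferences("ACGT", "ACGT"),
                   list(transitions = 0L, transversions = 0L, sites = 4L))
  expect_identical(countDifferences("ACGT", "GCGT")$transitions, 1L)
  expect_identical(countDifferences("AC-T", "ACGT")$sites, 3L)
  expect_error(countDifferences("----", "ACGT"),
               class = "ervkit_undefined_distance")

  withr::with_seed(42, {
    for (i in 1:25) {
      len <- sample(5:50, 1)
      a <- paste0(sample(c("A", "C", "G", "T", "-", "N"), len, TRUE,
                         prob = c(.22, .22, .22, .22, .06, .06)), collapse = "")
      b <- paste0(sample(c("A", "C", "G", "T", "-", "N"), len, TRUE,
                         prob = c(.22, .22, .22, .22, .06, .06)), collapse = "")
      want <- oracleCountDiffs(a, b)
      if (want$sites == 0) next
      expect_identical(countDifferences(a, b), want)
    }
  })
})

test_that("k2p reproduces the hand-evaluated closed form and its domain", {
  # 100 nt, exactly 10 transitions and 5 transversions: P=0.10, Q=0.05
  a <- strrep("A", 100)
  bv <- rep("A", 100); bv[1:10] <- "G"; bv[11:15] <- "C"
  pd <- k2pDistance(a, paste0(bv, collapse = ""))
  handK <- -0.5 * log(1 - 2 * 0.10 - 0.05) - 0.25 * log(1 - 2 * 0.05)
  expect_equal(kValue(pd), handK, tolerance = 1e-12)
  expect_equal(kValue(pd), 0.1701812, tolerance = 1e-6)
  expect_identical(siteCount(pd), 100L)

  expect_identical(kValue(k2pDistance("ACGT", "ACGT")), 0)

  # P = 0.45, Q = 0.10 sits exactly on the saturation boundary
  cv <- rep("A", 100); cv[1:45] <- "G"; cv[46:55] <- "C"
  expect_error(k2pDistance(a, paste0(cv, collapse = "")),
               "P = 0.45", class = "ervkit_saturation_error")
})

test_that("k2p is symmetric, dominates the p-distance, and gamma >= plain", {
  withr::with_seed(7, {
    for (i in 1:50) {
      a <- randomSeq(200)
      b <- mutateAt(a, sample(200, sample(5:40, 1)), seed = i)
      k1 <- k2pDistance(a, b); k2 <- k2pDistance(b, a)
      expect_identical(kValue(k1), kValue(k2))
      expect_gte(kValue(k1), k1@P + k1@Q)
    }
  })
  # gamma-corrected K >= plain K on a P/Q grid (numerical Jensen check)
  for (P in c(0.01, 0.05, 0.1, 0.2)) {
    for (Q in c(0.005, 0.02, 0.05, 0.1)) {
      plain <- ervkit:::.k2pFromPQ(P, Q, 100L)
      gam <- ervkit:::.k2pFromPQ(P, Q, 100L, gammaShape = 0.3608)
      expect_gte(kValue(gam), kValue(plain))
    }
  }
})

test_that("k2p agrees with an independent K80 implementation (ape)", {
  skip_if_not_installed("ape")
  withr::with_seed(11, {
    seqs <- character(6)
    seqs[1] <- randomSeq(300)
    for (i in 2:6) seqs[i] <- mutateAt(seqs[1], sample(300, 25), seed = i)
    aln <- alnFromStrings(seqs)
    K <- distanceMatrix(aln)
    bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
    names(bin) <- names(aln)
    apeK <- as.matrix(ape::dist.dna(bin, model = "K80"))
    expect_equal(unname(K), unname(apeK[rownames(K), colnames(K)]),
                 tolerance = 1e-10)
  })
})

test_that("distanceMatrix: symmetry, zero diagonal, policies, CpG exclusion", {
  aln <- alnFromStrings(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_identical(unname(distanceMatrix(aln)), matrix(0, 2, 2))

  withr::with_seed(3, {
    base <- randomSeq(120)
    seqs <- c(base, mutateAt(base, sample(120, 15), seed = 1),
              mutateAt(base, sample(120, 20), seed = 2))
    aln <- alnFromStrings(seqs)
    K <- distanceMatrix(aln)
    # element-wise pairwise oracle loop
    for (i in 1:2) for (j in (i + 1):3) {
      expect_identical(K[i, j], kValue(k2pDistance(seqs[i], seqs[j])))
      expect_identical(K[i, j], K[j, i])
    }
  })

  # complete deletion drops the gapped column for every pair
  aln2 <- alnFromStrings(c(a = "AC-TAAAA", b = "ACGTAAAA", c = "ACTTAAAA"))
  Kp <- distanceMatrix(aln2, policy = "pairwise")
  Kc <- distanceMatrix(aln2, policy = "complete")
  expect_gt(Kp["b", "c"], 0)   # G vs T at the gapped column counts pairwise
  expect_identical(Kc["b", "c"], 0)

  # an alignment whose only differences sit in CpG columns collapses to 0
  ref <- "AACGTTAACGTT"
  qry <- "AATGTTAACATT"   # CG->TG and CG->CA
  aln3 <- alnFromStrings(c(r = ref, q = qry))
  expect_gt(distanceMatrix(aln3)["r", "q"], 0)
  expect_identical(
    distanceMatrix(aln3, excludeCpG = TRUE, reference = ref)["r", "q"], 0)
})

test_that("tstvRatio counts pairwise and flags the zero-transversion case", {
  # pair with 4 transitions (A->G) and 1 transversion (A->C)
  a <- strrep("A", 20)
  bv <- rep("A", 20); bv[1:4] <- "G"; bv[5] <- "C"
  r <- tstvRatio(alnFromStrings(c(a, paste0(bv, collapse = ""))))
  expect_identical(r$R, 4)
  expect_false(r$infinite)

  same <- tstvRatio(alnFromStrings(rep("ACGTACGT", 3)))
  expect_true(same$infinite)
  expect_identical(same$R, Inf)
})

test_that("simulated transition bias is recovered by the count estimator", {
  params <- simParams(provirusLength = 2000, ltrLength = 450,
                      cpgTargetCount = 40, tstv = 10, cpgRate = 0)
  anc <- makeAncestor(params, seed = 5)
  base <- as.character(locusSeq(anc))
  # pool transition/transversion counts over 20 replicate pairs: the pooled
  # count ratio estimates the 10:1 event weighting
  withr::with_seed(99, {
    tot <- c(ts = 0L, tv = 0L)
    for (i in 1:20) {
      a <- evolveSequence(base, 4e6, params)$seq
      b <- evolveSequence(base, 4e6, params)$seq
      r <- tstvRatio(alnFromStrings(c(a, b)))
      tot <- tot + c(ts = r$transitions, tv = r$transversions)
    }
  })
  R <- tot[["ts"]] / tot[["tv"]]
  expect_gt(R, 8)
  expect_lt(R, 12)
})

test_that("baseComposition fractions and exclusions", {
  expect_equal(unname(baseComposition("ACGT")), rep(0.25, 4))
  expect_identical(baseComposition("AAAA")[["A"]], 1)
  comp <- baseComposition("AC-GN")
  expect_equal(sum(comp), 1)
  expect_equal(comp[["A"]], 1 / 3)
  expect_error(baseComposition("NN--"), class = "ervkit_undefined_distance")
  # region restriction
  expect_identical(baseComposition("AAAATTTT", region = c(5, 8))[["T"]], 1)
})

test_that("classifyGenotype labels by nearer exemplar with a tie margin", {
  withr::with_seed(21, {
    ref1 <- randomSeq(400)
    ref2 <- mutateAt(ref1, sample(400, 48), seed = 1)   # ~12% apart
    expect_identical(classifyGenotype(ref1, ref1, ref2)$label, "SERV1")
    drift <- mutateAt(ref2, sample(400, 20), seed = 2)  # near ref2
    expect_identical(classifyGenotype(drift, ref1, ref2)$label, "SERV2")
    res <- classifyGenotype(ref1, ref1,
                            mutateAt(ref1, 1, seed = 3), tieMargin = 0.01)
    expect_identical(res$label, "unassigned")
  })
})

test_that("genotype recovery on simulated descendants", {
  withr::with_seed(31, {
    p1 <- simParams(provirusLength = 1500, ltrLength = 420,
                    cpgTargetCount = 30, cpgRate = 0)
    ref1 <- as.character(locusSeq(makeAncestor(p1, seed = 1)))
    ref2 <- mutateAt(ref1, sample(nchar(ref1), round(0.12 * nchar(ref1))),
                     seed = 4)
    for (i in 1:5) {
      desc <- mutateAt(ref2, sample(nchar(ref2), round(0.05 * nchar(ref2))),
                       seed = 10 + i)
      expect_identical(classifyGenotype(desc, ref1, ref2)$label, "SERV2")
    }
  })
})
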