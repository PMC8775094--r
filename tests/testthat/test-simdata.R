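test_that("makeAncestor builds the documented provirus architecture", {
  params <- simParams()
  anc <- makeAncestor(params, seed = 1)
  v <- as.character(locusSeq(anc))
  expect_identical(nchar(v), 8393L)
  ltrs <- ltrSequences(anc)
  expect_identical(ltrs$ltr5, ltrs$ltr3)           # identical terminal LTRs
  expect_identical(nchar(ltrs$ltr5), 485L)
  expect_identical(substr(ltrs$ltr5, 1, 2), "TG")  # canonical LTR termini
  expect_identical(substr(ltrs$ltr5, 484, 485), "CA")
  # PBS immediately 3' of the 5' LTR
  expect_identical(substr(v, 486, 503), pbsReferences()[["lys3"]])
  # ORFs are recorded and open
  expect_identical(names(anc@orfs), c("gag", "pol", "env"))
  for (k in 1:3) {
    g <- substr(v, IRanges::start(anc@orfs)[k], IRanges::end(anc@orfs)[k])
    expect_identical(orfStatus(g, nchar(g))$state, "open")
  }
  # determinism
  expect_identical(as.character(locusSeq(makeAncestor(params, seed = 1))), v)
  expect_false(identical(as.character(locusSeq(makeAncestor(params, 2))), v))
})

test_that("planted CpG content hits the target within 5%", {
  countCG <- function(s) {
    v <- strsplit(s, "")[[1]]
    sum(v[-length(v)] == "C" & v[-1] == "G")
  }
  anc1 <- makeAncestor(simParams(), seed = 3)
  cnt1 <- countCG(as.character(locusSeq(anc1)))
  expect_gte(cnt1, 189); expect_lte(cnt1, 207)   # 198 +- 5%

  anc2 <- makeAncestor(simParams(genotype = "SERV2"), seed = 4)
  cnt2 <- countCG(as.character(locusSeq(anc2)))
  expect_gte(cnt2, 137); expect_lte(cnt2, 151)   # 144 +- 5%
  expect_identical(anc2@pbs, pbsReferences()[["lys12"]])
})

test_that("ancestor composition follows the A-rich regional profile", {
  anc <- makeAncestor(simParams(), seed = 5)
  v <- locusSeq(anc)
  ltrA <- baseComposition(v, anc@ltr5)[["A"]]
  gagA <- baseComposition(v, anc@orfs["gag"])[["A"]]
  envA <- baseComposition(v, anc@orfs["env"])[["A"]]
  expect_lt(ltrA, gagA)       # LTR is the least A-rich region
  expect_gt(gagA, envA)       # gag-pol more A-rich than env
  expect_equal(gagA, 0.333, tolerance = 0.05)
})

test_that("integrateProvirus plants an exact TSD and respects bounds", {
  params <- simParams(provirusLength = 1200, ltrLength = 420,
                      cpgTargetCount = 25)
  anc <- makeAncestor(params, seed = 6)
  host <- randomSeq(500, seed = 7)
  res <- integrateProvirus(host, anc, 100, params)
  expect_identical(nchar(res$truth$tsd), 6L)
  expect_identical(detectTSD(locusSeq(res$record),
                             c(res$truth$provStart, res$truth$provEnd)),
                   res$truth$tsd)
  expect_identical(res$truth$tsd, substr(host, 95, 100))

  # no duplication when tsdLength = 0
  params0 <- simParams(provirusLength = 1200, ltrLength = 420,
                       cpgTargetCount = 25, tsdLength = 0)
  res0 <- integrateProvirus(host, anc, 100, params0)
  expect_identical(res0$truth$tsd, NA_character_)
  got <- detectTSD(locusSeq(res0$record),
                   c(res0$truth$provStart, res0$truth$provEnd))
  expect_identical(got, NA_character_)

  expect_error(integrateProvirus(host, anc, 2, params),
               class = "ervkit_sim_error")
})

test_that("evolveSequence: zero years is identity; logs replay exactly", {
  base <- randomSeq(2000, seed = 8)
  none <- evolveSequence(base, 0)
  expect_identical(none$seq, base)
  expect_identical(nrow(none$log), 0L)

  params <- simParams()
  ev <- evolveSequence(base, 3e6, params, seed = 9)
  expect_identical(replayMutations(base, ev$log), ev$seq)
  expect_gt(nrow(ev$log), 0)
  # determinism under the same seed
  ev2 <- evolveSequence(base, 3e6, params, seed = 9)
  expect_identical(ev2$seq, ev$seq)
})

test_that("LTR-pair divergence matches the closed-form expectation 2rT", {
  # reduced-size Monte-Carlo (the full 200-replicate version runs in the
  # acceptance suite): T = 3 Myr, r = 5e-9 -> E[K] = 0.03
  params <- simParams(cpgRate = 0)
  anc <- makeAncestor(params, seed = 10)
  withr::with_seed(11, {
    Ks <- replicate(30, provirusAge(evolveRecord(anc, 3e6, params)$record)$K)
  })
  expect_gt(mean(Ks), 0.026)
  expect_lt(mean(Ks), 0.034)
})

test_that("CpG sites mutate much faster than the background", {
  params <- simParams()   # cpgRate/baseRate = 32
  anc <- makeAncestor(params, seed = 12)
  base <- as.character(locusSeq(anc))
  v <- strsplit(base, "")[[1]]
  cpg <- unique(c(which(v[-length(v)] == "C" & v[-1] == "G"),
                  which(v[-length(v)] == "C" & v[-1] == "G") + 1L))
  withr::with_seed(13, {
    for (i in 1:5) {
      ev <- evolveSequence(base, 2e6, params)
      mutPos <- unique(ev$log$position)
      fracCpG <- mean(cpg %in% mutPos)
      fracBg <- mean(setdiff(seq_along(v), cpg) %in% mutPos)
      expect_gt(fracCpG, fracBg)
      # the log labels deamination events
      expect_true(all(ev$log$cause %in% c("neutral", "cpg")))
      expect_gt(sum(ev$log$cause == "cpg"), 0)
    }
  })
})

test_that("apobecEdit follows pre-edit context semantics", {
  p <- mutationPattern("K", "G", "A", "D")
  # efficiency 0: unchanged
  e0 <- apobecEdit("TGGT", p, 0, seed = 1)
  expect_identical(e0$seq, "TGGT")
  # efficiency 1 on TGGT: both Gs qualify against the pre-edit sequence
  e1 <- apobecEdit("TGGT", p, 1, seed = 1)
  expect_identical(e1$seq, "TAAT")
  expect_identical(e1$nSites, 2L)
  expect_identical(e1$nEdited, 2L)

  # edited count lands inside the binomial 99% interval
  s <- randomSeq(3000, seed = 14)
  ed <- apobecEdit(s, p, 0.3, seed = 15)
  expect_gte(ed$nSites, 50L)
  ci <- qbinom(c(0.005, 0.995), ed$nSites, 0.3)
  expect_gte(ed$nEdited, ci[1])
  expect_lte(ed$nEdited, ci[2])
  # order independence: the same seed gives the same edit set regardless of
  # how many qualifying sites mutate, because context is pre-edit
  ed2 <- apobecEdit(s, p, 0.3, seed = 15)
  expect_identical(ed$seq, ed2$seq)
})

test_that("generateCohort is reproducible with a complete truth table", {
  params <- simParams(provirusLength = 1500, ltrLength = 430,
                      cpgTargetCount = 30)
  coh <- generateCohort(params, agesYears = c(1e6, 3e6), apobec = c(FALSE, TRUE),
                        nPerCell = 3, seed = 99, hostLength = 600)
  expect_identical(length(coh$records), 12L)
  expect_identical(nrow(coh$truth), 12L)
  expect_identical(sort(names(coh$records)), sort(coh$truth$id))

  # byte-identical under the same master seed
  coh2 <- generateCohort(params, agesYears = c(1e6, 3e6),
                         apobec = c(FALSE, TRUE), nPerCell = 3, seed = 99,
                         hostLength = 600)
  expect_identical(
    vapply(coh$records, function(r) as.character(locusSeq(r)), character(1)),
    vapply(coh2$records, function(r) as.character(locusSeq(r)), character(1)))

  # truth mutation logs replay to the emitted sequences
  for (id in names(coh$records)) {
    expect_identical(
      replayMutations(coh$truth$baseline[coh$truth$id == id], coh$logs[[id]]),
      as.character(locusSeq(coh$records[[id]])))
  }
})

test_that("writeCohort emits FASTA and a truth TSV", {
  params <- simParams(provirusLength = 1500, ltrLength = 430,
                      cpgTargetCount = 30)
  coh <- generateCohort(params, agesYears = 1e6, apobec = FALSE,
                        nPerCell = 2, seed = 5, hostLength = 600)
  dir <- tempfile()
  writeCohort(coh, dir)
  loci <- readFasta(file.path(dir, "loci.fasta"))
  expect_identical(length(loci), 2L)
  tt <- read.delim(file.path(dir, "truth.tsv"))
  expect_identical(nrow(tt), 2L)
  expect_true(all(c("id", "ageYears", "tsd") %in% names(tt)))
})
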