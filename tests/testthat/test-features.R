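test_that("extractLTRs recovers planted terminal repeats exactly", {
  s <- plantedRepeatSeq(coreLen = 7400, ltrLen = 480, seed = 2)
  n <- nchar(s)
  got <- extractLTRs(s)
  expect_identical(c(IRanges::start(got$ltr5), IRanges::end(got$ltr5)),
                   c(1L, 480L))
  expect_identical(c(IRanges::start(got$ltr3), IRanges::end(got$ltr3)),
                   c(n - 479L, n))
  expect_identical(got$identity, 1)
})

test_that("extractLTRs tolerates 2% substitutions in the 3' repeat", {
  s <- plantedRepeatSeq(coreLen = 7400, ltrLen = 480, seed = 3)
  n <- nchar(s)
  # mutate ~2% of the 3' copy (interior positions, sparing the TG/CA motifs)
  pos <- withr::with_seed(8, sample((n - 470):(n - 10), 10))
  s2 <- mutateAt(s, pos, seed = 9)
  got <- extractLTRs(s2)
  expect_identical(IRanges::start(got$ltr5), 1L)
  expect_identical(IRanges::end(got$ltr3), n)
  expect_equal(got$identity, 1 - 10 / 480, tolerance = 0.005)
})

test_that("extractLTRs errors on sequence without terminal repeats", {
  expect_error(extractLTRs(randomSeq(8000, seed = 4)),
               class = "ervkit_no_ltr")
  expect_error(extractLTRs(randomSeq(500, seed = 5)),
               class = "ervkit_no_ltr")
})

test_that("detectTSD requires an exact flanking duplication", {
  prov <- randomSeq(200, seed = 6)
  mk <- function(tsd5, tsd3) {
    paste0(randomSeq(30, seed = 7), tsd5, prov, tsd3, randomSeq(30, seed = 8))
  }
  span <- c(37, 36 + 200)
  expect_identical(detectTSD(mk("ATTTGG", "ATTTGG"), span), "ATTTGG")
  expect_identical(detectTSD(mk("TGGATA", "TGGATA"), span), "TGGATA")
  expect_identical(detectTSD(mk("ATTTGG", "ATTTGC"), span), NA_character_)
  # insufficient flank
  short <- paste0("AC", prov, "ACGTAC")
  expect_error(detectTSD(short, c(3, 202)), class = "ervkit_flank_error")
})

test_that("extractPBS returns the 18-mer after the 5' LTR, or a 19-nt
           window when a single insertion fits better", {
  refs <- pbsReferences()
  tail60 <- randomSeq(60, seed = 10)
  s <- paste0(randomSeq(450, seed = 11), refs[["lys3"]], tail60)
  expect_identical(extractPBS(s, c(1, 450)), refs[["lys3"]])

  # the documented variant: an additional T inserted in the PBS
  ins <- paste0(substr(refs[["lys12"]], 1, 8), "T",
                substr(refs[["lys12"]], 9, 18))
  s2 <- paste0(randomSeq(450, seed = 12), ins, tail60)
  got <- extractPBS(s2, c(1, 450))
  expect_identical(nchar(got), 19L)
  expect_identical(got, ins)

  expect_error(extractPBS(paste0(randomSeq(450, seed = 13), "ACGT"),
                          c(1, 450)),
               class = "ervkit_flank_error")
})

test_that("classifyPBS labels by Levenshtein distance with ambiguity", {
  refs <- pbsReferences()
  r3 <- classifyPBS(refs[["lys3"]])
  expect_identical(r3$label, "lys3")
  expect_identical(unname(r3$distances), c(0L, 4L))
  r12 <- classifyPBS(refs[["lys12"]])
  expect_identical(r12$label, "lys12")
  expect_identical(unname(r12$distances["lys12"]), 0L)

  # brute-force search for an equidistant witness among single/double edits
  witness <- NULL
  bases <- c("A", "C", "G", "T")
  v <- strsplit(refs[["lys3"]], "")[[1]]
  found <- FALSE
  for (i in seq_along(v)) {
    for (bi in bases[bases != v[i]]) {
      w <- v; w[i] <- bi
      for (j in seq_along(w)) {
        for (bj in bases[bases != w[j]]) {
          u <- w; u[j] <- bj
          s <- paste0(u, collapse = "")
          d <- as.integer(utils::adist(s, refs))
          if (d[1] == d[2]) { witness <- s; found <- TRUE; break }
        }
        if (found) break
      }
      if (found) break
    }
    if (found) break
  }
  expect_false(is.null(witness))
  expect_identical(classifyPBS(witness)$label, "ambiguous")

  # label is invariant under reference order
  swapped <- classifyPBS(refs[["lys12"]], refs = refs[c("lys12", "lys3")])
  expect_identical(swapped$label, "lys12")

  # variant report against the winning reference
  oneSub <- paste0("A", substr(refs[["lys3"]], 2, 18))
  call <- classifyPBS(oneSub)
  expect_identical(call$label, "lys3")
  expect_identical(call$variants$type, "substitution")
  expect_identical(call$variants$pos, 1L)
})

test_that("orfStatus distinguishes open, frameshift and premature stop", {
  orf <- function(codons) paste0(codons, collapse = "")
  open <- orf(c("ATG", "CGA", "TTA", "GGC", "TAA"))
  expect_identical(orfStatus(open, 15)$state, "open")

  # single-nt deletion -> frameshift
  del <- sub("G", "", open)
  expect_identical(orfStatus(del, 15)$state, "frameshift_indel")

  # CGA -> TGA mid-gene: CpG-type C->T creating a premature stop
  stopSeq <- orf(c("ATG", "TGA", "TTA", "GGC", "TAA"))
  st <- orfStatus(stopSeq, 15)
  expect_identical(st$state, "premature_stop")
  expect_identical(st$detail, 4L)

  # in-frame 3-nt indel keeps the frame
  infr <- orf(c("ATG", "CGA", "AAA", "TTA", "GGC", "TAA"))
  expect_identical(orfStatus(infr, 15)$state, "open")

  # synonymous changes that introduce no stop keep the gene open
  syn <- orf(c("ATG", "CGG", "TTG", "GGA", "TAA"))
  expect_identical(orfStatus(syn, 15)$state, "open")
})

test_that("validateProvirus flags LTR pairs that do not cluster", {
  cohort <- c(0.02, 0.03, 0.04, 0.03, 0.025)
  expect_identical(validateProvirus(0.02, cohort)$status, "valid")
  expect_identical(validateProvirus(0, cohort)$status, "valid")
  expect_identical(validateProvirus(0.75, cohort)$status, "suspect_assembly")
  # exceeding 3x the cohort median is enough even under the cap
  expect_identical(validateProvirus(0.12, cohort)$status, "suspect_assembly")

  # a shuffled 3' LTR sits near random expectation and is flagged
  ltr <- randomSeq(480, seed = 20)
  shuf <- withr::with_seed(21,
    paste0(sample(strsplit(ltr, "")[[1]]), collapse = ""))
  k <- tryCatch(kValue(k2pDistance(ltr, shuf)),
                ervkit_saturation_error = function(e) NA_real_)
  if (!is.na(k)) expect_gt(k, 0.5)
  rec <- provirusRecord("x", paste0(ltr, randomSeq(1000, seed = 22), shuf),
                        ltr5 = c(1, 480), ltr3 = c(1481, 1960))
  expect_identical(validateProvirus(rec, cohort)$status, "suspect_assembly")
})

test_that("flanksMatch compares integration-site flanks", {
  params <- simParams(provirusLength = 1200, ltrLength = 420,
                      cpgTargetCount = 25)
  anc <- makeAncestor(params, seed = 30)
  host <- randomSeq(600, seed = 31)
  a <- integrateProvirus(host, anc, 200, params, id = "a")$record
  b <- integrateProvirus(host, anc, 200, params, id = "b")$record
  expect_true(flanksMatch(a, b))

  # different positions in the same host: random 50-mers diverge far beyond
  # 10%, verified by direct identity count
  c2 <- integrateProvirus(host, anc, 400, params, id = "c")$record
  va <- substr(host, 150, 199); vc <- substr(host, 350, 399)
  ident <- mean(strsplit(va, "")[[1]] == strsplit(vc, "")[[1]])
  expect_lt(ident, 0.9)
  expect_false(flanksMatch(a, c2))

  # same position with 4% flank divergence still matches (0.96 >= 0.9)
  hostMut <- mutateAt(host, c(160, 180, 520, 540), seed = 32)
  d <- integrateProvirus(hostMut, anc, 200, params, id = "d")$record
  expect_true(flanksMatch(a, d))

  short <- provirusRecord("s", paste0("ACGTAC",
                                      as.character(locusSeq(anc)), "ACGTAC"),
                          ltr5 = c(7, 426), ltr3 = c(787, 1206))
  expect_error(flanksMatch(a, short), class = "ervkit_flank_error")
})

test_that("TSD round-trip holds for every undamaged simulated locus", {
  params <- simParams(provirusLength = 1500, ltrLength = 430,
                      cpgTargetCount = 30)
  anc <- makeAncestor(params, seed = 40)
  withr::with_seed(41, {
    for (i in 1:20) {
      host <- randomSeq(800)
      pos <- sample(100:600, 1)
      intd <- integrateProvirus(host, anc, pos, params, id = paste0("l", i))
      got <- detectTSD(locusSeq(intd$record),
                       c(intd$truth$provStart, intd$truth$provEnd))
      expect_identical(got, intd$truth$tsd)
    }
  })
})
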