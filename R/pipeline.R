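# Orchestration: run the full characterization workflow over a set of
# provirus loci and emit per-stage TSV tables plus a machine-readable JSON
# summary. Every number in the summary is recomputable from the per-stage
# tables.

#' Pipeline configuration
#'
#' @param rates fast/slow substitution rates, see [rateSet()].
#' @param gammaShape optional gamma shape for distances.
#' @param minLtrLen,minLtrIdentity,ltrTerminalFrac LTR detection thresholds
#'   (see [extractLTRs()]); raise `ltrTerminalFrac` when loci carry host
#'   flanks that are long relative to the provirus.
#' @param validationMultiple,validationCap mis-assembly thresholds
#'   (see [validateProvirus()]).
#' @param apobecPattern,nonApobec3GPattern hypermutation patterns scanned;
#'   defaults: `K-(G>A)-D | control K-(G>A)-N` (3G-type, CpG excluded) and
#'   `D-(G>A)-AD | control D-(G>A)-N` (non-3G).
#' @param tsdLength TSD length checked.
#' @param minCoverage column-coverage filter applied to a supplied alignment.
#' @return a list of class `RunConfig`.
#' @export
pipelineConfig <- function(rates = rateSet(), gammaShape = NULL,
                           minLtrLen = 400L, minLtrIdentity = 0.85,
                           ltrTerminalFrac = 0.10,
                           validationMultiple = 3, validationCap = 0.15,
                           apobecPattern =
                             parseMutationPattern("K-(G>A)-D | control K-(G>A)-N"),
                           nonApobec3GPattern =
                             parseMutationPattern("D-(G>A)-AD | control D-(G>A)-N"),
                           tsdLength = 6L, minCoverage = 0.95) {
  cfg <- list(rates = rates, gammaShape = gammaShape, minLtrLen = minLtrLen,
              minLtrIdentity = minLtrIdentity,
              ltrTerminalFrac = ltrTerminalFrac,
              validationMultiple = validationMultiple,
              validationCap = validationCap, apobecPattern = apobecPattern,
              nonApobec3GPattern = nonApobec3GPattern,
              tsdLength = tsdLength, minCoverage = minCoverage)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full provirus characterization workflow
#'
#' Stages: structural features (LTR pair, TSD, PBS), cohort validation,
#' LTR-divergence dating under both rates, CpG census and hypermutation scans
#' against the cohort consensus, and Tajima's D on the (trivially aligned,
#' equal-length) provirus set. Input is either a named list of
#' [ProvirusRecord-class] objects (e.g. `generateCohort()$records`) or the
#' path of a FASTA file of loci, in which case LTRs/TSD/PBS are detected from
#' sequence.
#'
#' @param loci list of `ProvirusRecord`s or a FASTA path.
#' @param outDir optional output directory; when given, writes
#'   `features.tsv`, `ages.tsv`, `signatures.tsv` and `summary.json`.
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list with `features`, `ages`, `signatures`
#'   data.frames, the `tajima` result (or `NULL`), and `summary`.
#' @export
runPipeline <- function(loci, outDir = NULL, config = pipelineConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.character(loci) && length(loci) == 1L) {
    seqs <- readFasta(loci)
    loci <- lapply(seq_along(seqs), function(i) {
      s <- as.character(seqs[[i]])
      lt <- extractLTRs(s, minLen = config$minLtrLen,
                        minIdentity = config$minLtrIdentity,
                        terminalFrac = config$ltrTerminalFrac)
      provirusRecord(id = names(seqs)[i], locus = s,
                     ltr5 = lt$ltr5, ltr3 = lt$ltr3,
                     ltrBounds = range(c(400L, 520L, IRanges::width(lt$ltr5),
                                         IRanges::width(lt$ltr3))))
    })
    names(loci) <- vapply(loci, function(r) r@id, character(1))
  }
  stopifnot(length(loci) >= 1L)

  # --- stage 1: structural features -------------------------------------
  features <- do.call(rbind, lapply(loci, function(r) {
    tsd <- tryCatch(detectTSD(locusSeq(r),
                              c(IRanges::start(r@ltr5), IRanges::end(r@ltr3)),
                              tsdLen = config$tsdLength),
                    ervkit_flank_error = function(e) NA_character_)
    pbs <- tryCatch(extractPBS(locusSeq(r), r@ltr5),
                    ervkit_flank_error = function(e) NA_character_)
    call <- if (!is.na(pbs)) classifyPBS(pbs) else NULL
    data.frame(id = r@id, strand = r@strand,
               ltr5Start = IRanges::start(r@ltr5),
               ltr5End = IRanges::end(r@ltr5),
               ltr3Start = IRanges::start(r@ltr3),
               ltr3End = IRanges::end(r@ltr3),
               tsd = ifelse(is.na(tsd), "absent", tsd),
               pbs = ifelse(is.na(pbs), "absent", pbs),
               pbsLabel = if (is.null(call)) "absent" else call$label,
               genotype = r@genotype)
  }))

  # --- stage 2: LTR distances, validation, dating ------------------------
  ltrK <- vapply(loci, function(r) {
    tryCatch(provirusAge(r, config$rates, config$gammaShape)$K,
             ervkit_error = function(e) NA_real_)
  }, numeric(1))
  ages <- do.call(rbind, lapply(seq_along(loci), function(i) {
    r <- loci[[i]]
    val <- validateProvirus(if (is.na(ltrK[i])) NA_real_ else ltrK[i],
                            ltrK[!is.na(ltrK)],
                            multiple = config$validationMultiple,
                            cap = config$validationCap)
    fast <- if (!is.na(ltrK[i]))
      ageMyr(dateIntegration(ltrK[i], config$rates[["fast"]])) else NA_real_
    slow <- if (!is.na(ltrK[i]))
      ageMyr(dateIntegration(ltrK[i], config$rates[["slow"]])) else NA_real_
    data.frame(id = r@id, K = ltrK[i], status = val$status,
               tFastMyr = fast, tSlowMyr = slow,
               tFastLabel = if (is.na(ltrK[i])) "NA"
                            else formatAgeMyr(fast, K = ltrK[i]),
               tSlowLabel = if (is.na(ltrK[i])) "NA"
                            else formatAgeMyr(slow, K = ltrK[i]))
  }))

  # --- stage 3: signatures against the cohort consensus ------------------
  provSeqs <- vapply(loci, function(r) {
    substr(as.character(locusSeq(r)), IRanges::start(r@ltr5),
           IRanges::end(r@ltr3))
  }, character(1))
  sameLen <- length(unique(nchar(provSeqs))) == 1L
  signatures <- NULL
  tajima <- NULL
  if (sameLen && length(loci) >= 2L) {
    aln <- ProviralAlignment(provSeqs)
    cons <- as.character(consensusSequence(aln))
    signatures <- do.call(rbind, lapply(names(provSeqs), function(id) {
      cen <- cpgCensus(cons, provSeqs[[id]])
      h3g <- hypermutScan(cons, provSeqs[[id]], config$apobecPattern)
      hn3g <- hypermutScan(cons, provSeqs[[id]], config$nonApobec3GPattern)
      data.frame(id = id, cpgSites = cen@nCpGSites, tpg = cen@nTpG,
                 cpa = cen@nCpA, cpgFraction = fractionMutated(cen),
                 a3gMut = h3g@matchedMutations, a3gPot = h3g@matchedPotentials,
                 a3gRateRatio = rateRatio(h3g), a3gP = pValue(h3g),
                 non3gMut = hn3g@matchedMutations,
                 non3gPot = hn3g@matchedPotentials,
                 non3gRateRatio = rateRatio(hn3g), non3gP = pValue(hn3g))
    }))
    tajima <- withCallingHandlers(
      tajimasD(aln),
      warning = function(w) invokeRestart("muffleWarning"))
  }

  # --- summary ------------------------------------------------------------
  okAges <- ages[!is.na(ages$K) & ages$status == "valid", , drop = FALSE]
  summary <- list(
    nLoci = length(loci),
    nValid = sum(ages$status == "valid"),
    nSuspect = sum(ages$status == "suspect_assembly"),
    tsdDetectedFraction = mean(features$tsd != "absent"),
    pbsTally = as.list(table(features$pbsLabel)),
    meanLtrK = if (nrow(okAges)) mean(okAges$K) else NA,
    ageFast = if (nrow(okAges))
      list(meanMyr = mean(okAges$tFastMyr), sdMyr = if (nrow(okAges) > 1L)
           sd(okAges$tFastMyr) else NA, minMyr = min(okAges$tFastMyr),
           maxMyr = max(okAges$tFastMyr)) else NULL,
    ageSlow = if (nrow(okAges))
      list(meanMyr = mean(okAges$tSlowMyr), sdMyr = if (nrow(okAges) > 1L)
           sd(okAges$tSlowMyr) else NA, minMyr = min(okAges$tSlowMyr),
           maxMyr = max(okAges$tSlowMyr)) else NULL,
    cpgFractionMean = if (!is.null(signatures))
      mean(signatures$cpgFraction, na.rm = TRUE) else NA,
    a3gSignificant = if (!is.null(signatures))
      sum(signatures$a3gP < 0.05, na.rm = TRUE) else NA,
    non3gSignificant = if (!is.null(signatures))
      sum(signatures$non3gP < 0.05, na.rm = TRUE) else NA,
    tajima = if (!is.null(tajima))
      list(n = tajima@n, S = tajima@S, pi = tajima@pi, D = tajimaD(tajima))
      else NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) write.table(df, file.path(outDir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    wt(features, "features.tsv")
    wt(ages, "ages.tsv")
    if (!is.null(signatures)) wt(signatures, "signatures.tsv")
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(list(features = features, ages = ages, signatures = signatures,
                 tajima = tajima, summary = summary))
}
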