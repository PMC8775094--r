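# Context-dependent hypermutation scanning (APOBEC3-type G->A signatures),
# the CpG deamination census, and the exact test used throughout.

# Qualifying focal sites for a context pattern: positions i where the
# reference holds `from` and both reference and query match the IUPAC
# upstream/downstream contexts ("enforced" mode: a mutation in a query
# context base disqualifies the site). A gap anywhere in the window (either
# sequence) disqualifies the site: a context interrupted by a gap does not
# match.
.contextSites <- function(rv, qv, from, upstream, downstream) {
  up <- strsplit(upstream, "", fixed = TRUE)[[1L]]
  down <- strsplit(downstream, "", fixed = TRUE)[[1L]]
  ulen <- length(up); dlen <- length(down)
  L <- length(rv)
  lo <- ulen + 1L; hi <- L - dlen
  if (lo > hi) return(integer())
  cand <- which(rv == from)
  cand <- cand[cand >= lo & cand <= hi]
  if (!length(cand)) return(integer())
  ok <- qv[cand] != "-"
  offs <- c(if (ulen) -(ulen:1) else integer(), if (dlen) 1:dlen else integer())
  codes <- c(up, down)
  for (k in seq_along(offs)) {
    pos <- cand + offs[k]
    ok <- ok & rv[pos] != "-" & qv[pos] != "-" &
      .iupacOK(rv[pos], codes[k]) & .iupacOK(qv[pos], codes[k])
  }
  cand[ok]
}

#' Scan a query for context-dependent hypermutation against a reference
#'
#' HYPERMUT-style scan: a *potential* site is a reference position holding
#' the pattern's `from` base whose upstream/downstream contexts match on both
#' reference and query; a *matched mutation* is a potential site where the
#' query holds `to`. The control arm uses the control contexts, minus any
#' site that also satisfies the primary contexts (disjoint arms). Enrichment
#' of mutations in the matched arm is assessed with a one-sided exact test on
#' the 2x2 table of (mutations, non-mutated potentials) by arm.
#'
#' @param reference,query aligned sequences of equal length.
#' @param pattern a [MutationPattern-class] (see [mutationPattern()] /
#'   [parseMutationPattern()]).
#' @return a [HypermutReport-class].
#' @examples
#' p <- mutationPattern("K", "G", "A", "D")   # APOBEC3G-type, CpG excluded
#' hypermutScan("TGGT", "TGAT", p)
#' @export
hypermutScan <- function(reference, query, pattern) {
  stopifnot(is(pattern, "MutationPattern"))
  rv <- .seqChars(reference); qv <- .seqChars(query)
  if (length(rv) != length(qv)) {
    .ervError("ervkit_alignment_error",
              "reference and query must have equal aligned lengths")
  }
  primary <- .contextSites(rv, qv, pattern@from, pattern@upstream,
                           pattern@downstream)
  ctl <- .contextSites(rv, qv, pattern@from, pattern@controlUpstream,
                       pattern@controlDownstream)
  ctl <- setdiff(ctl, primary)
  mm <- sum(qv[primary] == pattern@to)
  cm <- sum(qv[ctl] == pattern@to)
  mp <- length(primary); cp <- length(ctl)
  if (mp == 0L && cp == 0L) {
    return(new("HypermutReport", matchedMutations = 0L,
               matchedPotentials = 0L, controlMutations = 0L,
               controlPotentials = 0L, rateRatio = NA_real_,
               pValue = NA_real_, note = "no potential sites in either arm"))
  }
  rr <- if (mp > 0L && cp > 0L && cm > 0L) {
    (mm / mp) / (cm / cp)
  } else NA_real_
  p <- fisherExact(matrix(c(mm, mp - mm, cm, cp - cm), 2L, byrow = TRUE),
                   sided = "one_greater")
  new("HypermutReport", matchedMutations = as.integer(mm),
      matchedPotentials = as.integer(mp), controlMutations = as.integer(cm),
      controlPotentials = as.integer(cp), rateRatio = rr, pValue = p,
      note = "")
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail with fixed margins. `"one_greater"` tests
#' enrichment of the top-left cell; `"two"` sums all outcomes whose
#' point probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @param sided `"one_greater"` (default) or `"two"`.
#' @return the p-value.
#' @examples
#' fisherExact(matrix(c(3, 7, 0, 10), 2, byrow = TRUE))  # 120/1140
#' @export
fisherExact <- function(table, sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  if (!is.matrix(table)) table <- matrix(table, 2L, byrow = TRUE)
  stopifnot(all(table >= 0), all(table == round(table)))
  a <- table[1L, 1L]
  m <- sum(table[1L, ])   # row 1 total ("white balls")
  n <- sum(table[2L, ])   # row 2 total
  k <- sum(table[, 1L])   # column 1 total (draws)
  if (m + n == 0L || k == 0L) return(1)
  support <- max(0L, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  if (sided == "one_greater") {
    sum(probs[support >= a])
  } else {
    pObs <- dhyper(a, m, n, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  }
}

#' Census CpG methylation-associated mutations against a reference
#'
#' CpG sites are enumerated on the reference (a `C` immediately followed by
#' `G`, skipping columns gapped in both sequences). At each site the query
#' state is classified: `CG -> TG` counts as a TpG (plus-strand deamination
#' of methyl-C), `CG -> CA` as a CpA (minus-strand deamination), any other
#' non-identical state as "other". Sites where the query holds a gap or `N`
#' at either position are not comparable and are excluded from the site
#' count.
#'
#' @param reference,query aligned sequences of equal length.
#' @return a [CpGCensus-class].
#' @export
cpgCensus <- function(reference, query) {
  rv <- .seqChars(reference); qv <- .seqChars(query)
  if (length(rv) != length(qv)) {
    .ervError("ervkit_alignment_error",
              "reference and query must have equal aligned lengths")
  }
  shared <- !(rv == "-" & qv == "-")
  rv <- rv[shared]; qv <- qv[shared]
  L <- length(rv)
  cpos <- which(rv[-L] == "C" & rv[-1L] == "G")
  nTpG <- 0L; nCpA <- 0L; nOther <- 0L; nSites <- 0L
  if (length(cpos)) {
    qc <- qv[cpos]; qg <- qv[cpos + 1L]
    comparable <- .isBase(qc) & .isBase(qg)
    qc <- qc[comparable]; qg <- qg[comparable]
    nSites <- sum(comparable)
    state <- paste0(qc, qg)
    nTpG <- sum(state == "TG")
    nCpA <- sum(state == "CA")
    nOther <- sum(state != "CG" & state != "TG" & state != "CA")
  }
  new("CpGCensus", nCpGSites = as.integer(nSites), nTpG = nTpG, nCpA = nCpA,
      nOther = nOther,
      fractionMutated = if (nSites > 0L) (nTpG + nCpA) / nSites else NA_real_)
}

#' Pooled TpG:CpA strand split of a census set
#'
#' Methylation-associated deamination acts on both strands; a pooled ratio
#' near 1 indicates orientation-independent CpG methylation.
#'
#' @param censusSet list of [CpGCensus-class] objects (or a single one).
#' @return list with `tpg`, `cpa` (pooled totals), `ratio`
#'   (`tpg/cpa`; `NA` when undefined) and `flag` (`TRUE` when either pooled
#'   total is zero).
#' @export
cpgStrandSplit <- function(censusSet) {
  if (is(censusSet, "CpGCensus")) censusSet <- list(censusSet)
  tpg <- sum(vapply(censusSet, function(x) x@nTpG, integer(1)))
  cpa <- sum(vapply(censusSet, function(x) x@nCpA, integer(1)))
  flag <- tpg == 0L || cpa == 0L
  list(tpg = tpg, cpa = cpa,
       ratio = if (cpa > 0L) tpg / cpa else NA_real_, flag = flag)
}
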