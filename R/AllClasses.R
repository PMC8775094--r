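#' @import methods
#' @importClassesFrom Biostrings DNAStringSet DNAString
#' @importClassesFrom IRanges IRanges
#' @importFrom stats median sd setNames dhyper runif rbinom
#' @importFrom utils adist write.table
NULL

# ---------------------------------------------------------------------------
# ProviralAlignment: an equal-width, named DNA multiple alignment
# ---------------------------------------------------------------------------

#' Multiple alignment of proviral sequences
#'
#' A thin S4 container extending [Biostrings::DNAStringSet] that guarantees
#' the invariants every alignment-consuming operation in this package relies
#' on: at least one sequence, all sequences of equal (positive) width, and
#' unique sequence ids. Gaps are `-`; ambiguous/missing bases are `N`.
#'
#' @slot ... inherits all slots from `DNAStringSet`.
#' @seealso [readAlignment()], [filterColumns()], [consensusSequence()]
#' @export
setClass("ProviralAlignment", contains = "DNAStringSet")

setValidity("ProviralAlignment", function(object) {
  if (length(object) < 1L) return("alignment must contain at least 1 sequence")
  w <- Biostrings::width(object)
  if (length(unique(w)) != 1L) {
    return(paste0("sequences have unequal lengths: ",
                  paste(w, collapse = ", ")))
  }
  if (w[1L] < 1L) return("alignment length must be >= 1")
  ids <- names(object)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    return("all sequences must be named")
  }
  if (anyDuplicated(ids)) {
    return(paste0("duplicate sequence id: ", ids[duplicated(ids)][1L]))
  }
  TRUE
})

#' Construct a ProviralAlignment
#'
#' @param x a named `DNAStringSet`, or a named character vector of
#'   equal-length aligned sequences (gap character `-`).
#' @return a [ProviralAlignment-class] object.
#' @examples
#' aln <- ProviralAlignment(c(s1 = "ACGT-", s2 = "ACGTA"))
#' alignmentLength(aln)
#' @export
ProviralAlignment <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  new("ProviralAlignment", x)
}

#' @describeIn ProviralAlignment-class number of alignment columns.
#' @param aln a `ProviralAlignment`.
#' @export
alignmentLength <- function(aln) Biostrings::width(aln)[1L]

# ---------------------------------------------------------------------------
# ProvirusRecord
# ---------------------------------------------------------------------------

#' One provirus locus with its structural annotation
#'
#' Bundles a (possibly host-flanked) provirus sequence with the coordinates
#' of its two long terminal repeats (LTRs), the detected target-site
#' duplication (TSD), the primer binding site (PBS), a genotype label, and
#' (for simulated or annotated records) named ORF coordinates.
#'
#' Coordinates are 1-based inclusive [IRanges::IRanges] on `locus`.
#'
#' @slot id single character, unique record id.
#' @slot locus a [Biostrings::DNAString], the locus sequence.
#' @slot strand `"+"` or `"-"`.
#' @slot ltr5,ltr3 length-1 `IRanges`; `ltr5` must precede and not overlap
#'   `ltr3`.
#' @slot tsd the 6-nt target-site duplication, or `NA` when absent.
#' @slot pbs the extracted PBS (17-19 nt), or `NA`.
#' @slot genotype `"SERV1"`, `"SERV2"`, or `"unassigned"`.
#' @slot orfs named `IRanges` of ORF coordinates (may be empty).
#' @export
setClass("ProvirusRecord",
  representation(id = "character", locus = "DNAString", strand = "character",
                 ltr5 = "IRanges", ltr3 = "IRanges", tsd = "character",
                 pbs = "character", genotype = "character", orfs = "IRanges"))

setValidity("ProvirusRecord", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || object@id == "")
    return("id must be a non-empty string")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (length(object@ltr5) != 1L || length(object@ltr3) != 1L)
    return("ltr5 and ltr3 must each be a single range")
  if (IRanges::end(object@ltr5) >= IRanges::start(object@ltr3))
    return("ltr5 must precede ltr3 without overlap")
  n <- length(object@locus)
  if (IRanges::start(object@ltr5) < 1L || IRanges::end(object@ltr3) > n)
    return("LTR spans fall outside the locus")
  if (!is.na(object@tsd) && nchar(object@tsd) != 6L)
    return("tsd must be exactly 6 nt when present")
  if (!is.na(object@pbs) && !nchar(object@pbs) %in% 17:19)
    return("pbs must be 17-19 nt when present")
  if (!object@genotype %in% c("SERV1", "SERV2", "unassigned"))
    return("genotype must be SERV1, SERV2 or unassigned")
  TRUE
})

#' Construct a ProvirusRecord
#'
#' @param id record id.
#' @param locus locus sequence (character or `DNAString`).
#' @param ltr5,ltr3 coordinate pairs `c(start, end)` or length-1 `IRanges`.
#' @param strand `"+"` (default) or `"-"`.
#' @param tsd,pbs detected TSD / PBS, `NA` when absent.
#' @param genotype genotype label.
#' @param orfs named `IRanges` of ORFs (optional).
#' @param ltrBounds permitted LTR length range, default `c(400, 520)` nt
#'   (the observed SERV LTR lengths, 439-495 nt, with slack).
#' @return a [ProvirusRecord-class].
#' @export
provirusRecord <- function(id, locus, ltr5, ltr3, strand = "+",
                           tsd = NA_character_, pbs = NA_character_,
                           genotype = "unassigned",
                           orfs = IRanges::IRanges(),
                           ltrBounds = c(400L, 520L)) {
  if (!is(locus, "DNAString")) {
    locus <- Biostrings::DNAString(toupper(as.character(locus)))
  }
  asRange <- function(x) {
    if (is(x, "IRanges")) x else IRanges::IRanges(x[1L], x[2L])
  }
  ltr5 <- asRange(ltr5); ltr3 <- asRange(ltr3)
  wl <- c(IRanges::width(ltr5), IRanges::width(ltr3))
  if (any(wl < ltrBounds[1L] | wl > ltrBounds[2L])) {
    .ervError("ervkit_ltr_bounds_error",
              sprintf("LTR lengths (%d, %d) outside permitted bounds [%d, %d]",
                      wl[1L], wl[2L], ltrBounds[1L], ltrBounds[2L]))
  }
  new("ProvirusRecord", id = id, locus = locus, strand = strand,
      ltr5 = ltr5, ltr3 = ltr3, tsd = tsd, pbs = pbs,
      genotype = genotype, orfs = orfs)
}

setMethod("show", "ProvirusRecord", function(object) {
  cat("ProvirusRecord '", object@id, "' (", length(object@locus), " nt, ",
      object@strand, " strand)\n", sep = "")
  cat(sprintf("  5' LTR %d-%d | 3' LTR %d-%d\n",
              IRanges::start(object@ltr5), IRanges::end(object@ltr5),
              IRanges::start(object@ltr3), IRanges::end(object@ltr3)))
  cat("  TSD:", ifelse(is.na(object@tsd), "absent", object@tsd),
      "| PBS:", ifelse(is.na(object@pbs), "absent", object@pbs),
      "| genotype:", object@genotype, "\n")
})

#' @describeIn ProvirusRecord-class locus sequence as `DNAString`.
#' @param x a `ProvirusRecord`.
#' @export
locusSeq <- function(x) x@locus

#' @describeIn ProvirusRecord-class LTR spans as a named list of `IRanges`.
#' @export
ltrSpans <- function(x) list(ltr5 = x@ltr5, ltr3 = x@ltr3)

#' @describeIn ProvirusRecord-class extract the two LTR sequences.
#' @export
ltrSequences <- function(x) {
  s <- as.character(x@locus)
  list(ltr5 = substr(s, IRanges::start(x@ltr5), IRanges::end(x@ltr5)),
       ltr3 = substr(s, IRanges::start(x@ltr3), IRanges::end(x@ltr3)))
}

# ---------------------------------------------------------------------------
# PairDistance / AgeEstimate
# ---------------------------------------------------------------------------

#' Kimura-2-parameter pairwise distance
#'
#' @slot P transition proportion; @slot Q transversion proportion;
#' @slot sites comparable sites used; @slot K corrected distance
#'   (substitutions/site); @slot gammaShape gamma shape used, `NA` for the
#'   plain (uniform-rate) form.
#' @seealso [k2pDistance()]
#' @export
setClass("PairDistance",
  representation(P = "numeric", Q = "numeric", sites = "integer",
                 K = "numeric", gammaShape = "numeric"))

setValidity("PairDistance", function(object) {
  if (object@P < 0 || object@Q < 0 || object@P + object@Q > 1)
    return("P and Q must be non-negative with P + Q <= 1")
  if (object@sites < 1L) return("sites must be >= 1")
  if (object@K < object@P + object@Q - 1e-12)
    return("corrected K cannot be smaller than the p-distance")
  TRUE
})

setMethod("show", "PairDistance", function(object) {
  cat(sprintf("K2P distance: K = %.6g (P = %.4g, Q = %.4g, %d sites%s)\n",
              object@K, object@P, object@Q, object@sites,
              if (is.na(object@gammaShape)) ""
              else sprintf(", gamma shape %.4g", object@gammaShape)))
})

#' Integration-age estimate from LTR divergence
#'
#' Holds `T = K / (2 r)` together with its inputs. `ageYears()` and
#' `ageMyr()` return the age in years and million years.
#'
#' @slot K LTR-pair distance (substitutions/site); @slot r substitution rate
#'   (substitutions/site/year); @slot years estimated age; @slot label free
#'   text naming the comparison.
#' @seealso [dateIntegration()]
#' @export
setClass("AgeEstimate",
  representation(K = "numeric", r = "numeric", years = "numeric",
                 label = "character"))

setValidity("AgeEstimate", function(object) {
  if (object@K < 0) return("K must be non-negative")
  if (object@r <= 0) return("rate r must be positive")
  if (abs(object@years - object@K / (2 * object@r)) >
      1e-9 * max(1, object@years))
    return("years must equal K / (2 r)")
  TRUE
})

setMethod("show", "AgeEstimate", function(object) {
  cat(sprintf("AgeEstimate%s: K = %.4g at r = %.3g s/s/y -> T = %s Myr\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              object@K, object@r,
              if (object@K == 0) "<0.3" else .fmtMyr(object@years / 1e6)))
})

#' @describeIn AgeEstimate-class age in years.
#' @param x an `AgeEstimate`.
#' @export
ageYears <- function(x) x@years

#' @describeIn AgeEstimate-class age in million years.
#' @export
ageMyr <- function(x) x@years / 1e6

#' K (substitutions/site) stored in a distance or age object
#' @param x a `PairDistance` or `AgeEstimate`.
#' @export
kValue <- function(x) x@K

#' Comparable sites used by a pairwise distance
#' @param x a `PairDistance`.
#' @export
siteCount <- function(x) x@sites

# ---------------------------------------------------------------------------
# MutationPattern / HypermutReport / CpGCensus
# ---------------------------------------------------------------------------

#' Context-dependent mutation pattern (HYPERMUT-style)
#'
#' Describes a focal substitution `from -> to` constrained by IUPAC upstream
#' and downstream contexts, plus the contexts defining the control arm.
#' Control sites are sites that match the control contexts but *not* the
#' primary contexts (disjoint arms).
#'
#' @slot upstream,downstream IUPAC context strings (may be empty).
#' @slot from,to single bases.
#' @slot controlUpstream,controlDownstream IUPAC context strings of the
#'   control arm.
#' @seealso [mutationPattern()], [hypermutScan()]
#' @export
setClass("MutationPattern",
  representation(upstream = "character", from = "character", to = "character",
                 downstream = "character", controlUpstream = "character",
                 controlDownstream = "character"))

setValidity("MutationPattern", function(object) {
  codes <- names(.IUPAC)
  chk <- function(s, what) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (length(ch) && !all(ch %in% codes))
      return(sprintf("%s contains non-IUPAC letters: %s", what, s))
    NULL
  }
  for (w in c("upstream", "downstream", "controlUpstream",
              "controlDownstream")) {
    bad <- chk(slot(object, w), w)
    if (!is.null(bad)) return(bad)
  }
  if (!object@from %in% c("A", "C", "G", "T") ||
      !object@to %in% c("A", "C", "G", "T"))
    return("from and to must be single unambiguous bases")
  if (object@from == object@to) return("from and to must differ")
  TRUE
})

#' @rdname MutationPattern-class
#' @param upstream,downstream IUPAC context strings of the primary pattern.
#' @param from,to focal substitution bases.
#' @param controlUpstream,controlDownstream control-arm contexts (default:
#'   same upstream, downstream `"N"`).
#' @return a [MutationPattern-class].
#' @examples
#' # APOBEC3G-type signature excluding CpG: K-(G>A)-D vs control K-(G>A)-N
#' mutationPattern("K", "G", "A", "D")
#' @export
mutationPattern <- function(upstream = "", from = "G", to = "A",
                            downstream = "", controlUpstream = upstream,
                            controlDownstream = "N") {
  new("MutationPattern", upstream = toupper(upstream), from = toupper(from),
      to = toupper(to), downstream = toupper(downstream),
      controlUpstream = toupper(controlUpstream),
      controlDownstream = toupper(controlDownstream))
}

#' Parse a text pattern specification
#'
#' Accepts the compact notation used in configuration files, e.g.
#' `"K-(G>A)-D | control K-(G>A)-N"`. The control part may be omitted, in
#' which case the control downstream context defaults to `N`.
#'
#' @param spec single character string.
#' @return a [MutationPattern-class].
#' @export
parseMutationPattern <- function(spec) {
  parts <- strsplit(spec, "|", fixed = TRUE)[[1L]]
  parseOne <- function(s) {
    s <- gsub("control", "", s, fixed = TRUE)
    s <- gsub("→", ">", gsub("\\s", "", s))
    m <- regmatches(s, regexec("^([A-Z]*)-?\\(([ACGT])>([ACGT])\\)-?([A-Z]*)$",
                               s))[[1L]]
    if (length(m) != 5L) {
      .ervError("ervkit_pattern_error",
                paste0("cannot parse mutation pattern: '", s, "'"))
    }
    m[-1L]
  }
  p <- parseOne(parts[1L])
  if (length(parts) > 1L) {
    ctl <- parseOne(parts[2L])
    if (ctl[2L] != p[2L] || ctl[3L] != p[3L]) {
      .ervError("ervkit_pattern_error",
                "control pattern must use the same focal substitution")
    }
    mutationPattern(p[1L], p[2L], p[3L], p[4L],
                    controlUpstream = ctl[1L], controlDownstream = ctl[4L])
  } else {
    mutationPattern(p[1L], p[2L], p[3L], p[4L])
  }
}

#' Hypermutation scan report
#'
#' Counts of matched/control mutations and potential sites, the rate ratio
#' `(mm/mp)/(cm/cp)` and the one-sided exact-test p-value for enrichment of
#' mutations in the matched arm.
#'
#' @slot matchedMutations,matchedPotentials,controlMutations,controlPotentials
#'   integer counts; @slot rateRatio numeric (`NA` when a denominator is 0);
#' @slot pValue numeric in (0, 1], `NA` when no potentials exist;
#' @slot note character, non-empty when the report is degenerate.
#' @seealso [hypermutScan()]
#' @export
setClass("HypermutReport",
  representation(matchedMutations = "integer", matchedPotentials = "integer",
                 controlMutations = "integer", controlPotentials = "integer",
                 rateRatio = "numeric", pValue = "numeric", note = "character"))

setValidity("HypermutReport", function(object) {
  if (object@matchedMutations > object@matchedPotentials ||
      object@controlMutations > object@controlPotentials)
    return("mutations cannot exceed potentials")
  TRUE
})

setMethod("show", "HypermutReport", function(object) {
  cat(sprintf(
    "HypermutReport: matched %d/%d, control %d/%d, rate ratio %s, p = %s%s\n",
    object@matchedMutations, object@matchedPotentials,
    object@controlMutations, object@controlPotentials,
    ifelse(is.na(object@rateRatio), "undefined",
           sprintf("%.3g", object@rateRatio)),
    ifelse(is.na(object@pValue), "NA", sprintf("%.4g", object@pValue)),
    ifelse(nzchar(object@note), paste0(" [", object@note, "]"), "")))
})

#' @describeIn HypermutReport-class exact-test p-value.
#' @param x a `HypermutReport`.
#' @export
pValue <- function(x) x@pValue

#' @describeIn HypermutReport-class matched/control rate ratio.
#' @export
rateRatio <- function(x) x@rateRatio

#' CpG deamination census
#'
#' Per-query counts of reference CpG sites and their mutated states:
#' CpG -> TpG (plus-strand deamination) and CpG -> CpA (minus strand).
#'
#' @slot nCpGSites reference CpG sites comparable in the query;
#' @slot nTpG,nCpA,nOther mutated-site counts; @slot fractionMutated
#'   `(nTpG + nCpA) / nCpGSites`.
#' @seealso [cpgCensus()]
#' @export
setClass("CpGCensus",
  representation(nCpGSites = "integer", nTpG = "integer", nCpA = "integer",
                 nOther = "integer", fractionMutated = "numeric"))

setValidity("CpGCensus", function(object) {
  if (object@nTpG + object@nCpA > object@nCpGSites)
    return("nTpG + nCpA cannot exceed nCpGSites")
  if (!is.na(object@fractionMutated) &&
      (object@fractionMutated < 0 || object@fractionMutated > 1))
    return("fractionMutated must lie in [0, 1]")
  TRUE
})

setMethod("show", "CpGCensus", function(object) {
  cat(sprintf("CpGCensus: %d CpG sites, %d TpG + %d CpA (+%d other) = %s\n",
              object@nCpGSites, object@nTpG, object@nCpA, object@nOther,
              ifelse(is.na(object@fractionMutated), "NA",
                     sprintf("%.1f%% mutated",
                             100 * object@fractionMutated))))
})

#' @describeIn CpGCensus-class fraction of CpG sites mutated to TpG or CpA.
#' @param x a `CpGCensus`.
#' @export
fractionMutated <- function(x) x@fractionMutated

# ---------------------------------------------------------------------------
# TajimaResult
# ---------------------------------------------------------------------------

#' Tajima's D result
#'
#' @slot n sequences; @slot S segregating sites; @slot sitesUsed columns kept
#'   after complete deletion; @slot pi mean pairwise difference count (per
#'   alignment); @slot piPerSite `pi / sitesUsed`; @slot D the statistic
#'   (`NA` when `S = 0`); @slot note warnings (e.g. small n).
#' @seealso [tajimasD()]
#' @export
setClass("TajimaResult",
  representation(n = "integer", S = "integer", sitesUsed = "integer",
                 pi = "numeric", piPerSite = "numeric", D = "numeric",
                 note = "character"))

setMethod("show", "TajimaResult", function(object) {
  cat(sprintf("Tajima's D: n = %d, S = %d (over %d sites), pi = %.4g, D = %s%s\n",
              object@n, object@S, object@sitesUsed, object@pi,
              ifelse(is.na(object@D), "undefined", sprintf("%.4f", object@D)),
              ifelse(nzchar(object@note), paste0(" [", object@note, "]"), "")))
})

#' @describeIn TajimaResult-class the D statistic.
#' @param x a `TajimaResult`.
#' @export
tajimaD <- function(x) x@D
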