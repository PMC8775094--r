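# Structural features of provirus loci: terminal LTR detection, target-site
# duplications, PBS extraction/classification, ORF interruption scanning, and
# cohort-level validity checks.

#' PBS reference 18-mers
#'
#' The two tRNA-lysine primer binding sites that distinguish the SERV
#' genotypes: PBS-lys3 (`TGGCGCCCGAACAGGGAC`, SERV-1) and PBS-lys1,2
#' (`TGGCGCCCAACGTGGGGC`, SERV-2).
#'
#' @return named character vector with elements `lys3` and `lys12`.
#' @export
pbsReferences <- function() {
  c(lys3 = "TGGCGCCCGAACAGGGAC", lys12 = "TGGCGCCCAACGTGGGGC")
}

#' Locate the terminal LTR pair of a provirus
#'
#' Finds the highest-scoring pair of same-orientation terminal direct
#' repeats: a local alignment between the head and tail regions of the
#' sequence, with the 5' copy required to start within the first
#' `terminalFrac` of the sequence and the 3' copy to end within the last
#' `terminalFrac`. Candidate pairs must be at least `minLen` nt long with at
#' least `minIdentity` identity. Because retroviral LTRs begin with `TG` and
#' end with `CA`, span boundaries are refined to that motif (within
#' `snapWindow` nt) when both copies carry it, which removes chance
#' extensions of the alignment into flanking sequence.
#'
#' @param x provirus sequence (character or `DNAString`), possibly with host
#'   flanks.
#' @param minLen minimum LTR length, default 400 nt.
#' @param minIdentity minimum LTR-pair identity, default 0.85.
#' @param terminalFrac terminal anchoring fraction, default 0.10.
#' @param snapWindow search window (nt) for the TG...CA boundary motif;
#'   `0` disables refinement.
#' @return list with `ltr5`, `ltr3` (length-1 `IRanges`, 1-based inclusive)
#'   and `identity` (fraction). Errors with class
#'   `ervkit_no_ltr` when no qualifying repeat pair exists.
#' @export
extractLTRs <- function(x, minLen = 400L, minIdentity = 0.85,
                        terminalFrac = 0.10, snapWindow = 6L) {
  v <- .seqChars(x)
  n <- length(v)
  if (n < 2L * minLen) {
    .ervError("ervkit_no_ltr",
              sprintf("sequence (%d nt) shorter than two LTRs", n))
  }
  margin <- floor(terminalFrac * n)
  # head/tail search windows never cross the midpoint: the two LTR copies
  # cannot overlap, and overlapping windows would self-align
  headEnd <- min(n %/% 2L, margin + 600L)
  tailStart <- max(n %/% 2L + 1L, n - margin - 600L + 1L)
  headSeq <- Biostrings::DNAString(.collapse(v[1:headEnd]))
  tailSeq <- Biostrings::DNAString(.collapse(v[tailStart:n]))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(headSeq, tailSeq, type = "local",
                                      substitutionMatrix = sm,
                                      gapOpening = 2, gapExtension = 1)
  p <- Biostrings::pattern(pa); s <- Biostrings::subject(pa)
  ltr5 <- c(Biostrings::start(p), Biostrings::end(p))
  ltr3 <- c(tailStart - 1L + Biostrings::start(s),
            tailStart - 1L + Biostrings::end(s))
  identity <- Biostrings::pid(pa) / 100

  # Snap boundaries to the canonical TG...CA LTR termini when both copies
  # agree (only attempted for indel-free alignments, where one offset moves
  # both copies in register).
  if (snapWindow > 0L && Biostrings::nindel(pa)@insertion[1L] == 0L &&
      Biostrings::nindel(pa)@deletion[1L] == 0L) {
    snap <- function(pos5, pos3, motif, anchor) {
      offs <- seq(-snapWindow, snapWindow)
      for (d in offs[order(abs(offs))]) {
        i5 <- pos5 + d; i3 <- pos3 + d
        idx <- if (anchor == "start") 0:1 else -1:0
        if (i5 + min(idx) >= 1L && i3 + max(idx) <= n &&
            identical(v[i5 + idx], motif) && identical(v[i3 + idx], motif)) {
          return(d)
        }
      }
      NA_integer_
    }
    dStart <- snap(ltr5[1L], ltr3[1L], c("T", "G"), "start")
    dEnd <- snap(ltr5[2L], ltr3[2L], c("C", "A"), "end")
    if (!is.na(dStart)) { ltr5[1L] <- ltr5[1L] + dStart
                          ltr3[1L] <- ltr3[1L] + dStart }
    if (!is.na(dEnd))   { ltr5[2L] <- ltr5[2L] + dEnd
                          ltr3[2L] <- ltr3[2L] + dEnd }
    if (!is.na(dStart) || !is.na(dEnd)) {
      a <- v[ltr5[1L]:ltr5[2L]]; b <- v[ltr3[1L]:ltr3[2L]]
      identity <- mean(a == b)
    }
  }

  width <- c(ltr5[2L] - ltr5[1L] + 1L, ltr3[2L] - ltr3[1L] + 1L)
  anchored <- ltr5[1L] <= max(1L, margin) && ltr3[2L] >= n - margin + 1L
  if (any(width < minLen) || identity < minIdentity || !anchored) {
    .ervError("ervkit_no_ltr",
              sprintf(paste0("no terminal repeat pair with length >= %d, ",
                             "identity >= %.2f and terminal anchoring found"),
                      minLen, minIdentity))
  }
  list(ltr5 = IRanges::IRanges(ltr5[1L], ltr5[2L]),
       ltr3 = IRanges::IRanges(ltr3[1L], ltr3[2L]),
       identity = identity)
}

#' Detect a target-site duplication around a provirus
#'
#' A `tsdLen`-nt host duplication immediately flanking the provirus on both
#' sides is the hallmark of integrase-driven insertion. The match must be
#' exact (the duplication is treated as binary evidence); any mismatch,
#' gap or `N` yields `NA`.
#'
#' @param locus locus sequence containing the provirus plus host flanks.
#' @param provirusSpan `c(start, end)` or length-1 `IRanges` of the provirus
#'   within `locus`.
#' @param tsdLen duplication length, default 6 nt.
#' @return the TSD string, or `NA_character_` when absent.
#' @export
detectTSD <- function(locus, provirusSpan, tsdLen = 6L) {
  v <- .seqChars(locus)
  if (is(provirusSpan, "IRanges")) {
    provirusSpan <- c(IRanges::start(provirusSpan), IRanges::end(provirusSpan))
  }
  s <- provirusSpan[1L]; e <- provirusSpan[2L]
  if (s - tsdLen < 1L || e + tsdLen > length(v)) {
    .ervError("ervkit_flank_error",
              sprintf("fewer than %d nt of host flank on one side", tsdLen))
  }
  left <- v[(s - tsdLen):(s - 1L)]
  right <- v[(e + 1L):(e + tsdLen)]
  if (all(.isBase(left)) && identical(left, right)) .collapse(left)
  else NA_character_
}

#' Extract the primer binding site downstream of the 5' LTR
#'
#' Returns the 18 nt immediately 3' of the 5' LTR. When extending the window
#' to 19 nt yields a strictly smaller Levenshtein distance to both PBS
#' references (i.e. the site carries a single insertion), the 19-nt window is
#' returned instead.
#'
#' @param x locus sequence.
#' @param ltr5Span `c(start, end)` or length-1 `IRanges` of the 5' LTR.
#' @param refs PBS reference set, default [pbsReferences()].
#' @return the PBS string (18 or 19 nt).
#' @export
extractPBS <- function(x, ltr5Span, refs = pbsReferences()) {
  v <- .seqChars(x)
  if (is(ltr5Span, "IRanges")) {
    ltr5Span <- c(IRanges::start(ltr5Span), IRanges::end(ltr5Span))
  }
  from <- ltr5Span[2L] + 1L
  if (from + 17L > length(v)) {
    .ervError("ervkit_flank_error", "fewer than 18 nt follow the 5' LTR")
  }
  s18 <- .collapse(v[from:(from + 17L)])
  d18 <- min(adist(s18, refs))
  if (from + 18L <= length(v)) {
    s19 <- .collapse(v[from:(from + 18L)])
    if (min(adist(s19, refs)) < d18) return(s19)
  }
  s18
}

#' Classify a PBS against the tRNA-lys reference sites
#'
#' Levenshtein edit distances to PBS-lys3 and PBS-lys1,2 decide the label;
#' equal distances yield `"ambiguous"`. Variants (substitutions, insertions,
#' deletions) are reported against the winning reference, 1-based in the
#' reference.
#'
#' @param pbs PBS string (17-19 nt).
#' @param refs PBS reference set, default [pbsReferences()].
#' @return list with `label` (`"lys3"`, `"lys12"`, or `"ambiguous"`),
#'   `distances` (named integer vector), and `variants` (data.frame with
#'   columns `pos`, `type`, `ref`, `obs`).
#' @export
classifyPBS <- function(pbs, refs = pbsReferences()) {
  pbs <- toupper(pbs)
  stopifnot(nchar(pbs) %in% 17:19)
  d <- setNames(as.integer(adist(pbs, refs)), names(refs))
  label <- if (d[1L] == d[2L]) "ambiguous" else names(refs)[which.min(d)]
  variants <- data.frame(pos = integer(), type = character(),
                         ref = character(), obs = character())
  if (label != "ambiguous") {
    variants <- .alignmentVariants(pbs, refs[[label]])
  }
  list(label = label, distances = d, variants = variants)
}

# Global alignment of obs against ref with unit edit costs; returns the
# variant table (positions 1-based in ref; insertions take the position of
# the following reference base).
.alignmentVariants <- function(obs, ref) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(obs, ref, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 1)
  po <- .seqChars(as.character(Biostrings::alignedPattern(pa)))
  pr <- .seqChars(as.character(Biostrings::alignedSubject(pa)))
  refPos <- cumsum(pr != "-")
  out <- data.frame(pos = integer(), type = character(),
                    ref = character(), obs = character())
  for (i in seq_along(po)) {
    if (po[i] == pr[i]) next
    if (pr[i] == "-") {
      out <- rbind(out, data.frame(pos = refPos[i] + 1L, type = "insertion",
                                   ref = "-", obs = po[i]))
    } else if (po[i] == "-") {
      out <- rbind(out, data.frame(pos = refPos[i], type = "deletion",
                                   ref = pr[i], obs = "-"))
    } else {
      out <- rbind(out, data.frame(pos = refPos[i], type = "substitution",
                                   ref = pr[i], obs = po[i]))
    }
  }
  out
}

#' Scan a gene sequence for ORF interruptions
#'
#' A gapless gene sequence (excised by alignment coordinates against a
#' reference ORF) is `"frameshift_indel"` when its length differs from the
#' reference length by a non-multiple of 3, else `"premature_stop"` at the
#' first in-frame `TAA`/`TAG`/`TGA` before the terminal codon, else
#' `"open"`.
#'
#' @param geneSeq gapless gene sequence.
#' @param referenceLen reference ORF length (nt).
#' @param gene optional gene name carried through to the result.
#' @return list with `gene`, `state`, `detail` (1-based nt position of the
#'   first premature stop, the length difference for frameshifts, `NA` for
#'   open genes).
#' @export
orfStatus <- function(geneSeq, referenceLen, gene = NA_character_) {
  v <- .seqChars(geneSeq)
  v <- v[v != "-"]
  dlen <- length(v) - referenceLen
  if (dlen %% 3L != 0L) {
    return(list(gene = gene, state = "frameshift_indel", detail = dlen))
  }
  ncod <- length(v) %/% 3L
  if (ncod >= 2L) {
    starts <- seq(1L, by = 3L, length.out = ncod - 1L)  # exclude final codon
    codons <- paste0(v[starts], v[starts + 1L], v[starts + 2L])
    hit <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(hit)) {
      return(list(gene = gene, state = "premature_stop",
                  detail = starts[hit[1L]]))
    }
  }
  list(gene = gene, state = "open", detail = NA_integer_)
}

#' Validate a provirus record against its cohort
#'
#' A provirus whose 5' and 3' LTRs are far more divergent than is typical for
#' its cohort is likely a mis-assembly (the two LTRs "do not cluster"). The
#' record is flagged `suspect_assembly` when its LTR-pair K2P distance
#' exceeds `multiple` times the cohort median within-provirus LTR distance,
#' or exceeds the absolute cap, or when the distance is saturated.
#'
#' @param rec a [ProvirusRecord-class] (or a precomputed numeric LTR-pair K).
#' @param cohortLtrDistances numeric vector of within-provirus LTR distances
#'   for the cohort.
#' @param multiple multiple of the cohort median tolerated, default 3.
#' @param cap absolute distance cap, default 0.15.
#' @return list with `status` (`"valid"`/`"suspect_assembly"`) and `k`
#'   (`NA` when saturated).
#' @export
validateProvirus <- function(rec, cohortLtrDistances, multiple = 3,
                             cap = 0.15) {
  k <- if (is.numeric(rec)) {
    rec
  } else {
    ltrs <- ltrSequences(rec)
    tryCatch(kValue(k2pDistance(ltrs$ltr5, ltrs$ltr3)),
             ervkit_saturation_error = function(e) NA_real_)
  }
  if (is.na(k)) {
    return(list(status = "suspect_assembly", k = NA_real_))
  }
  med <- median(cohortLtrDistances, na.rm = TRUE)
  suspect <- (med > 0 && k > multiple * med) || k > cap
  list(status = if (suspect) "suspect_assembly" else "valid", k = k)
}

#' Do two provirus records share an integration site?
#'
#' Compares `window` nt of host flank on each side of the provirus;
#' both flank pairs must align with at least `minIdentity` identity
#' (position-wise, indel-free comparison).
#'
#' @param a,b [ProvirusRecord-class] objects whose `ltr5`/`ltr3` spans
#'   delimit the provirus within the locus.
#' @param window flank length compared, default 50 nt.
#' @param minIdentity required identity, default 0.9.
#' @return `TRUE` if both flanks match, else `FALSE`.
#' @export
flanksMatch <- function(a, b, window = 50L, minIdentity = 0.9) {
  getFlanks <- function(r) {
    v <- .seqChars(locusSeq(r))
    s <- IRanges::start(r@ltr5); e <- IRanges::end(r@ltr3)
    if (s - window < 1L || e + window > length(v)) {
      .ervError("ervkit_flank_error",
                sprintf("record '%s' has less than %d nt of flank",
                        r@id, window))
    }
    list(left = v[(s - window):(s - 1L)], right = v[(e + 1L):(e + window)])
  }
  fa <- getFlanks(a); fb <- getFlanks(b)
  mean(fa$left == fb$left) >= minIdentity &&
    mean(fa$right == fb$right) >= minIdentity
}
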