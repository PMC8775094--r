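# Kimura-2-parameter distances, transition/transversion accounting,
# nucleotide composition, and distance-based genotype assignment.

#' Count transitions, transversions and comparable sites for one pair
#'
#' Positions are comparable when both sequences hold an unambiguous base
#' (`A C G T`); gaps and `N` are excluded pairwise. Transitions are the
#' purine-purine (A/G) and pyrimidine-pyrimidine (C/T) mismatches;
#' transversions are all other mismatches.
#'
#' @param a,b aligned sequences of equal length (character scalar,
#'   `DNAString`, or character vector of bases).
#' @param mask optional logical vector of columns to use (e.g. a
#'   complete-deletion mask computed across a whole alignment).
#' @return list with `transitions`, `transversions`, `sites`.
#' @export
countDifferences <- function(a, b, mask = NULL) {
  av <- .seqChars(a); bv <- .seqChars(b)
  if (length(av) != length(bv)) {
    .ervError("ervkit_alignment_error",
              sprintf("sequences have unequal lengths (%d vs %d)",
                      length(av), length(bv)))
  }
  ok <- .isBase(av) & .isBase(bv)
  if (!is.null(mask)) ok <- ok & mask
  sites <- sum(ok)
  if (sites == 0L) {
    .ervError("ervkit_undefined_distance",
              "no comparable sites between the two sequences")
  }
  diff <- ok & av != bv
  ts <- sum(diff & .isTransition(av, bv))
  list(transitions = ts, transversions = sum(diff) - ts, sites = sites)
}

.k2pFromPQ <- function(P, Q, sites, gammaShape = NULL) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    .ervError("ervkit_saturation_error",
              sprintf(paste0("K2P correction undefined (saturation): ",
                             "P = %.4g, Q = %.4g"), P, Q))
  }
  if (is.null(gammaShape) || is.na(gammaShape)) {
    K <- -0.5 * log(w1) - 0.25 * log(w2)
    gammaShape <- NA_real_
  } else {
    a <- gammaShape
    K <- (a / 2) * (w1^(-1 / a) - 1) + (a / 4) * (w2^(-1 / a) - 1)
  }
  new("PairDistance", P = P, Q = Q, sites = as.integer(sites), K = K,
      gammaShape = gammaShape)
}

#' Kimura-2-parameter distance between two aligned sequences
#'
#' With transition proportion `P` and transversion proportion `Q` over the
#' comparable sites, the plain form is
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`; the gamma-distributed-rates
#' form with shape `a` is
#' `K = a/2 ((1-2P-Q)^(-1/a) - 1) + a/4 ((1-2Q)^(-1/a) - 1)`.
#'
#' @inheritParams countDifferences
#' @param gammaShape positive gamma shape, or `NULL` (default) for the plain
#'   correction.
#' @return a [PairDistance-class].
#' @examples
#' a <- paste(rep("A", 100), collapse = "")
#' k2pDistance("ACGT", "ACGT")        # K = 0
#' @export
k2pDistance <- function(a, b, gammaShape = NULL, mask = NULL) {
  cd <- countDifferences(a, b, mask = mask)
  .k2pFromPQ(cd$transitions / cd$sites, cd$transversions / cd$sites,
             cd$sites, gammaShape)
}

# Complete-deletion column mask: TRUE for columns where every sequence holds
# an unambiguous base.
.completeMask <- function(m) {
  colSums(array(!(m %in% c("A", "C", "G", "T")), dim(m))) == 0L
}

#' Columns occupied by CpG dinucleotides in a reference sequence
#'
#' Returns the (1-based) positions of both the C and the G of every CpG in
#' `reference`; these are the columns removed by
#' `distanceMatrix(..., excludeCpG = TRUE)`.
#'
#' @param reference character scalar or `DNAString`.
#' @return sorted integer vector of positions.
#' @export
cpgColumns <- function(reference) {
  v <- .seqChars(reference)
  cpos <- which(v[-length(v)] == "C" & v[-1L] == "G")
  sort(unique(c(cpos, cpos + 1L)))
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Under `policy = "pairwise"` each pair excludes only its own gap/`N`
#' positions; under `policy = "complete"` every column containing a gap or
#' `N` in any sequence is dropped once for the whole set. With
#' `excludeCpG = TRUE`, columns that are part of a CpG dinucleotide in
#' `reference` (default: the majority consensus) are removed first.
#'
#' @param aln a [ProviralAlignment-class] (>= 2 sequences).
#' @param policy `"pairwise"` (default) or `"complete"` gap deletion.
#' @param gammaShape optional gamma shape passed to [k2pDistance()].
#' @param excludeCpG drop CpG columns before computing distances.
#' @param reference sequence defining CpG columns when `excludeCpG = TRUE`;
#'   defaults to [consensusSequence()] of the alignment.
#' @return symmetric numeric matrix of K values with a zero diagonal;
#'   a pair with no comparable sites or a saturated correction yields `NA`
#'   with a warning.
#' @export
distanceMatrix <- function(aln, policy = c("pairwise", "complete"),
                           gammaShape = NULL, excludeCpG = FALSE,
                           reference = NULL) {
  policy <- match.arg(policy)
  stopifnot(is(aln, "ProviralAlignment"))
  if (length(aln) < 2L) {
    .ervError("ervkit_alignment_error",
              "distance matrix requires at least 2 sequences")
  }
  m <- .alnMatrix(aln)
  if (excludeCpG) {
    if (is.null(reference)) reference <- consensusSequence(aln)
    drop <- cpgColumns(reference)
    if (length(drop)) m <- m[, -drop, drop = FALSE]
    if (ncol(m) == 0L) {
      .ervError("ervkit_alignment_error",
                "all columns removed by the CpG filter")
    }
  }
  mask <- if (policy == "complete") .completeMask(m) else NULL
  n <- nrow(m)
  K <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      K[i, j] <- K[j, i] <- tryCatch(
        kValue(k2pDistance(m[i, ], m[j, ], gammaShape = gammaShape,
                           mask = mask)),
        ervkit_error = function(e) {
          warning("pair (", rownames(m)[i], ", ", rownames(m)[j], "): ",
                  conditionMessage(e), call. = FALSE)
          NA_real_
        })
    }
  }
  K
}

#' Observed transition/transversion ratio of an alignment
#'
#' Count-based estimator: total pairwise transitions divided by total
#' pairwise transversions over all sequence pairs. This approximates, but is
#' not, a maximum-likelihood estimate of the substitution bias; when no
#' transversion is observed the ratio is flagged infinite rather than
#' reported as a number.
#'
#' @inheritParams distanceMatrix
#' @return list with `R` (ratio; `Inf` when flagged), `transitions`,
#'   `transversions`, `infinite` (logical flag).
#' @export
tstvRatio <- function(aln, policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  stopifnot(is(aln, "ProviralAlignment"), length(aln) >= 2L)
  m <- .alnMatrix(aln)
  mask <- if (policy == "complete") .completeMask(m) else NULL
  ts <- 0L; tv <- 0L
  n <- nrow(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cd <- countDifferences(m[i, ], m[j, ], mask = mask)
      ts <- ts + cd$transitions
      tv <- tv + cd$transversions
    }
  }
  list(R = if (tv == 0L) Inf else ts / tv,
       transitions = ts, transversions = tv, infinite = tv == 0L)
}

#' Nucleotide composition of a sequence or region
#'
#' @param x sequence (character scalar or `DNAString`).
#' @param region optional `c(start, end)` (1-based inclusive) or length-1
#'   `IRanges` restricting the count.
#' @return named fractions of `A`, `C`, `G`, `T` summing to 1; gaps and `N`
#'   are excluded from the denominator.
#' @export
baseComposition <- function(x, region = NULL) {
  v <- .seqChars(x)
  if (!is.null(region)) {
    if (is(region, "IRanges")) {
      region <- c(IRanges::start(region), IRanges::end(region))
    }
    v <- v[region[1L]:region[2L]]
  }
  v <- v[.isBase(v)]
  if (length(v) == 0L) {
    .ervError("ervkit_undefined_distance",
              "no unambiguous bases left after filtering")
  }
  counts <- table(factor(v, levels = c("A", "C", "G", "T")))
  as.numeric(counts) / length(v) -> frac
  setNames(frac, c("A", "C", "G", "T"))
}

#' Assign a genotype by distance to two exemplar sequences
#'
#' The query is labelled after the nearer exemplar by K2P distance;
#' when the two distances differ by less than `tieMargin` the label is
#' `"unassigned"` (ties are never resolved arbitrarily). Assignment is by
#' whole-genome distance, not PBS, since primer-binding-site switching
#' between genotypes is common.
#'
#' @param x query sequence, aligned to both exemplars.
#' @param ref1,ref2 exemplar sequences of the two genotypes.
#' @param labels labels returned for `ref1`/`ref2` proximity.
#' @param tieMargin minimum |d1 - d2| needed to assign, default 0.01.
#' @inheritParams k2pDistance
#' @return list with `label`, `d1`, `d2`.
#' @export
classifyGenotype <- function(x, ref1, ref2, gammaShape = NULL,
                             tieMargin = 0.01,
                             labels = c("SERV1", "SERV2")) {
  d1 <- kValue(k2pDistance(x, ref1, gammaShape = gammaShape))
  d2 <- kValue(k2pDistance(x, ref2, gammaShape = gammaShape))
  label <- if (abs(d1 - d2) < tieMargin) "unassigned"
           else if (d1 < d2) labels[1L] else labels[2L]
  list(label = label, d1 = d1, d2 = d2)
}
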