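# Molecular dating of integrations from LTR divergence: T = K / (2 r).
# At integration the two LTRs are identical copies; each then accumulates
# substitutions at the host rate r, so their distance K clocks 2 r T.

#' Fast/slow substitution-rate pair for provirus dating
#'
#' Primate-ERV substitution rates span roughly 2.3-5e-9 substitutions per
#' site per year; ages are conventionally reported under both ends of the
#' range.
#'
#' @param fast,slow rates in substitutions/site/year.
#' @return named numeric vector `c(fast=, slow=)`.
#' @export
rateSet <- function(fast = 5e-9, slow = 2.3e-9) {
  stopifnot(fast > 0, slow > 0, fast >= slow)
  c(fast = fast, slow = slow)
}

#' Date an integration from LTR divergence
#'
#' `T = K / (2 r)`: `K` is the pairwise distance between the 5' and 3' LTR
#' and `r` the substitution rate per site per year; the factor 2 reflects
#' that both LTR copies accumulate mutations independently.
#'
#' @param K LTR-pair distance (substitutions/site), or a
#'   [PairDistance-class].
#' @param r substitution rate (substitutions/site/year).
#' @param label free-text label carried into the estimate.
#' @return an [AgeEstimate-class].
#' @examples
#' ageMyr(dateIntegration(0.023, 5e-9))   # 2.3 Myr
#' @export
dateIntegration <- function(K, r, label = "") {
  if (is(K, "PairDistance")) K <- kValue(K)
  if (K < 0) .ervError("ervkit_dating_error", "K must be non-negative")
  stopifnot(r > 0)
  new("AgeEstimate", K = K, r = r, years = K / (2 * r), label = label)
}

#' Format an age in Myr the way dating tables print it
#'
#' Ages below the resolution of a single LTR substitution (i.e. `K = 0`)
#' print as `"<0.3"`: one substitution on a ~485-nt LTR at the fast rate
#' corresponds to about 0.2 Myr, reported as a `<0.3` Myr band.
#'
#' @param age an [AgeEstimate-class] or numeric Myr value.
#' @param K the distance (only needed when `age` is numeric).
#' @return character scalar, Myr to 1 decimal or `"<0.3"`.
#' @export
formatAgeMyr <- function(age, K = NULL) {
  if (is(age, "AgeEstimate")) {
    K <- kValue(age)
    age <- ageMyr(age)
  }
  if (!is.null(K) && K == 0) "<0.3" else .fmtMyr(age)
}

#' Age a provirus from its own LTR pair under a fast and a slow rate
#'
#' Computes the K2P distance between the record's 5' and 3' LTR (CpG sites
#' included, pairwise deletion) and converts it to years under both rates.
#'
#' @param rec a [ProvirusRecord-class].
#' @param rates a [rateSet()].
#' @param gammaShape optional gamma shape for the distance.
#' @return list with `fast` and `slow` [AgeEstimate-class] objects and `K`.
#' @export
provirusAge <- function(rec, rates = rateSet(), gammaShape = NULL) {
  ltrs <- ltrSequences(rec)
  pd <- k2pDistance(ltrs$ltr5, ltrs$ltr3, gammaShape = gammaShape)
  list(fast = dateIntegration(pd, rates[["fast"]],
                              label = paste0(rec@id, " fast")),
       slow = dateIntegration(pd, rates[["slow"]],
                              label = paste0(rec@id, " slow")),
       K = kValue(pd))
}

#' Summarize a cohort of age estimates
#'
#' @param ages list of [AgeEstimate-class] objects (one rate).
#' @return list with `n`, `meanMyr`, `sdMyr` (`NA` for a single estimate),
#'   `minMyr`, `maxMyr`, `nFloor` (estimates with `K = 0`, reported as
#'   `"<0.3"`), and `rangeLabel`.
#' @export
cohortAgeSummary <- function(ages) {
  if (length(ages) == 0L) {
    .ervError("ervkit_dating_error", "no age estimates to summarize")
  }
  if (is(ages, "AgeEstimate")) ages <- list(ages)
  myr <- vapply(ages, ageMyr, numeric(1))
  ks <- vapply(ages, kValue, numeric(1))
  lo <- if (any(ks == 0)) "<0.3" else .fmtMyr(min(myr))
  list(n = length(myr),
       meanMyr = mean(myr),
       sdMyr = if (length(myr) > 1L) sd(myr) else NA_real_,
       minMyr = min(myr), maxMyr = max(myr),
       nFloor = sum(ks == 0),
       rangeLabel = paste0(lo, "-", .fmtMyr(max(myr))))
}

#' Average component ages into one event age
#'
#' Event ages (e.g. "integration of the shared provirus", "TMRCA of the
#' carrier species") are the arithmetic mean of their unrounded component
#' ages; per-row report values round to 1 decimal Myr only at print time.
#'
#' @param ages list of [AgeEstimate-class] objects or numeric Myr values.
#' @param label event label.
#' @return list with `label`, `meanMyr`, `minMyr`, `maxMyr`, `componentsMyr`.
#' @export
eventAge <- function(ages, label = "") {
  myr <- if (is.numeric(ages)) ages else vapply(ages, ageMyr, numeric(1))
  if (length(myr) == 0L) {
    .ervError("ervkit_dating_error", "event has no component ages")
  }
  list(label = label, meanMyr = mean(myr), minMyr = min(myr),
       maxMyr = max(myr), componentsMyr = myr)
}

#' Date a shared integration across carrier species
#'
#' For a provirus orthologous in several species, within-species 5'-vs-3'
#' LTR distances date the integration itself, while between-species 5'-vs-5'
#' and 3'-vs-3' distances date the species divergence (TMRCA of the carrier
#' clade). All LTRs are stacked into one alignment and columns carrying a
#' gap or `N` in any sequence are dropped once (complete deletion); CpG
#' sites are included.
#'
#' @param ltr5Set,ltr3Set named, aligned sets of 5' and 3' LTR sequences
#'   (named character vectors, `DNAStringSet`, or `ProviralAlignment`);
#'   names are species/assembly labels. All sequences across both sets must
#'   share one alignment length. Species present in only one set contribute
#'   only to the comparisons that use that set.
#' @param rates a [rateSet()].
#' @param gammaShape optional gamma shape.
#' @return list with `pairs` (data.frame: `type`
#'   (`within`/`between5`/`between3`), `a`, `b`, `K`, `sites`, `tFastMyr`,
#'   `tSlowMyr`) and `integration` (the [eventAge()] of the within-species
#'   pairs, `NULL` when no species carries both LTRs).
#' @export
sharedProvirusAges <- function(ltr5Set, ltr3Set, rates = rateSet(),
                               gammaShape = NULL) {
  asChar <- function(x) {
    if (is(x, "XStringSet")) setNames(as.character(x), names(x))
    else toupper(x)
  }
  l5 <- asChar(ltr5Set); l3 <- asChar(ltr3Set)
  if (is.null(names(l5)) || is.null(names(l3))) {
    .ervError("ervkit_dating_error", "LTR sets must be named by species")
  }
  all <- c(setNames(l5, paste0("5:", names(l5))),
           setNames(l3, paste0("3:", names(l3))))
  if (length(unique(nchar(all))) != 1L) {
    .ervError("ervkit_alignment_error",
              "all LTR sequences must share one alignment length")
  }
  m <- t(vapply(all, function(s) .seqChars(s), character(nchar(all[1L]))))
  mask <- .completeMask(m)
  onePair <- function(a, b, type, na, nb) {
    pd <- k2pDistance(m[a, ], m[b, ], gammaShape = gammaShape, mask = mask)
    data.frame(type = type, a = na, b = nb, K = kValue(pd),
               sites = siteCount(pd),
               tFastMyr = ageMyr(dateIntegration(pd, rates[["fast"]])),
               tSlowMyr = ageMyr(dateIntegration(pd, rates[["slow"]])))
  }
  rows <- list()
  for (sp in intersect(names(l5), names(l3))) {
    rows[[length(rows) + 1L]] <-
      onePair(paste0("5:", sp), paste0("3:", sp), "within", sp, sp)
  }
  betweenRows <- function(nms, prefix, type) {
    if (length(nms) < 2L) return(NULL)
    cmb <- utils::combn(nms, 2L)
    lapply(seq_len(ncol(cmb)), function(i) {
      onePair(paste0(prefix, cmb[1L, i]), paste0(prefix, cmb[2L, i]),
              type, cmb[1L, i], cmb[2L, i])
    })
  }
  rows <- c(rows, betweenRows(names(l5), "5:", "between5"),
            betweenRows(names(l3), "3:", "between3"))
  pairs <- do.call(rbind, rows)
  within <- pairs[pairs$type == "within", , drop = FALSE]
  integration <- if (nrow(within)) {
    eventAge(within$tFastMyr, label = "integration (fast rate)")
  } else NULL
  list(pairs = pairs, integration = integration)
}
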