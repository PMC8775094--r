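# Tajima's D neutrality test on ORF alignments.

#' Tajima's D
#'
#' Contrasts mean pairwise diversity with the segregating-site count.
#' Columns containing any gap or `N` are excluded (complete deletion);
#' sequences with out-of-frame indels should be excluded upstream (see
#' [orfStatus()]). `S` is the number of polymorphic columns, `pi` the mean
#' pairwise difference count per alignment (the per-site value is reported
#' additionally), and
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard constants
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param aln a [ProviralAlignment-class] with `n >= 2` sequences
#'   (`n >= 4` recommended; smaller sets trigger a warning, not an error,
#'   since per-genotype ORF sets can be small).
#' @return a [TajimaResult-class]; `D` is `NA` when `S = 0`, with `S` and
#'   `pi` still reported.
#' @export
tajimasD <- function(aln) {
  stopifnot(is(aln, "ProviralAlignment"))
  n <- length(aln)
  if (n < 2L) {
    .ervError("ervkit_popgen_error", "Tajima's D needs at least 2 sequences")
  }
  note <- ""
  if (n < 4L) {
    note <- sprintf("n = %d < 4: D is poorly calibrated for tiny samples", n)
    warning(note, call. = FALSE)
  }
  m <- .alnMatrix(aln)
  keep <- .completeMask(m)
  m <- m[, keep, drop = FALSE]
  sitesUsed <- ncol(m)
  if (sitesUsed == 0L) {
    .ervError("ervkit_popgen_error",
              "no gap-free columns left under complete deletion")
  }
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  # mean pairwise difference count
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) total <- total + sum(m[i, ] != m[j, ])
  }
  pi <- total / choose(n, 2)
  if (S == 0L) {
    return(new("TajimaResult", n = as.integer(n), S = 0L,
               sitesUsed = as.integer(sitesUsed), pi = pi,
               piPerSite = pi / sitesUsed, D = NA_real_,
               note = paste0(note, if (nzchar(note)) "; " else "",
                             "monomorphic alignment: D undefined")))
  }
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  new("TajimaResult", n = as.integer(n), S = as.integer(S),
      sitesUsed = as.integer(sitesUsed), pi = pi, piPerSite = pi / sitesUsed,
      D = D, note = note)
}
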