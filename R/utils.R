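# Internal helpers shared across modules.

# IUPAC nucleotide codes -> the set of unambiguous bases each matches.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

# Coerce a sequence (character scalar, DNAString, or single-element
# DNAStringSet) to an uppercase character vector of single bases.
.seqChars <- function(x) {
  if (is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    x <- x[[1L]]
  }
  if (is(x, "XString")) x <- as.character(x)
  if (is.character(x) && length(x) == 1L) {
    return(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  }
  if (is.character(x)) return(toupper(x))
  stop("cannot interpret object of class '", class(x)[1L], "' as a sequence")
}

.collapse <- function(chars) paste0(chars, collapse = "")

# Alignment (ProviralAlignment/DNAStringSet) -> character matrix,
# rows = sequences, columns = alignment columns.
.alnMatrix <- function(aln) {
  m <- t(vapply(seq_along(aln),
                function(i) .seqChars(as.character(aln[[i]])),
                character(Biostrings::width(aln)[1L])))
  rownames(m) <- names(aln)
  m
}

# Run expr with a fixed RNG state, restoring the caller's state afterwards.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(expr)
}

# Derive n reproducible child seeds (< 2^31) from one master seed.
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Condition constructors: errors carry a machine-readable class so callers
# (e.g. validateProvirus) can branch on saturation vs undefined distance.
.ervError <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "ervkit_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.isBase <- function(chars) chars %in% c("A", "C", "G", "T")

.isTransition <- function(a, b) {
  (a %in% .PURINES & b %in% .PURINES) |
    (a %in% .PYRIMIDINES & b %in% .PYRIMIDINES)
}

# Match sequence bases against a vector of IUPAC pattern codes.
# An 'N' (or gap) in the *sequence* only satisfies pattern code 'N'.
.iupacOK <- function(bases, code) {
  if (code == "N") return(!is.na(bases) & bases != "-")
  bases %in% .IUPAC[[code]]
}

.fmtMyr <- function(myr) sprintf("%.1f", myr)
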