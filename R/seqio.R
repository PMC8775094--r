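# Sequence and alignment I/O, the alignment-column coverage filter, and the
# majority-rule consensus used as default reference for the CpG census.

#' Read DNA sequences from FASTA
#'
#' Reads a (plain or aligned) FASTA file, upper-cases residues, maps RNA `U`
#' to `T`, and validates the alphabet (`A C G T N -`). Record ids are the
#' first whitespace-delimited token of each header; the remainder is kept as
#' the `description` metadata column.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "acgu", ">b", "ACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) {
    .ervError("ervkit_format_error", paste0("file not found: ", path))
  }
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .ervError("ervkit_format_error",
                    paste0("not a readable FASTA file: ", conditionMessage(e))))
  if (length(raw) == 0L) {
    .ervError("ervkit_format_error", paste0("empty FASTA file: ", path))
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    .ervError("ervkit_format_error",
              paste0("duplicate sequence id: ", ids[duplicated(ids)][1L]))
  }
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    offender <- ids[bad][1L]
    badChar <- regmatches(seqs[bad][1L], regexpr("[^ACGTN-]", seqs[bad][1L]))
    .ervError("ervkit_format_error",
              sprintf("illegal character '%s' in record '%s'",
                      badChar, offender))
  }
  if (any(nchar(seqs) == 0L)) {
    .ervError("ervkit_format_error",
              paste0("empty sequence in record '", ids[nchar(seqs) == 0L][1L],
                     "'"))
  }
  out <- Biostrings::DNAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write DNA sequences to FASTA
#'
#' @param x a `DNAStringSet`, `ProviralAlignment`, or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(as(x, "DNAStringSet"), path)
  invisible(path)
}

#' Read a multiple alignment from FASTA
#'
#' As [readFasta()] but validates that all records have equal length and
#' returns a [ProviralAlignment-class].
#'
#' @param path path to an aligned FASTA file (gap character `-`).
#' @return a [ProviralAlignment-class].
#' @export
readAlignment <- function(path) {
  x <- readFasta(path)
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1L) {
    .ervError("ervkit_alignment_error",
              paste0("aligned records have unequal lengths: ",
                     paste(w, collapse = ", ")))
  }
  ProviralAlignment(x)
}

#' Filter alignment columns by site coverage
#'
#' Keeps exactly the columns whose coverage (fraction of sequences holding a
#' non-gap, non-`N` base) is at least `minCoverage`, in their original order.
#' This is the standard partial-deletion filter used before distance and tree
#' estimation; `N` counts as missing data, like a gap. The boundary is
#' inclusive: a column at exactly `minCoverage` is retained.
#'
#' @param aln a [ProviralAlignment-class].
#' @param minCoverage required fraction in (0, 1]; default 0.95 (at most 5%
#'   gaps/missing/ambiguous bases per column).
#' @return a filtered `ProviralAlignment`; the retained column indices are
#'   available as `metadata(x)$keptColumns`.
#' @export
filterColumns <- function(aln, minCoverage = 0.95) {
  stopifnot(is(aln, "ProviralAlignment"),
            minCoverage > 0, minCoverage <= 1)
  m <- .alnMatrix(aln)
  cov <- colMeans(array(m %in% c("A", "C", "G", "T"), dim(m)))
  keep <- which(cov >= minCoverage - 1e-12)
  if (length(keep) == 0L) {
    .ervError("ervkit_alignment_error",
              sprintf("no column reaches %.0f%% coverage; empty alignment",
                      100 * minCoverage))
  }
  out <- ProviralAlignment(Biostrings::DNAStringSet(
    setNames(apply(m[, keep, drop = FALSE], 1L, .collapse), names(aln))))
  S4Vectors::metadata(out) <- list(keptColumns = keep,
                                   retained = length(keep),
                                   removed = ncol(m) - length(keep))
  out
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the strict plurality base among `A C G T`; gaps and `N` are
#' treated as absent. Ties yield `N` (no mutation direction is fabricated),
#' and all-gap columns yield `-`.
#'
#' @param aln a [ProviralAlignment-class].
#' @return a [Biostrings::DNAString] of the alignment length.
#' @export
consensusSequence <- function(aln) {
  stopifnot(is(aln, "ProviralAlignment"))
  cm <- Biostrings::consensusMatrix(aln)
  bases <- c("A", "C", "G", "T")
  counts <- cm[bases, , drop = FALSE]
  cons <- apply(counts, 2L, function(col) {
    tot <- sum(col)
    if (tot == 0L) return("-")
    mx <- max(col)
    winners <- bases[col == mx]
    if (length(winners) == 1L) winners else "N"
  })
  Biostrings::DNAString(.collapse(cons))
}
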