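# Shared fixture builders. Everything is generated in code; no stored data.

alnFromStrings <- function(x) {
  if (is.null(names(x))) names(x) <- paste0("s", seq_along(x))
  ProviralAlignment(x)
}

randomSeq <- function(n, seed = NULL,
                      prob = c(0.25, 0.25, 0.25, 0.25)) {
  draw <- function() paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                   prob = prob), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# A bare synthetic provirus: two identical terminal repeats around a random
# core, with TG...CA repeat termini and distinct post-repeat boundary bases.
plantedRepeatSeq <- function(coreLen = 7400, ltrLen = 480, seed = 1) {
  withr::with_seed(seed, {
    ltr <- paste0("TG", randomSeq(ltrLen - 4), "CA")
    paste0(ltr, randomSeq(coreLen), ltr)
  })
}

# Mutate a sequence at k distinct positions (substitutions only).
mutateAt <- function(s, pos, seed = 1) {
  v <- strsplit(s, "")[[1]]
  withr::with_seed(seed, {
    for (p in pos) {
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    }
  })
  paste0(v, collapse = "")
}

# Independent brute-force oracle for pairwise difference counting.
oracleCountDiffs <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ts <- 0L; tv <- 0L; sites <- 0L
  pur <- c("A", "G"); pyr <- c("C", "T")
  for (i in seq_along(av)) {
    if (!av[i] %in% c(pur, pyr) || !bv[i] %in% c(pur, pyr)) next
    sites <- sites + 1L
    if (av[i] == bv[i]) next
    if ((av[i] %in% pur && bv[i] %in% pur) ||
        (av[i] %in% pyr && bv[i] %in% pyr)) ts <- ts + 1L else tv <- tv + 1L
  }
  list(transitions = ts, transversions = tv, sites = sites)
}

# Exact hypergeometric tail from first principles (choose() ratios), the
# independent oracle for fisherExact(one_greater).
oracleFisherGreater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

# Independent Tajima's D oracle: direct formula evaluation with explicit
# double loops over a character matrix (complete deletion).
oracleTajima <- function(mat) {
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- mat[, keep, drop = FALSE]
  n <- nrow(m)
  S <- 0L
  for (j in seq_len(ncol(m))) if (length(unique(m[, j])) > 1) S <- S + 1L
  tot <- 0L; np <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ]); np <- np + 1L
  }
  pi <- tot / np
  if (S == 0) return(list(S = 0L, pi = pi, D = NA_real_))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(S = S, pi = pi,
       D = (pi - S / a1) / sqrt((c1 / a1) * S +
                                (c2 / (a1^2 + a2)) * S * (S - 1)))
}

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
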