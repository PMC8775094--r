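# Truth-tagged endogenization simulator. Generates proviral ancestors with
# realistic structure (terminal LTRs, PBS, open ORFs, planted CpG content),
# integrates them into host sequence with target-site duplication, applies an
# optional pre-integration APOBEC editing episode, and evolves loci under a
# neutral transition-biased substitution process with elevated CpG
# deamination. Every mutation is logged so emitted sequences can be replayed
# exactly.

#' Simulation parameters
#'
#' Defaults emulate a full-length SERV provirus: 8393 nt genome, 485 nt
#' LTRs, an 18-nt PBS immediately 3' of the 5' LTR, a 6-nt target-site
#' duplication, neutral substitution at 5e-9 substitutions/site/year with a
#' 4:1 transition:transversion event weighting, and CpG-site deamination
#' transitions at 1.6e-7 substitutions/site/year. The two genotype profiles
#' differ in PBS use and CpG content: `"SERV1"` carries PBS-lys3 and ~198
#' CpG sites, `"SERV2"` PBS-lys1,2 and ~144 CpG sites.
#'
#' @param genotype profile preset, `"SERV1"` (default) or `"SERV2"`.
#' @param provirusLength provirus length (nt).
#' @param ltrLength LTR length (nt).
#' @param pbsChoice `"lys3"` or `"lys12"`; default set by `genotype`.
#' @param cpgTargetCount CpG dinucleotides planted in the ancestor (+-5%);
#'   default set by `genotype`.
#' @param baseRate neutral substitution rate (substitutions/site/year).
#' @param cpgRate additional CpG deamination-transition rate
#'   (substitutions/site/year).
#' @param tstv transition:transversion event weighting (a modeling default;
#'   the transversion spectrum itself is unreported for these proviruses).
#' @param tsdLength target-site duplication length (nt).
#' @param epochs evolution epochs per run; CpG hotspot status is re-evaluated
#'   against the current sequence each epoch, so destroyed CpGs stop being
#'   hotspots.
#' @param composition per-region base composition (named fractions over
#'   `A C G T` for `ltr`, `gagpol`, `env`, `other`), approximating the
#'   A-rich, G-poor D-type retroviral genome (gag-pol ~33.3% A, env ~29.7% A,
#'   LTR ~22.6% A).
#' @return a validated list of class `SimParams`.
#' @export
simParams <- function(genotype = c("SERV1", "SERV2"),
                      provirusLength = 8393L, ltrLength = 485L,
                      pbsChoice = NULL, cpgTargetCount = NULL,
                      baseRate = 5e-9, cpgRate = 1.6e-7, tstv = 4,
                      tsdLength = 6L, epochs = 10L,
                      composition = NULL) {
  genotype <- match.arg(genotype)
  if (is.null(pbsChoice)) {
    pbsChoice <- if (genotype == "SERV1") "lys3" else "lys12"
  }
  if (is.null(cpgTargetCount)) {
    cpgTargetCount <- if (genotype == "SERV1") 198L else 144L
  }
  if (is.null(composition)) {
    composition <- list(
      ltr    = c(A = 0.226, C = 0.280, G = 0.270, T = 0.224),
      gagpol = c(A = 0.333, C = 0.187, G = 0.210, T = 0.270),
      env    = c(A = 0.297, C = 0.260, G = 0.230, T = 0.213),
      other  = c(A = 0.300, C = 0.230, G = 0.220, T = 0.250))
  }
  p <- list(genotype = genotype,
            provirusLength = as.integer(provirusLength),
            ltrLength = as.integer(ltrLength), pbsChoice = pbsChoice,
            cpgTargetCount = as.integer(cpgTargetCount),
            baseRate = baseRate, cpgRate = cpgRate, tstv = tstv,
            tsdLength = as.integer(tsdLength), epochs = as.integer(epochs),
            composition = composition)
  stopifnot(p$provirusLength > 0L, p$ltrLength > 0L,
            p$provirusLength >= 2L * p$ltrLength + 60L,
            p$baseRate >= 0, p$cpgRate >= 0, p$tstv > 0,
            p$tsdLength >= 0L, p$epochs >= 1L,
            p$pbsChoice %in% c("lys3", "lys12"))
  class(p) <- "SimParams"
  p
}

.randBases <- function(n, comp) {
  if (n <= 0L) return(character())
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = comp)
}

# Random open reading frame: ATG, non-stop internal codons, terminal stop.
.randOrf <- function(lenNt, comp) {
  stopifnot(lenNt %% 3L == 0L, lenNt >= 9L)
  ncod <- lenNt %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  mid <- character(ncod - 2L)
  i <- 1L
  while (i <= length(mid)) {
    cod <- .collapse(.randBases(3L, comp))
    if (!cod %in% stops) { mid[i] <- cod; i <- i + 1L }
  }
  .seqChars(paste0("ATG", .collapse(mid), sample(stops, 1L)))
}

# Does the in-frame codon containing any of `positions` read as a stop?
.introducesStop <- function(v, positions, orfs) {
  stops <- c("TAA", "TAG", "TGA")
  for (k in seq_along(orfs)) {
    os <- IRanges::start(orfs)[k]; oe <- IRanges::end(orfs)[k]
    inside <- positions[positions >= os & positions <= oe - 3L]  # keep stop
    for (p in inside) {
      cstart <- os + ((p - os) %/% 3L) * 3L
      if (cstart == oe - 2L) next  # terminal stop codon
      if (.collapse(v[cstart:(cstart + 2L)]) %in% stops) return(TRUE)
    }
  }
  FALSE
}

#' Build a proviral ancestor sequence
#'
#' Assembles `5'LTR - PBS - leader - gag - pol - env - 3'UTR - 3'LTR` with
#' identical LTR copies (canonical `TG...CA` termini), the chosen PBS 18-mer
#' immediately 3' of the 5' LTR, open reading frames for the three major
#' genes (reference lengths gag 1977, pol 2613, env 1713 nt, scaled down for
#' short test genomes), region-specific base composition, and CpG
#' dinucleotide content adjusted to `cpgTargetCount` within +-5%.
#'
#' @param params a [simParams()] object.
#' @param seed integer seed (the same seed reproduces the ancestor exactly).
#' @param id record id.
#' @return a [ProvirusRecord-class] whose `orfs` slot holds the gag/pol/env
#'   coordinates.
#' @export
makeAncestor <- function(params = simParams(), seed = 1L, id = "ancestor") {
  stopifnot(inherits(params, "SimParams"))
  .withSeed(seed, {
    L <- params$ltrLength
    n <- params$provirusLength
    comp <- params$composition
    internal <- n - 2L * L - 18L
    orfLens <- c(gag = 1977L, pol = 2613L, env = 1713L)
    minFlank <- 60L
    avail <- internal - 2L * minFlank
    if (avail < 27L) {
      .ervError("ervkit_sim_error",
                "provirus too short for LTRs, PBS and coding region")
    }
    f <- min(1, avail / sum(orfLens))
    orfLens[] <- pmax(9L, (as.integer(orfLens * f) %/% 3L) * 3L)
    while (sum(orfLens) > avail) orfLens <- orfLens - 3L
    leader <- minFlank + floor((internal - 2L * minFlank - sum(orfLens)) * 0.4)
    utr3 <- internal - sum(orfLens) - leader

    ltr <- c("T", "G", .randBases(L - 4L, comp$ltr), "C", "A")
    pbs <- .seqChars(pbsReferences()[[params$pbsChoice]])
    body <- c(ltr, pbs,
              .randBases(leader, comp$other),
              .randOrf(orfLens[["gag"]], comp$gagpol),
              .randOrf(orfLens[["pol"]], comp$gagpol),
              .randOrf(orfLens[["env"]], comp$env),
              .randBases(utr3, comp$other))
    gagStart <- L + 18L + leader + 1L
    orfs <- IRanges::IRanges(
      start = c(gagStart, gagStart + orfLens[["gag"]],
                gagStart + orfLens[["gag"]] + orfLens[["pol"]]),
      width = orfLens)
    names(orfs) <- c("gag", "pol", "env")

    # Adjust CpG content toward the target, mirroring the 3' LTR so the two
    # copies stay identical. Protected positions: LTR termini, the PBS, and
    # ORF start/stop codons; edits may not introduce in-frame stops.
    protect <- c(1L, 2L, L - 1L, L, (L + 1L):(L + 18L))
    for (k in seq_along(orfs)) {
      os <- IRanges::start(orfs)[k]; oe <- IRanges::end(orfs)[k]
      protect <- c(protect, os:(os + 2L), (oe - 2L):oe)
    }
    target <- params$cpgTargetCount
    band <- floor(0.05 * target)
    fullSeq <- function(b) c(b, b[1:L])   # body + mirrored 3' LTR
    cgCount <- function(v) sum(v[-length(v)] == "C" & v[-1L] == "G")
    attempts <- 0L
    repeat {
      cnt <- cgCount(fullSeq(body))
      if (abs(cnt - target) <= band) break
      attempts <- attempts + 1L
      if (attempts > 20000L) {
        .ervError("ervkit_sim_error",
                  sprintf("cannot reach %d CpG sites (at %d after %d edits)",
                          target, cnt, attempts))
      }
      if (cnt < target) {
        i <- sample.int(length(body) - 1L, 1L)
        if (i %in% protect || (i + 1L) %in% protect) next
        if (body[i] == "C" && body[i + 1L] == "G") next
        old <- body[c(i, i + 1L)]
        body[i] <- "C"; body[i + 1L] <- "G"
        if (.introducesStop(body, c(i, i + 1L), orfs)) {
          body[c(i, i + 1L)] <- old
        }
      } else {
        cg <- which(body[-length(body)] == "C" & body[-1L] == "G")
        cg <- cg[!(cg %in% protect) & !((cg + 1L) %in% protect)]
        if (!length(cg)) {
          .ervError("ervkit_sim_error", "no removable CpG site left")
        }
        i <- cg[sample.int(length(cg), 1L)]
        j <- if (runif(1) < 0.5) i else i + 1L
        old <- body[j]
        body[j] <- if (j == i) "T" else "A"   # C->T or G->A deamination-style
        if (.introducesStop(body, j, orfs)) body[j] <- old
      }
    }
    v <- fullSeq(body)
    provirusRecord(id = id, locus = .collapse(v),
                   ltr5 = c(1L, L), ltr3 = c(n - L + 1L, n),
                   pbs = .collapse(pbs), genotype = params$genotype,
                   orfs = orfs, ltrBounds = c(min(400L, L), max(520L, L)))
  })
}

#' Integrate a provirus into host sequence with target-site duplication
#'
#' The `tsdLength`-mer of host sequence ending at `position` is duplicated on
#' both flanks of the inserted provirus (integrase semantics); with
#' `tsdLength = 0` the provirus is inserted without duplication.
#'
#' @param host host sequence (character or `DNAString`).
#' @param provirus a [ProvirusRecord-class] (e.g. from [makeAncestor()]) or a
#'   plain provirus sequence.
#' @param position insertion point: the provirus is inserted immediately
#'   after host position `position`.
#' @param params a [simParams()] (supplies `tsdLength`).
#' @param id id for the new locus record.
#' @return list with `record` (a [ProvirusRecord-class] whose locus is the
#'   flanked integration) and `truth` (list: `position`, `tsd`, `provStart`,
#'   `provEnd`).
#' @export
integrateProvirus <- function(host, provirus, position,
                              params = simParams(), id = "locus") {
  hv <- .seqChars(host)
  tlen <- params$tsdLength
  if (position < tlen || position > length(hv) - 1L) {
    .ervError("ervkit_sim_error",
              sprintf("position %d out of range for a %d nt host with %d nt TSD",
                      position, length(hv), tlen))
  }
  if (is(provirus, "ProvirusRecord")) {
    pv <- .seqChars(locusSeq(provirus))
    ltr5 <- provirus@ltr5; ltr3 <- provirus@ltr3
    orfs <- provirus@orfs
    pbs <- provirus@pbs; genotype <- provirus@genotype
  } else {
    pv <- .seqChars(provirus)
    L <- NA_integer_
    .ervError("ervkit_sim_error",
              "provirus must be a ProvirusRecord carrying LTR spans")
  }
  tsd <- if (tlen > 0L) hv[(position - tlen + 1L):position] else character()
  locus <- c(hv[1:position], pv, tsd,
             if (position < length(hv)) hv[(position + 1L):length(hv)])
  shift <- position
  wl <- c(IRanges::width(ltr5), IRanges::width(ltr3))
  rec <- provirusRecord(
    id = id, locus = .collapse(locus),
    ltr5 = IRanges::shift(ltr5, shift), ltr3 = IRanges::shift(ltr3, shift),
    tsd = if (tlen > 0L) .collapse(tsd) else NA_character_,
    pbs = pbs, genotype = genotype, orfs = IRanges::shift(orfs, shift),
    ltrBounds = range(c(400L, 520L, wl)))
  list(record = rec,
       truth = list(position = position,
                    tsd = if (tlen > 0L) .collapse(tsd) else NA_character_,
                    provStart = position + 1L,
                    provEnd = position + length(pv)))
}

# One evolution epoch on a character vector; returns list(v, log rows).
.evolveEpoch <- function(v, pBase, pCpG, tstv, epoch) {
  L <- length(v)
  logs <- list()
  # neutral substitutions, transition-biased
  hit <- which(runif(L) < pBase & .isBase(v))
  if (length(hit)) {
    from <- v[hit]
    isTs <- runif(length(hit)) < tstv / (tstv + 1)
    transitionOf <- c(A = "G", G = "A", C = "T", T = "C")
    tvChoices <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
    to <- character(length(hit))
    to[isTs] <- transitionOf[from[isTs]]
    if (any(!isTs)) {
      pick <- runif(sum(!isTs)) < 0.5
      to[!isTs] <- mapply(function(f, first) tvChoices[[f]][if (first) 1L else 2L],
                          from[!isTs], pick)
    }
    v[hit] <- to
    logs[[1L]] <- data.frame(epoch = epoch, position = hit, from = from,
                             to = to, cause = "neutral")
  }
  # CpG deamination on the *current* sequence state
  if (pCpG > 0) {
    cIdx <- which(v[-L] == "C" & v[-1L] == "G")
    if (length(cIdx)) {
      gIdx <- cIdx + 1L
      cHit <- cIdx[runif(length(cIdx)) < pCpG]
      gHit <- gIdx[runif(length(gIdx)) < pCpG]
      if (length(cHit)) {
        logs[[length(logs) + 1L]] <-
          data.frame(epoch = epoch, position = cHit, from = "C", to = "T",
                     cause = "cpg")
        v[cHit] <- "T"
      }
      if (length(gHit)) {
        gHit <- gHit[v[gHit] == "G"]   # unchanged by the C->T step
        if (length(gHit)) {
          logs[[length(logs) + 1L]] <-
            data.frame(epoch = epoch, position = gHit, from = "G", to = "A",
                       cause = "cpg")
          v[gHit] <- "A"
        }
      }
    }
  }
  list(v = v, log = if (length(logs)) do.call(rbind, logs) else NULL)
}

#' Evolve a sequence neutrally for a span of years
#'
#' Per-site Bernoulli substitution with probability `baseRate * years`
#' (Poisson approximation, spread over `epochs` sequential epochs so that
#' multiple hits and back-mutations can occur), with the configured
#' transition:transversion event weighting. Sites that are currently the C
#' or G of a CpG dinucleotide additionally receive deamination-type
#' transitions (C->T on the plus strand, G->A representing minus-strand
#' deamination, equal weight) with probability `cpgRate * years`; hotspot
#' status is re-evaluated every epoch.
#'
#' @param x sequence (character scalar, `DNAString`) to evolve.
#' @param years elapsed time (>= 0).
#' @param params a [simParams()].
#' @param seed optional seed; `NULL` draws from the current RNG state.
#' @return list with `seq` (character scalar) and `log` (data.frame with
#'   `epoch`, `position`, `from`, `to`, `cause`), ordered as applied.
#' @export
evolveSequence <- function(x, years, params = simParams(), seed = NULL) {
  stopifnot(years >= 0)
  v <- .seqChars(x)
  if (max(params$baseRate, params$cpgRate) * years > 0.5) {
    warning("expected per-site substitution probability exceeds 0.5: ",
            "the Poisson approximation is saturated", call. = FALSE)
  }
  if (years == 0) {
    return(list(seq = .collapse(v),
                log = data.frame(epoch = integer(), position = integer(),
                                 from = character(), to = character(),
                                 cause = character())))
  }
  .withSeed(seed, {
    ep <- params$epochs
    pBase <- params$baseRate * years / ep
    pCpG <- params$cpgRate * years / ep
    logs <- vector("list", ep)
    for (e in seq_len(ep)) {
      step <- .evolveEpoch(v, pBase, pCpG, params$tstv, e)
      v <- step$v
      logs[[e]] <- step$log
    }
    log <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
    if (is.null(log)) {
      log <- data.frame(epoch = integer(), position = integer(),
                        from = character(), to = character(),
                        cause = character())
    }
    rownames(log) <- NULL
    list(seq = .collapse(v), log = log)
  })
}

#' Evolve the locus of a ProvirusRecord
#'
#' @inheritParams evolveSequence
#' @param rec a [ProvirusRecord-class].
#' @return list with `record` (locus replaced by the evolved sequence;
#'   spans unchanged, the process is indel-free) and `log`.
#' @export
evolveRecord <- function(rec, years, params = simParams(), seed = NULL) {
  out <- evolveSequence(locusSeq(rec), years, params, seed)
  rec@locus <- Biostrings::DNAString(out$seq)
  list(record = rec, log = out$log)
}

#' Apply a pre-integration APOBEC editing episode
#'
#' Every plus-strand position matching the pattern's primary context (with
#' the context evaluated on the *pre-edit* sequence, making the edit
#' order-independent) receives the focal substitution with independent
#' probability `efficiency`. Biologically this models cytidine deamination of
#' the minus strand during reverse transcription, seen as G->A on the plus
#' strand, and is applied once, before integration and evolution.
#'
#' @param x sequence to edit.
#' @param pattern a [MutationPattern-class]; only the primary context is
#'   used.
#' @param efficiency per-site editing probability in `[0, 1]`.
#' @param seed optional seed.
#' @return list with `seq`, `log` (cause `"apobec"`), `nSites` (qualifying
#'   positions) and `nEdited`.
#' @export
apobecEdit <- function(x, pattern, efficiency, seed = NULL) {
  stopifnot(is(pattern, "MutationPattern"),
            efficiency >= 0, efficiency <= 1)
  v <- .seqChars(x)
  sites <- .contextSites(v, v, pattern@from, pattern@upstream,
                         pattern@downstream)
  .withSeed(seed, {
    edited <- sites[runif(length(sites)) < efficiency]
    log <- data.frame(epoch = rep(0L, length(edited)), position = edited,
                      from = rep(pattern@from, length(edited)),
                      to = rep(pattern@to, length(edited)),
                      cause = rep("apobec", length(edited)))
    v[edited] <- pattern@to
    list(seq = .collapse(v), log = log, nSites = length(sites),
         nEdited = length(edited))
  })
}

#' Replay a mutation log
#'
#' Applies a log (as produced by [evolveSequence()]/[apobecEdit()], rows in
#' order) to a starting sequence; each row's `from` base must match the
#' current state, which verifies that the log replays to the emitted
#' sequence exactly.
#'
#' @param x starting sequence.
#' @param log mutation log data.frame.
#' @return the replayed sequence (character scalar).
#' @export
replayMutations <- function(x, log) {
  v <- .seqChars(x)
  for (i in seq_len(nrow(log))) {
    p <- log$position[i]
    if (v[p] != log$from[i]) {
      .ervError("ervkit_sim_error",
                sprintf("log row %d: expected %s at %d, found %s",
                        i, log$from[i], p, v[p]))
    }
    v[p] <- log$to[i]
  }
  .collapse(v)
}

#' Generate a truth-tagged cohort of simulated provirus loci
#'
#' For every cell of the `agesYears` x `apobec` grid, `nPerCell` loci are
#' built from one shared ancestor: (optional) APOBEC editing of the provirus,
#' integration into a fresh random host at a random position (with TSD), and
#' neutral evolution for the cell's age. All randomness flows from one master
#' seed; the same seed reproduces the cohort byte for byte.
#'
#' @param params a [simParams()].
#' @param agesYears integration ages (years) simulated.
#' @param apobec logical vector of APOBEC-episode settings.
#' @param nPerCell loci per grid cell.
#' @param seed master seed.
#' @param hostLength random host length (nt) around each integration.
#' @param apobecPattern editing context, default the GG-dinucleotide
#'   (3G-type) signature `K-(G>A)-D`.
#' @param apobecEfficiency per-site editing probability.
#' @return list with `ancestor`, `records` (named list of
#'   [ProvirusRecord-class]), `truth` (data.frame keyed by locus id), and
#'   `logs` (named list of mutation logs, replayable on the unevolved,
#'   unedited integrated locus).
#' @export
generateCohort <- function(params = simParams(),
                           agesYears = c(1e6, 3e6, 8e6),
                           apobec = c(FALSE, TRUE), nPerCell = 10L,
                           seed = 1L, hostLength = 1200L,
                           apobecPattern = mutationPattern("K", "G", "A", "D"),
                           apobecEfficiency = 0.3) {
  grid <- expand.grid(age = agesYears, apo = apobec)
  nLoci <- nrow(grid) * nPerCell
  seeds <- .childSeeds(seed, nLoci + 1L)
  ancestor <- makeAncestor(params, seed = seeds[1L])
  records <- list(); logs <- list(); truth <- list()
  idx <- 1L
  for (g in seq_len(nrow(grid))) {
    for (rep in seq_len(nPerCell)) {
      id <- sprintf("locus_%gmyr_%s_%02d", grid$age[g] / 1e6,
                    if (grid$apo[g]) "apo" else "neu", rep)
      locusSeed <- seeds[idx + 1L]
      res <- .withSeed(locusSeed, {
        host <- .collapse(.randBases(hostLength, c(.25, .25, .25, .25)))
        pos <- sample(seq(params$tsdLength + 50L, hostLength - 50L), 1L)
        prov <- ancestor
        aLog <- NULL
        if (grid$apo[g]) {
          ed <- apobecEdit(locusSeq(prov), apobecPattern, apobecEfficiency)
          prov@locus <- Biostrings::DNAString(ed$seq)
          aLog <- ed$log
        }
        intd <- integrateProvirus(host, prov, pos, params, id = id)
        # log coordinates are locus coordinates: shift the provirus-frame
        # APOBEC log by the insertion offset
        if (!is.null(aLog) && nrow(aLog)) {
          aLog$position <- aLog$position + intd$truth$position
        }
        ev <- evolveRecord(intd$record, grid$age[g], params)
        log <- rbind(aLog, ev$log)
        # baseline for replay: the *unedited* ancestor integrated at pos
        base <- integrateProvirus(host, ancestor, pos, params, id = id)
        list(record = ev$record, log = log, truth = intd$truth,
             base = as.character(locusSeq(base$record)))
      })
      records[[id]] <- res$record
      logs[[id]] <- res$log
      truth[[id]] <- data.frame(
        id = id, ageYears = grid$age[g], apobec = grid$apo[g],
        genotype = params$genotype, pbsLabel = params$pbsChoice,
        tsd = res$truth$tsd, provStart = res$truth$provStart,
        provEnd = res$truth$provEnd,
        ltr5Start = IRanges::start(res$record@ltr5),
        ltr5End = IRanges::end(res$record@ltr5),
        ltr3Start = IRanges::start(res$record@ltr3),
        ltr3End = IRanges::end(res$record@ltr3),
        seed = locusSeed, baseline = res$base)
      idx <- idx + 1L
    }
  }
  list(ancestor = ancestor, records = records,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       logs = logs, params = params, seed = seed)
}

#' Write a simulated cohort to disk
#'
#' Emits `loci.fasta` (all locus sequences), `ancestor.fasta`, and
#' `truth.tsv` (the truth table minus the baseline sequences) under `dir`.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(
    vapply(cohort$records, function(r) as.character(locusSeq(r)),
           character(1)))
  writeFasta(seqs, file.path(dir, "loci.fasta"))
  writeFasta(Biostrings::DNAStringSet(
    setNames(as.character(locusSeq(cohort$ancestor)), "ancestor")),
    file.path(dir, "ancestor.fasta"))
  tt <- cohort$truth
  tt$baseline <- NULL
  write.table(tt, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
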