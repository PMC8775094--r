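---
title: "Provirus characterization, LTR-divergence dating and mutation signatures with ervkit"
author: "ervkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Provirus characterization, LTR-divergence dating and mutation signatures with ervkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervkit)
```

## The problem

Endogenous retroviruses (ERVs) are chromosomally fixed remnants of past
germ-line infections. A full-length provirus has the structure
LTR–gag–pro/pol–env–LTR: two long terminal repeats (LTRs) that are *identical*
at the moment of integration, an 18-nt primer binding site (PBS) immediately
3' of the 5' LTR that is complementary to the host tRNA priming reverse
transcription, and a short (here 6-nt) target-site duplication (TSD) of host
sequence flanking the insertion, the hallmark of integrase activity. The
simian endogenous retrovirus (SERV) of Old World monkeys — a type D
betaretrovirus with an ~8.4 kb genome, ~485 nt LTRs, and two genotypes that
differ in PBS use (PBS-lys3 vs PBS-lys1,2) — is the model system the defaults
of this package describe.

`ervkit` implements the analysis workflow a paleovirologist applies to a set
of such proviruses: validate that each locus is a genuine, well-assembled
integration; date each integration from the divergence of its two LTRs;
census the CpG methylation-associated mutations that accumulate after
integration; scan for APOBEC3-type G→A hypermutation acquired before
integration; classify PBS use; and test the coding regions for departures
from neutrality. Because genome-scale inputs cannot be bundled, a
truth-tagged simulator generates cohorts with exactly the statistical
structure the analysis assumes, and every stage is validated against that
truth.

## Dating from LTR divergence

At integration the two LTR copies are identical; afterwards each accumulates
substitutions at the host's neutral rate $r$. With $K$ the
Kimura-2-parameter (K2P) distance between the 5' and 3' LTR of one provirus,
the age is

$$T = \frac{K}{2r},$$

the factor two reflecting that both copies mutate independently. Two rates
bracket the plausible range for primate ERVs: a fast rate of
$5\times10^{-9}$ and a slow rate of $2.3\times10^{-9}$
substitutions/site/year (`rateSet()`); ages are reported under both. An age
of exactly $K = 0$ is below the resolution of a single substitution on a
~485-nt LTR (about 0.2 Myr at the fast rate) and is printed as "<0.3 Myr"
rather than 0.

The same arithmetic extends to integrations shared across species
(`sharedProvirusAges()`): within-species 5'-vs-3' distances date the
integration; between-species 5'-vs-5' and 3'-vs-3' distances date the
divergence of the carrier species (TMRCA). Event ages are arithmetic means
of the *unrounded* component ages; rounding to 0.1 Myr happens only at print
time. Rounding components first is deliberately not supported — it is not
associative with averaging and produces irreproducible table values.

### K2P distances and gap policies

With transition proportion $P$ and transversion proportion $Q$ over the
comparable sites, $K = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$; under
gamma-distributed rate variation with shape $a$,
$K = \tfrac{a}{2}[(1-2P-Q)^{-1/a}-1] + \tfrac{a}{4}[(1-2Q)^{-1/a}-1]$.
Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) raises a typed error naming $P$
and $Q$ instead of returning a number. Two deletion policies are offered:
*pairwise* (each pair drops only its own gap/`N` positions) and *complete*
(columns with any gap/`N` are dropped once for the whole set). `N` is always
treated as missing data. The gamma shape is exposed as configuration and
defaults to off: group dating tables in this field typically state
"gamma-distributed" without printing the shape, so both forms are provided
and the plain form is the default. A count-based transition:transversion
ratio (`tstvRatio()`) is shipped for simulation checks; it is *not* a
maximum-likelihood estimate of the substitution bias and is validated only
by simulation recovery.

## Mutation signatures

### CpG deamination census

Methylated CpG deaminates at a strongly elevated rate — transitions at human
CpG sites run near $1.6\times10^{-7}$ substitutions/site/year, ~32× the fast
neutral rate — producing CpG→TpG on the plus strand and CpG→CpA on the
minus strand. `cpgCensus()` enumerates CpG sites on a reference (consensus
by default), classifies the query state at each site (TpG, CpA, or other),
and `cpgStrandSplit()` pools the TpG:CpA ratio: a value near 1 indicates
orientation-independent methylation. The census is implemented by direct
site enumeration rather than as a context-pattern scan: the conventional
"control" setting for CpG mutations in pattern-scanning tools is not a
well-formed mutation pattern, and direct enumeration needs no control arm.

### APOBEC3-type hypermutation

APOBEC3 cytidine deaminases edit retroviral minus-strand DNA during
replication — before integration — seen as G→A on the plus strand in
dinucleotide contexts (GG for APOBEC3G, GA for 3F). `hypermutScan()`
implements the HYPERMUT-style scan: a *potential* site holds the focal base
with the IUPAC upstream/downstream context satisfied on **both** reference
and query ("enforced" mode, so a neighboring mutation disqualifies a site);
a *matched mutation* is a potential site where the query holds the target
base. The shipped defaults exclude CpG-driven G→A: primary `K-(G>A)-D` with
control `K-(G>A)-N` for the 3G-type signature, and `D-(G>A)-AD` with
`D-(G>A)-N` for non-3G patterns. The control arm is made *disjoint* from the
primary arm (control-context sites that also satisfy the primary context are
removed); overlapping arms would count primary sites twice and bias the
test toward the null. Enrichment is assessed with a one-sided exact
hypergeometric test (`fisherExact()`); two-sided testing is used for
ORF-fraction comparisons. Context strings of arbitrary length are supported,
so both one- and two-base downstream readings of a non-3G pattern are
expressible.

## Structural validation

* **LTR detection** (`extractLTRs()`): the highest-scoring local alignment
  between the head and tail of the sequence, with defaults `minLen = 400`,
  `minIdentity = 0.85` and terminal anchoring within 10% of each end —
  bounds chosen from observed SERV LTR lengths (means 484/486 nt, range
  439–495 nt) with slack for deletion variants. Search windows never cross
  the sequence midpoint (the two copies cannot overlap). Because retroviral
  LTRs canonically begin `TG` and end `CA`, boundaries are snapped to that
  motif within ±6 nt when both copies carry it; this removes chance
  extensions of the alignment into flanking sequence and is skipped when the
  alignment contains indels or the motif is absent.
* **TSD** (`detectTSD()`): the duplication is treated as binary evidence of
  integrase-driven insertion, so an exact 6/6 match is required; any
  mismatch reports "absent" rather than fuzzy-matching.
* **PBS** (`extractPBS()`, `classifyPBS()`): classification is by
  Levenshtein (not Hamming) distance to the two reference 18-mers, so the
  common single-nt-insertion variants classify correctly; the extraction
  window widens to 19 nt when a single insertion fits both references
  strictly better. Equal distances yield "ambiguous", never an arbitrary
  pick. Genotype assignment (`classifyGenotype()`) is by whole-genome
  distance, not PBS, because PBS switching between genotypes occurs; ties
  within `K` of 0.01 are "unassigned".
* **Assembly validation** (`validateProvirus()`): proviruses whose LTR pair
  is wildly more divergent than the cohort's are likely assembly artifacts.
  "Does not cluster" has no published numeric definition, so the package
  declares one: suspect when the LTR-pair distance exceeds 3× the cohort
  median within-provirus distance or an absolute cap of 0.15, or when the
  distance is saturated. Both thresholds are configurable. When the cohort
  median is 0 (identical-LTR cohorts), only the absolute cap applies.
* **ORF scanning** (`orfStatus()`): frameshift when the length differs from
  the reference by a non-multiple of 3; otherwise premature stop at the
  first in-frame TAA/TAG/TGA before the terminal codon; otherwise open.

## Neutrality

`tajimasD()` contrasts mean pairwise diversity with the segregating-site
count under complete deletion, using the standard constants; $\pi$ is
computed on difference *counts* (the per-site value is reported
additionally), matching the convention of the desktop phylogenetics tools
this workflow replaces. Sequences with out-of-frame indels should be
excluded upstream via `orfStatus()`. `n < 4` warns rather than errors —
per-genotype ORF sets can be legitimately tiny. Monomorphic alignments
report $S = 0$, $\pi$, and an undefined $D$.

## The simulator and what it does (not) emulate

`simParams()` defaults *are* the study conditions: an 8393-nt provirus with
two identical 485-nt LTRs (TG…CA termini), the chosen PBS immediately 3' of
the 5' LTR, open gag (1977 nt), pol (2613 nt) and env (1713 nt) ORFs,
region-specific base composition (gag-pol ~33.3% A, env ~29.7% A, LTR
~22.6% A — the A-rich, G-poor D-type profile), and CpG content planted to
198 (genotype-1 profile) or 144 (genotype-2) dinucleotides ±5%. Integration
duplicates a 6-nt target site; evolution is per-site Bernoulli with
probability $r\,t$ (Poisson approximation — adequate because $r\,t \le 0.1$
in all default regimes, and far simpler to replay than a Gillespie
simulation), spread over 10 epochs with a 4:1 transition:transversion event
weighting. The transversion spectrum of these proviruses is unreported; 4:1
is a tunable modeling default. Sites that are currently the C or G of a CpG
receive additional deamination transitions (C→T / G→A, equal weight) at
$1.6\times10^{-7}$ s/s/y, with hotspot status re-evaluated each epoch so a
destroyed CpG stops being hot — mutated CpGs are historical, not ongoing.
An optional APOBEC episode edits qualifying plus-strand sites *before*
integration with independent per-site probability, contexts evaluated
against the pre-edit sequence (making the edit order-independent). Every
mutation is logged (position, from, to, cause) and the logs replay exactly
to the emitted sequences, which is itself tested.

The simulator deliberately omits: indel evolution (except that `orfStatus()`
is exercised with constructed indels), recombination and solo-LTR formation,
selection, alignment uncertainty, and assembly error. Passing tests
therefore demonstrate the correctness and calibration of the *methods* under
the stated model — not robustness to misalignment or to the heterozygosity
and assembly artifacts of real genome data.

## Numerical and design choices

* **Column filter**: coverage counts `N` as missing (consistent with
  partial-deletion conventions, which group gaps, missing data and ambiguous
  bases); the ≥ boundary is inclusive. Whether published 95%-coverage
  filters count `N` as coverage is ambiguous; this package declares the
  stricter reading.
* **Consensus ties** return `N`, never an alphabetical pick, so the CpG
  census cannot fabricate a mutation direction.
* **Coordinates**: 0-based half-open internally where slicing demands it,
  1-based inclusive in every user-facing report (`IRanges` convention).
* **Undamaged loci** in round-trip validation are defined from the truth
  log: no mutation inside either TSD copy (TSD recovery), and ≤1 mutation
  inside the PBS window for label recovery — the two PBS references are 4
  edits apart, so a single edit cannot flip the nearest-reference call.
* **Determinism**: all simulator randomness flows from one master seed via
  derived child seeds; the RNG state of the caller is restored afterwards.

## Validation scale

The test suite validates the stochastic claims at these problem sizes,
chosen to give comfortable statistical resolution: dating recovery with 50
replicates per truth age (1, 3, 8 Myr; mean within 15% of truth, mean LTR
divergence at 3 Myr within [0.026, 0.034] against the expectation
$2rT = 0.03$); hypermutation sensitivity on 100 APOBEC-edited replicates
(efficiency 0.3, ≥50 potential sites; ≥90% flagged at $p<0.05$) and type-I
error on 200 neutral replicates (≤7%, allowing for the discreteness of the
exact test); exact-test agreement with exhaustive enumeration for all 2×2
tables with total ≤ 60; Tajima statistics against a brute-force oracle on
50 random alignments up to 20×100 plus 100 star-phylogeny replicates; and
CpG census recovery over 100 replicates at per-site probability 0.15
(mean within 0.02). `scripts/acceptance.R` recomputes the same quantities
from scratch at the same sizes.

## Known limitations

* The count-based transition:transversion ratio is downward/upward biased
  relative to ML estimates on real, tree-structured data; it is intended
  for simulation checks only.
* LTR detection assumes terminal, same-orientation, non-overlapping
  repeats; heavily deleted or rearranged proviruses and solo LTRs are out
  of scope.
* With the CpG-elevated process switched on, fast-rate ages are biased
  upward (CpG mutations inflate $K$) — this mirrors the real rate-choice
  dilemma for ERV dating and is asserted directionally in the tests rather
  than "corrected".
* At ages ≥ 8 Myr the expected per-CpG-site mutation probability exceeds
  0.5 and the simulator emits a saturation warning; CpG-site ages at that
  depth should not be taken quantitatively.

## A worked example

```{r example, eval = FALSE}
library(ervkit)

params <- simParams()                       # SERV-1 profile, 8393 nt
cohort <- generateCohort(params, agesYears = c(1e6, 3e6), apobec = FALSE,
                         nPerCell = 5, seed = 11)
res <- runPipeline(cohort$records, outDir = "serv_run")

res$summary$ageFast$meanMyr                 # recovered cohort mean age
res$summary$cpgFractionMean                 # CpG sites mutated vs consensus
head(res$ages)
```
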