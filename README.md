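# ervkit

Characterization, molecular dating and mutation-signature analysis of
full-length endogenous retrovirus (ERV) proviruses, built around the simian
endogenous retrovirus (SERV) of Old World monkeys as the model system.

## What it does, and for whom

A provirus integrates as `LTR–gag–pro/pol–env–LTR` with two *identical* long
terminal repeats (LTRs), a tRNA primer binding site (PBS) just 3' of the 5'
LTR, and a 6-nt target-site duplication (TSD) of host sequence on both
flanks. For a paleovirologist working from a set of such loci, `ervkit`
provides the complete downstream workflow:

- **Structural validation** — terminal LTR detection (`extractLTRs`), exact
  TSD detection (`detectTSD`), PBS extraction and tRNA-lys3 / tRNA-lys1,2
  classification by edit distance (`extractPBS`, `classifyPBS`), ORF
  interruption scanning (`orfStatus`), and flagging of mis-assembled records
  whose two LTRs "do not cluster" (`validateProvirus`).
- **Distances** — Kimura-2-parameter distances with pairwise- or
  complete-deletion gap policies, optional gamma rate variation, optional
  CpG-column exclusion (`k2pDistance`, `distanceMatrix`), nucleotide
  composition and distance-based genotype assignment.
- **Dating** — integration ages from LTR divergence,

  T = K / (2 r),

  where `K` is the K2P distance between a provirus's own 5' and 3' LTR and
  `r` the neutral substitution rate (fast 5e-9 / slow 2.3e-9
  substitutions/site/year), plus cross-species TMRCA logic for shared
  integrations (`dateIntegration`, `provirusAge`, `sharedProvirusAges`,
  `eventAge`).
- **Mutation signatures** — a CpG methylation-deamination census
  (CpG→TpG / CpG→CpA; `cpgCensus`, `cpgStrandSplit`) and HYPERMUT-style
  context-dependent APOBEC3 G→A scans with one-sided exact-test enrichment
  (`hypermutScan`, `fisherExact`), using CpG-excluding patterns such as
  `K-(G>A)-D` with control `K-(G>A)-N`.
- **Neutrality** — Tajima's D on ORF alignments (`tajimasD`).
- **Simulation** — a truth-tagged endogenization simulator (`simParams`,
  `makeAncestor`, `integrateProvirus`, `apobecEdit`, `evolveSequence`,
  `generateCohort`) whose defaults emulate a full-length SERV provirus:
  8393 nt genome, identical 485-nt LTRs, planted CpG content (198 or 144
  sites by genotype profile), neutral substitution at 5e-9 s/s/y with 4:1
  transition bias, CpG deamination at 1.6e-7 s/s/y, and an optional
  pre-integration APOBEC editing episode. Every mutation is logged and
  replayable.
- **Orchestration** — `runPipeline()` runs all stages over a locus set and
  writes per-stage TSVs plus a JSON summary.

See the methods vignette (`vignettes/ervkit-methods.Rmd`) for the models,
assumptions, parameter defaults and known limitations.

## A worked example

```r
library(ervkit)

# Dating a shared integration from its gelada LTR pair (K = 0.072, fast rate)
dateIntegration(0.072, 5e-9, label = "chr17 5p/3p LTR, gelada")
#> AgeEstimate [chr17 5p/3p LTR, gelada]: K = 0.072 at r = 5e-09 s/s/y -> T = 7.2 Myr

# Simulate a small cohort and run the whole workflow
params <- simParams()                      # SERV-1 profile, 8393 nt provirus
cohort <- generateCohort(params, agesYears = c(1e6, 3e6), apobec = FALSE,
                         nPerCell = 5, seed = 11)
res <- runPipeline(cohort$records)

head(res$ages[, c("id", "K", "status", "tFastLabel", "tSlowLabel")], 4)
#>                 id          K status tFastLabel tSlowLabel
#>  locus_1myr_neu_01 0.03186110  valid        3.2        6.9
#>  locus_1myr_neu_02 0.02749426  valid        2.7        6.0
#>  locus_1myr_neu_03 0.02105574  valid        2.1        4.6
#>  locus_1myr_neu_04 0.02105574  valid        2.1        4.6
```

`K` is each provirus's 5'-vs-3' LTR distance and the two labels are its age
under the fast and slow rate, printed to 0.1 Myr (`"<0.3"` when `K = 0`).
Note the fast-rate ages of the 1-Myr loci run high: the default simulation
includes the elevated CpG deamination process, which inflates LTR divergence
— exactly the rate-choice caveat that makes ERV dating report ages under two
rates. With `simParams(cpgRate = 0)` the estimates are unbiased (this is
what the parameter-recovery tests check).

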