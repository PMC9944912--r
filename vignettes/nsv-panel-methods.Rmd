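---
title: "From coding variants to selection signals: the models behind nsvatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From coding variants to selection signals: the models behind nsvatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsvatlas)
```

nsvatlas implements the computational pipeline behind non-synonymous-variant
(NSV) panel studies in species with well-annotated genomes, with the turbot
(*Scophthalmus maximus*) wild/farm system as its reference design: classify
coding SNVs, prioritise them into a genotyping panel through an auditable
filter cascade, summarise panel genotypes with F-statistics, and scan for
loci under divergent or balancing selection against a simulated island-model
null. This vignette explains the models, the defaults, and the choices made
where the design was genuinely open.

## Effect annotation

A variant is classified against a single-transcript gene model (CDS
segments in transcription order, internally 0-based half-open; conversions
to the 1-based conventions of GFF3 and VCF happen only at format
boundaries). The affected codon is extracted from the spliced CDS — codons
spanning two CDS segments are handled by construction — the alternate base
is substituted (reverse-complemented for minus-strand genes), and both
codons are translated under the standard nuclear genetic code. Classes are
`synonymous`, `missense`, `stop_gained`, `stop_lost`, `start_lost` (codon 1
ATG lost) and `noncoding`; an ambiguous `N` in the reference codon makes the
call `unresolvable`, excluded with a logged count. Substitution notation is
the field's compact form (`A44T`: reference residue, 1-based codon index,
alternate residue).

The test suite holds the classifier to 100% agreement with an independent
brute-force oracle (translate the full mutated CDS, diff the proteins) on
1,000 random substitutions across strands and exon-spanning codons, and to
invariance under reverse-complementing the genome.

## The filter cascade

`run_cascade()` turns a raw annotated call set into a genotyping panel.
Steps, in order, with defaults:

| step | rule | default |
|---|---|---|
| nsv | keep missense/nonsense classes | — |
| qual | site Phred quality | keep `QUAL >= 30` |
| pseudogene | genes with too many NSVs dropped whole | `>= 3` missense |
| nonsense | drop truncating stop-gains | on |
| triallelic | drop sites with 2+ alternate alleles | on |
| flanking | no other variant within the primer window | ±100 bp, inclusive |
| hwe | exact-test exclusion in the discovery cohort | `p < 0.01` |
| deleterious | externally scored substitutions | verdict join |
| candidate | marker within gene or nearby | `< 500` kb, strict |
| maf_top | per gene, most diverse eligible SNP | MAF `>= 0.10` |

Design choices worth stating:

* **Flanking cleanliness is judged against the full pre-cascade variant
  set**, including indels and synonymous sites, because any variation
  disrupts primer annealing; the window is inclusive (a neighbour at
  exactly 100 bp fails, at 101 bp passes). Because this step references the
  pre-filter set, the cascade is idempotent on its own output for every
  step *except* flanking, which is documented and tested.
* **`stop_lost`/`start_lost` are retained but flagged**; only stop-gains
  produce the truncated proteins the nonsense criterion targets.
* **The pseudogene heuristic counts missense calls only** (the NSV
  definition), and removes all of a dropped gene's calls together.
* **HWE screening uses the discovery cohort** (the resequenced individuals)
  because filtering precedes panel genotyping; the exact test is Levene's
  conditional distribution with probability-ordered two-sided p-values.
* **Ties in the per-gene MAF maximisation break to the smaller genomic
  position**, making the panel deterministic.
* Every removed call carries exactly one first-failure reason code; the
  ledger records `count_in`/`count_out` per step with drop percentages
  relative to the immediately previous step (one decimal), and the
  reason-code counts reconcile with the ledger deltas by construction.

True multiplex assay design (primer chemistry, plex compatibility) is out
of scope; the flanking-cleanliness rule is its technical proxy.

## Population-genetic summaries

Expected heterozygosity uses Nei's unbiased small-sample correction
`2n/(2n-1) * (1 - sum p_i^2)` (the plug-in estimator is available via an
argument). `F_IS = 1 - H_O/H_E` is reported as `NA`, not 0, for monomorphic
locus-population cells. The exact Hardy-Weinberg test enumerates Levene's
conditional distribution of the heterozygote count given allele counts; a
mid-p variant exists but is off by default.

Differentiation uses the Weir-Cockerham unbiased ANOVA estimator: per-locus
variance components `a` (among populations), `b` (among individuals within
populations), `c` (within individuals), with `theta = a/(a+b+c)` — negative
estimates are meaningful and retained. Multilocus and pairwise values
combine components by **ratio of sums**, never by averaging per-locus
ratios. The hierarchical wild-versus-farm analysis is a four-level nested
random-effects ANOVA on allele-count indicators (group / population /
individual / allele copy) with method-of-moments components from the
unbalanced expected-mean-square equations; `F_CT` is the among-group
component over the total, `F_SC` the among-population component within
groups. For the flat design this construction reproduces the
Weir-Cockerham components exactly, which the tests exploit as a
dual-implementation oracle. Statistics are computed on pairwise-complete
per-locus data under missingness.

Where a per-locus summary averages diversity across population samples
(`locus_summary()`), the mean is unweighted by sample size; both per-locus
and per-population averaging conventions of H~E~ differ slightly and the
underlying per-cell table (`locus_pop_stats()`) is exported so either can
be formed.

## The outlier scan

The scan follows the FDIST logic: simulate a neutral null of (He, F~ST~)
pairs under an island model matched to the data, then judge each observed
locus by its conditional tail probability given heterozygosity.

* **Calibration.** The scaled migration rate is bisected until the median
  simulated per-locus F~ST~ matches the target within 0.005. The target is
  the trimmed multilocus theta of the scanned loci (top and bottom 5% of
  per-locus estimates removed) — or a user-supplied neutral-background set,
  which is the better choice when the scanned panel is itself enriched for
  candidates, as NSV panels are.
* **Engines.** The default fast engine draws per-deme allele frequencies
  from the Balding-Nichols beta distribution at the F implied by the island
  model (ancestral frequency uniform, monomorphic samples redrawn) and
  genotypes binomially under within-deme Hardy-Weinberg equilibrium. The
  reference engine simulates a structured-coalescent genealogy of the
  sampled copies (100 demes by default; coalescence rate 1 per within-deme
  pair, per-lineage migration `M/2`) and places a single mutation uniformly
  on the tree, which guarantees sample polymorphism. Both run off R's RNG,
  so identical seeds give bit-identical clouds.
* **Conditioning.** p-values are computed among the `k = 1000` simulated
  loci nearest in He (k-nearest-neighbour rather than fixed bins — robust
  at sparse He extremes), with the add-one correction
  `p = (count + 1)/(k + 1)` so p-values are never zero.
* **Classification.** Divergent when `p_upper < 0.01`, balancing when
  `p_lower < 0.01`; loci reaching only 0.05 are tagged *suggestive*.
  Monomorphic observed loci are excluded with a logged reason.
* **Hierarchical mode.** For wild-versus-farm contrasts the null is a
  two-level island model (20 groups of 100 demes by default; migration
  within groups above migration between), calibrated sequentially — the
  within-group rate against the wild-only differentiation, the
  between-group rate against the observed total — and the observed
  statistic is the per-locus total F~ST~ from the hierarchical
  decomposition.

### Known limitation: the fast engine's tails

The two engines agree closely in location (medians match after calibration)
but not in conditional tail weight: with 16 demes of 25 diploids sampled at
target F~ST~ 0.05, the coalescent null's conditional 0.99 F~ST~ quantile
exceeds the beta-binomial engine's by about 0.03-0.045 for He above 0.15
and by up to 0.08 below it. The cause is structural: genealogical noise
gives each coalescent locus its own realized differentiation (young,
deme-localized alleles dominate low He), whereas the fixed-F beta model
only carries sampling noise. The coalescent engine was checked against an
independent simulator (msprime) and matches it; the gap is a property of
the approximation, not a bug. Consequence: at a strict 0.01 threshold the
fast engine is mildly anticonservative relative to the coalescent null for
rare alleles. For final inference on real data, or whenever low-He loci are
decision-relevant, run the scan with `engine = "coalescent"`; the fast
engine is the right tool for simulation studies whose data generator is
itself Balding-Nichols, where its type-I rate is accurate by construction
(verified at 0.008 against a nominal 0.01 in the acceptance suite).

## The synthetic-data generators

The generators produce every pipeline input with known truth, and their
defaults are the study conditions, not tuning knobs:

* **Panel design:** 16 population samples — 13 wild (Baltic, Atlantic,
  Mediterranean, Black Sea regions) plus 3 farm broodstocks — totalling 355
  diploids, genotyped at 18 unlinked biallelic loci.
* **Frequencies:** ancestral minor-allele frequency uniform on
  [0.01, 0.5]; wild-population frequencies Balding-Nichols at the
  locus-specific F — background 0.05, divergent 0.25 (2 of 18 loci),
  balancing 0.005 (2 of 18) — chosen so that per-locus estimates across
  seeds span the empirical panel range (about -0.009 to 0.15).
* **Farms:** each farm resamples a founder pool (default 25 diploids) from
  a designated Atlantic wild source and drifts binomially for 5
  generations, the documented breeding history of the system; artificial
  selection is emulated by directly planting group-divergent loci (a farm
  allele-frequency shift), not by a selection model.
* **Missingness** defaults to one masked call per 6,390 genotypes, the
  near-perfect assay consistency the target platform attains.
* **Genomes and spikes:** random multi-exon genes on both strands with ATG
  start, clean stop and no internal stops; planted variants carry
  generator-side truth computed directly from the affected codon
  (independent of the classifier under test), spaced > 200 bp apart unless
  a flank violation is the point of the plant.

What passing tests on these data do **not** show: the generator has no
linkage, no clinal geography (islands are exchangeable, real samples are
not), no genotyping error, and BN frequencies rather than coalescent ones —
so calibration results transfer to real data only to the extent the island
model does, which is exactly the caveat the FDIST family always carries.

## Numerical and reproducibility choices

Monomorphic loci: theta undefined (`NA`), H~E~ 0, exact-test p 1. HWE
probability ties are compared with a `1 + 1e-9` relative tolerance.
Degenerate hierarchical designs (< 2 groups sampled) are errors, not
silent `NA`s. All stochastic functions take a `seed` argument, run under a
locally restored RNG state, and are bit-reproducible; every output table
carries a provenance header (package version, seed, configuration hash) so
byte-identity across reruns is testable. Simulation problem sizes in the
test and acceptance suites (200-locus panels, 10,000-50,000-point null
clouds, 20-seed replications) were chosen as the smallest sizes at which
Monte-Carlo error is well below the tolerances being asserted.

## Interfaces

Exported functions are the primary interface; `inst/cli/nsvatlas.R`
provides thin `simulate`/`annotate`/`filter`/`stats`/`scan` subcommands
over them for shell pipelines. Genepop export (`write_genepop()`, 2-digit
allele codes, `0000` missing) supports cross-checks against external
population-genetics software.
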