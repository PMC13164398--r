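---
title: "Methods: BSA-seq scanning, interval calling, and fine-mapping"
author: "bsaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSA-seq scanning, interval calling, and fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The experimental design and its genetic model

`bsaqtl` targets the classic bulked-segregant mapping design: two fully
homozygous inbred parents with contrasting phenotypes are crossed, the F₁
is selfed, and a large F₂ segregates for the trait. The motivating
application is whole-plant shoot branching in sunflower, where the
non-branched allele is completely dominant: genotypes *AA* and *AH* at the
causal locus are non-branched, *BB* plants branch along the whole stem.
Under this model an F₂ segregates 3:1, which `chisq_goodness_of_fit()`
tests with unrounded expected counts (for 626 plants under 3:1 these are
469.5 and 156.5; rounding them to integers would distort the statistic in
the third decimal) and no continuity correction. The recessive-class
proportion is summarized with a **Wilson score interval**
(`stats::prop.test(correct = FALSE)`), chosen over Wald and
Clopper–Pearson because it keeps honest coverage at a few hundred plants
and behaves correctly at the boundaries (its lower bound at zero successes
is exactly 0 and its upper bound is z²/(n+z²)).

Two DNA bulks are formed from the phenotypic extremes (default 30 plants
each) and sequenced together with the parents (~30× per sample). At a
variant site where the parents are fixed for opposite alleles, the bulks'
allele frequencies diverge only near the causal locus; everything in the
scan machinery quantifies that divergence.

## Per-site statistics

All three channels are computed by `compute_site_stats()` from the
ref/alt read depths of the two bulks, after polarization:

* **SNP-index** per bulk = read fraction of the allele carried by parent B
  (the high/branched parent). The parent-B allele is determined per site
  from parent B's own reads, so the statistic is polarized identically at
  every site regardless of which allele the reference genome happens to
  carry. At a fully dominant causal locus with exact phenotyping, the
  branched bulk is all *BB* (index 1) and the non-branched bulk is
  *AA*:*AH* = 1:2 (index 1/3), so Δ(SNP-index) = index_high − index_low
  has expectation **2/3** at the locus, decaying to 0 with genetic
  distance — the analytic anchor used throughout the test suite.
* **G statistic** = 2 Σ obs·ln(obs/exp) over the 2×2 (bulk × allele)
  read-count table, expected counts from the marginals under independence,
  0·ln 0 = 0, natural logarithm. A site with a zero marginal (a bulk with
  no reads, or an allele absent from both bulks) is undefined, carried as
  `NA`, and excluded from smoothing — never coerced to 0, which would
  dilute window means.
* **ED** = √2·|p_high − p_low| for biallelic frequency vectors, and ED⁴,
  which suppresses background relative to peaks before smoothing.

Each channel handles degeneracy independently: a site with zero depth in
one bulk is undefined for all three, but a site with depth in both bulks
and a zero allele marginal is undefined only for G.

## Informative-marker filters

`filter_informative()` applies, in a fixed order (site quality, mapping
quality, parent depth, bulk depth, parental fixation), the thresholds
QUAL ≥ 30, MQ ≥ 30, total depth ≥ 10 in each parent and ≥ 15 in each
bulk, and requires the parents to be homozygous for opposite alleles.
Homozygosity is operationalized as ≥ 90% of a parent's reads supporting
one allele (`hom_frac = 0.9`): demanding literal 100% would discard
genuinely fixed sites hit by a single sequencing error, while 90% still
rejects heterozygous parents decisively at depth ≥ 10. The fixed rule
order makes per-rule exclusion counts deterministic and additive (each
excluded site is attributed to the first rule it fails), and the filter is
idempotent. Both SNPs and indels flow through one code path, tagged by a
`class` column computed from allele lengths.

## Window smoothing and thresholds

Per-site statistics are noisy at 30× depth (a binomial read draw per
bulk), so each channel is smoothed into a `window_track`:

| channel | smoothing | step | why |
|---|---|---|---|
| Δ(SNP-index) | 4 Mb window mean | 10 kb | see below |
| G′ | 1 Mb tricube kernel per site | 10 kb grid | depth-noise scale |
| ED⁴ | 4 Mb window mean | 200 kb | channel convention |

Windows are anchored at fixed genomic offsets (1, 1+step, …), truncated at
chromosome ends; a window's value is the arithmetic mean of non-missing
site values inside it, and empty windows are `NA`. G′ is evaluated
site-wise — the tricube weight w = (1 − (d/D)³)³ over sites within half a
window of the focal site, which drops smoothly to exactly zero at the
half-window distance — and then aggregated onto the same anchored grid so
that interval calling is channel-agnostic.

The significance cutoff per channel is the **0.999 linear-interpolation
sample quantile** (type 7) of all non-missing window values pooled across
chromosomes. A quantile of the smoothed (not raw site) distribution is
used because the scan operates on the smoothed scale; the realized cutoff
is therefore data-dependent and is recomputed for every dataset.

**Why a 4 Mb window for Δ(SNP-index).** The quantile threshold retains by
construction about 0.1% of windows, i.e. a supra-threshold sliver of
roughly 0.001 × genome length plus one window width around the peak
summit. The summit itself wanders around the true locus: bulk-composition
noise changes only through crossovers among the ~120 bulk chromosomes
(steps of ~1/60 in frequency about every centimorgan), while the expected
Δ(SNP-index) falls off only linearly (2/3 − (4/3)·r for recombination
fraction r on the non-branched-bulk side). At 1 cM/Mb these two scales
imply summit wander of a couple of megabases. A 1 Mb window leaves the
called interval narrower than that wander and the scan misses the locus in
a substantial fraction of replicates; 4 Mb — the smoothing scale of the
original QTL-seq protocol — widens the called span enough that the
package's recovery property (the interval contains the causal position in
at least 90% of seeded replicates at the reference design) holds. All
window sizes remain configurable via `scan_config()`.

## Interval calling and the ten-variant rule

`call_intervals()` merges maximal runs of above-cutoff windows whose spans
overlap, snaps interval boundaries to the outermost variant positions
inside the merged span (reported coordinates are variant-resolution, as
scan intervals conventionally are), and keeps a region only if it has at
least `min_variants_above = 10` supporting variants.

"Variants above the threshold" admits two readings, and the package
exposes both (`count_above`):

* `"site"` (default): a supporting variant's **own per-site statistic**
  must exceed the cutoff;
* `"window"`: any variant inside an above-cutoff window counts.

The site-level reading is the package default because it is the one that
makes the rule discriminating. Under a null simulation (no causal locus)
the 0.999 quantile still leaves ~0.1% of windows above the cutoff —
clustered at the genome-wide noise maximum because adjacent windows share
almost all their sites — so the window-level reading counts every variant
in that cluster and routinely calls a false interval. Site-level support
requires individual variants to reach the smoothed-scale cutoff, which
raw-site noise rarely does inside a null cluster; the package's null
property (fewer than one called interval per replicate on average) holds
under this reading and not reliably under the other.

Interval lengths are reported as end − start in bp and in Mb rounded
half-up to two decimals (matching how such tables are conventionally
printed; banker's rounding would print 3.365 as 3.36 or 3.37 depending on
parity). `interval_overlap()` gives overlap in bp, the overlap as a
fraction of each interval, and containment flags.

## The simulator

`simulate_f2()` draws, per gamete and chromosome, a Poisson number of
crossovers with mean equal to the genetic length in Morgans, places them
uniformly, and alternates parental phase — the Haldane no-interference
model that underlies the standard F₂ mapping functions. Phenotypes follow
the causal genotype under complete dominance, optionally flipped with a
misclassification probability; the causal position need not be a marker
(the gamete phase is evaluated at the exact causal coordinate).
`make_bulks()` samples without replacement within phenotype class;
`sequence_bulks()` draws per-sample site depth as Poisson and read counts
as binomial in the true bulk allele frequency, shifted symmetrically by a
sequencing error rate (default 10⁻³), with ref/alt orientation randomized
per site so downstream polarization is genuinely exercised. Parents are
emitted as fixed opposite homozygotes with qualities above the filter
thresholds.

`study_design()` freezes the reference conditions: 17 chromosomes × 176 Mb
(a sunflower-scale genome) at 1 cM/Mb, n = 660 F₂ individuals, bulks of
30, 30× depth per bulk and parent, a causal locus on chromosome 10, and
uniformly placed markers — 2,000 on the causal chromosome, 500 elsewhere
(10,000 genome-wide). The genome-wide marker density is kept near this
scale deliberately: at several-fold higher densities every supra-threshold
noise cluster contains many variants and the ten-variant rule loses its
discriminating power.

**What the simulator does not emulate:** read-level artifacts (mapping
error, duplicates, indel realignment), depth heterogeneity beyond Poisson,
linked selection or segregation distortion, multi-locus or epistatic trait
architectures, and the intermediate branching classes observed in real
populations (only the binary extreme contrast used for bulks is modeled).
Passing tests therefore demonstrate the statistical machinery under the
idealized design, not robustness to alignment or calling artifacts — those
are the province of the upstream variant-calling pipeline whose VCF output
this package consumes.

## Fine-mapping

`delimit_locus()` treats each genotyped recombinant as a constraint under
complete dominance: a branched individual must be *B* at the locus (its
*A* and *H* blocks are excluded), a non-branched individual must not be
*B* (its *B* blocks are excluded); missing calls constrain nothing, and
breakpoints adjacent to missing calls are localized only to the span
between flanking non-missing markers (`genotype_blocks()`). The locus is
the intersection of all constraints. Boundaries are reported at the
nearest excluded markers flanking the allowed run — the locus lies
*between* those markers, which is how fine-mapped intervals are named by
their flanking assay markers — or at the panel's outermost marker when the
allowed run reaches the panel edge. An empty intersection is flagged
(`consistent = FALSE`, with the individuals whose removal would restore
consistency) rather than resolved: phenotype misclassification is
surfaced, never silently absorbed.

Because constraints are evaluated at marker resolution, a panel with many
recombinants whose breakpoints bracket the locus tightly on both sides can
exclude *every* marker even though all individuals are genetically
consistent with a locus between two adjacent markers; real recombinant
screens genotype a handful of informative plants, which
`panel_from_population(max_individuals =)` mirrors.

`select_markers()` picks genotyping-assay candidates in a target region:
sites passing the informative filters with no other variant within
`flank_clear = 50` bp on either side (a typical allele-specific-PCR primer
constraint). From the candidates it maximizes the minimum spacing —
including the gaps to the region endpoints — by bisection over the spacing
value with a left-to-right greedy feasibility check, which solves the
max–min placement problem exactly. A farthest-point heuristic was
considered and rejected: it places markers at dyadic midpoints and its
minimum gap can fall well below the achievable region/(n+1).

## Numerical conventions

* Coordinates are 1-based inclusive internally; BED export converts to
  0-based half-open.
* Undefined statistics are `NA` end to end; no zero-imputation anywhere.
* Quantiles are type 7 (linear interpolation), R's default.
* Mb/kb display rounding is half-up; all arithmetic is done in bp.
* All randomness flows through explicit integer seeds; per-stage sub-seeds
  are derived deterministically from the root seed, so a pipeline rerun
  with the same configuration is byte-identical.
* `g_statistic()` clamps the tiny negative residue that floating-point
  cancellation can leave on exactly-independent tables.

## Problem sizes in the test suite

The suite validates large-sample behaviour at n = 10,000 individuals
(3-standard-error bands around the 3:1 and 1:2:1 oracles), scan recovery
and the null false-call rate on 20 seeded replicates each of the reference
design, and fine-map containment on 20 simulated 12-recombinant panels;
brute-force oracles (window re-means, tricube weighted means, exhaustive
marker-spacing search, log-linear model G) run at small n where
exhaustive computation is exact. These sizes are the package's chosen
validation scale; all of them are plain function arguments and can be
increased by the user.

## Known limitations

* The G′ implementation smooths G with a distance kernel but does not
  implement the companion null-variance model for analytic p-values; the
  package's thresholds are empirical genome-wide quantiles instead.
* Interval calling assumes a single biallelic contrast; multi-bulk or
  multi-parent designs are out of scope.
* The delimitation logic is exact for complete dominance only; other
  penetrance models would need a different constraint mapping.
* The empirical 0.999-quantile threshold always flags ~0.1% of windows,
  so on a truly null dataset the *threshold* exists even though the
  ten-variant rule usually rejects the resulting regions; users comparing
  channels should inspect supporting-variant counts, not only cutoffs.
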