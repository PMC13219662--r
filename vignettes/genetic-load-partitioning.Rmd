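---
title: "Partitioning genetic load and inferring purging and inbreeding from genotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning genetic load and inferring purging and inbreeding from genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loadscape)
```

## The problem

Very small, isolated populations — island endemics, relict
micro-populations — accumulate and express deleterious variation in a
characteristic way. Under the common assumption that most deleterious
mutations are (close to) recessive, a deleterious allele in a
heterozygote is hidden from both selection and phenotype: it
contributes to the **masked load**, a liability for future
generations. The same allele in a homozygote is expressed and reduces
fitness now: the **realized load**. Drift and inbreeding in a small
population move variation from the first column to the second, while
selection against exposed homozygotes can remove strongly deleterious
alleles altogether — **purging**. Distinguishing these regimes
requires counting genotypes per deleteriousness class, polarized into
ancestral and derived states, and an independent measure of inbreeding
and recent demography, which runs of homozygosity (ROHs) provide.

`loadscape` implements this analysis chain as composable,
tibble-in/tibble-out functions, plus a synthetic-data generator that
reproduces the statistical structure of such a study design so that
every stage is testable end to end.

## Filtering model

Filtering operates on already-called records (variant calling itself
is out of scope). Site-level thresholds apply to SNP records
(QUAL < 60, QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < −20,
ReadPosRankSum < −8); indels are retained only when QUAL ≥ 60 and only
to remove SNPs within 5 bp of them, since variation near indels is
alignment-artifact prone. Genotype-level masking sets single calls to
missing on GQ < 10 (SNPs), RGQ < 10 (invariant sites) or a depth
outside (mean/3, 2·mean) — bounds are exclusive, so a genotype at
exactly twice the sample's mean depth survives. Sites with more than
25 % missing genotypes after masking are removed, as are excluded
chromosomes (e.g. sex chromosomes) and region masks (repeats,
high-heterozygosity regions), supplied as BED (converted to the
package's 1-based inclusive coordinates on read).

Three choices were genuinely open and are worth recording:

- **Depth reference.** "Mean depth" is read as the *per-sample*
  genome-wide mean (DP is a per-genotype FORMAT field in the standard
  toolchain), not a cohort site mean; `mean_depths` is an explicit
  argument, so either convention can be supplied.
- **Missing INFO keys.** A record lacking an annotation needed by an
  enabled rule *fails* that rule (counted in the report). GATK would
  silently pass it; failing closed is the conservative choice for a
  load analysis, where a biased surviving set is worse than a smaller
  one.
- **Rule attribution order.** A site failing several rules is counted
  under the first in the fixed order QUAL → QD → FS → MQ → MQRankSum →
  ReadPosRankSum → indel proximity → excluded chromosome → region mask
  → missingness. The order affects only the report's attribution; the
  surviving set is the complement of the union of failures, which the
  tests assert directly.

The missingness rule is evaluated *after* genotype-level masking by
default (`missingness_before_masking` switches this), since masked
genotypes are exactly as uninformative as missing ones.

## Ancestral polarization

Two outgroup species anchor the derived/ancestral assignment: a
distant species A (four individuals) and a nearer species B (two).
The ancestral allele must be carried **homozygously** by at least
three A individuals and by every called B individual (at least one B
called); any heterozygous outgroup genotype discards the site
outright, because an outgroup segregating for both alleles carries no
information about the pre-divergence state. Missing outgroup genotypes
are tolerated — support is counted over called individuals — but the
A-support threshold stays absolute (≥ 3 of 4), which is the
conservative reading when data are missing. Analyzable sites must then
carry at least one derived allele in the pooled ingroup and not be
fixed derived across it (a fixed difference carries no
within-population information). All discarded sites are retained with
a status label, so statuses partition the input and the accounting is
checkable.

The tests verify the assignment against an independently written
brute-force evaluator over *all* 4^6 outgroup genotype configurations,
and against generator truth: with no outgroup-branch mutation the
recovery is exact, and every error at positive mutation rates traces
to a simulated post-divergence substitution.

## Load classes and counting

Effect classes follow the standard annotation-impact mapping:
synonymous → LOW, missense → MODERATE, and the nonsense set
(stop-gained, start-gained, start-lost, splice-acceptor, splice-donor)
→ HIGH. When one site carries several effect terms, the first decides
— annotators order effects by impact and canonical transcript, so
position 1 is the intended summary. Conservation classes use a strict
GERP > 4 cutoff; classes deliberately overlap (high-GERP missense is a
class of its own), and the synonymous class is carried through every
comparison as the neutral baseline.

Per individual and class, the masked load is the heterozygous-genotype
count and the realized load the homozygous-derived count; missing
genotypes contribute to neither, and the identity
`derived = masked + 2 × realized` is asserted on every run. Population
frequencies are computed over non-missing alleles only (the standard
allele-frequency convention; the high-frequency load uses a strict
> 0.9 threshold). The per-individual table also reports callable class
sites per individual (`n_callable`) for optional normalization when
missingness differs among individuals.

## Purging contrasts

Three complementary signals are computed:

1. **Percent reduction** per class,
   `100 (n_ref − n_focal) / n_ref`, against the large reference
   population, with the synonymous baseline showing how much reduction
   drift alone produces. The identity
   `n_ref (1 − pr/100) = n_focal` is asserted rather than any
   antisymmetry (the percentage is not antisymmetric under swapping
   the roles).
2. **GERP profile** of the derived alleles present in a population:
   mean score and proportion > 4. Each site with at least one derived
   copy contributes once (set semantics); the frequency-weighted
   variant is behind a flag, since "the average deleteriousness of
   derived alleles" is ambiguous between the two and the unweighted
   set is the more conservative comparison across populations of very
   different frequency spectra.
3. **Nonparametric tests**, all two-tailed, no multiple-testing
   correction: pairwise Wilcoxon on per-individual raw masked/realized
   counts, Kruskal–Wallis and pairwise Kolmogorov–Smirnov on GERP
   score distributions, and χ² (no continuity correction, df =
   groups − 1) on above/below-threshold counts.

## ROH, F_ROH and recent Ne

F<sub>ROH</sub> is the fraction of the callable genome in merged ROHs
of length ≥ 1 Mb with P(ROH) > 0.9. Interval input is BED-like
(0-based half-open) with a posterior column, matching external HMM
callers; the built-in `call_roh_windows()` is an explicitly simplified
stand-in (fixed windows, het-count threshold, adjacent ROH windows
merged) for workflows without such a caller. Merging collapses only
strictly overlapping intervals; abutting tracts remain distinct ROHs,
which matters when tract counts per length class are interpreted.

The recent-Ne reconstruction composes two closed forms with no hidden
transforms: the recombination-clock age of an ROH of length `L` Mb,
`g = 100/(2 r L)` with r = 2.8 cM/Mb (the chicken map — the closest
available estimate for reptiles lacking a species map) and a
generation time of 2 years for the year scale; and the inversion of
`F_ROH,t = 1 − (1 − 1/(2 Ne))^t` at `t = g(L)`,
`Ne = 1/(2(1 − (1 − F)^{1/t}))`. Genome fractions per ROH length bin
are averaged over the individuals of a population. Default bins are
[1, 4), [4, 16), [16, 64) Mb (geometric spacing matches the 1/L age
clock; the exact binning is a user choice), and each bin's
representative length is the geometric mean of its bounds — again
because age is inverse in L, so the geometric mean is the natural
midpoint; an arithmetic-midpoint option exists. Bins with zero
fraction are reported as undetermined (`NA`) rather than an infinite
Ne.

Numerically, `ne_from_froh()` evaluates `1/(2·(−expm1(log(1−F)/t)))`;
when F is within rounding distance of 1 the complement can be supplied
directly (`froh_survival()` produces it at full precision), which is
what the forward/inverse round-trip test uses to reach 10⁻⁹ relative
accuracy across Ne ∈ {2, …, 10⁴}.

## Diversity summaries and the tree

Heterozygosity is het count over non-missing called sites — the
denominator must include invariant callable sites, which is why the
reader preserves them. SNP counts per population require both alleles
observed within that population. Site thinning is greedy
left-to-right at 50 kb. The pairwise distance is 1 − IBS (the
allele-sharing proportion, `2 − |g_i − g_j|` shared alleles per
jointly-called site), the conventional individual-pair distance of
standard population-genetics toolkits; a Hamming alternative is behind
a flag. Neighbor joining is implemented in the package with two
determinism contracts the usual library routines do not make: Q-matrix
ties break to the lowest index pair, and negative branch lengths are
clamped to zero with the deficit moved to the sister branch so the
pair's length sum is preserved. On additive matrices the tests require
exact recovery of topology and branch lengths, and cross-check the
topology against an independent NJ implementation.

## What the generator emulates — and what it does not

`simulate_dataset()` reproduces the statistical skeleton of a
three-population island contrast: per-population derived-allele
frequencies from a symmetric Beta parameterized so that
E[2q(1−q)] hits a target per-site heterozygosity θ (defaults
2×10⁻⁴ : 8×10⁻³ : 0.28, the 1 : 40 : 1400 regime of a tiny islet, a
small islet and a large diverse population, scaled to desk-sized site
counts); Hardy–Weinberg genotypes outside planted ROH tracts and
forced homozygosity inside them; outgroups fixed ancestral except at a
known per-species substitution fraction (2 % by default); effect
classes at 45/45/5/5 % synonymous/missense/nonsense/other with
Gaussian GERP scores (means −0.87, 1.9, 2.3, 0; sd 1.5 — reproducing
the canonical ordering of class constraint); and Poisson(20) depths
with passing quality annotations. Every draw is recorded in a truth
table, and identical config + seed yields byte-identical files.

`simulate_purging_pair()` adds the selective dynamics: unlinked sites
per class evolve by deterministic recessive selection
(fitnesses 1, 1, 1 − s; `q' = q(1 − sq)/(1 − sq²)`, with the fixed
lethal limit mapped to 0) followed by binomial drift, in a large
reference (2N = 1000) and a small focal population (2N = 50) split
from shared Beta(0.5, 5) initial frequencies, for 100 generations.
Selection defaults s = 0 / 0.05 / 0.3 for synonymous / missense /
nonsense: moderate and strong recessive effects at the scale where a
bottleneck of tens of individuals exposes homozygotes within ~100
generations. A desk power check at design time confirmed the
rank-order signal (nonsense reduction > missense reduction) is
detectable at 1000 sites per class before these values were frozen.

The constant-Ne ROH generator (`simulate_roh_coalescent()`) draws a
renewal sequence of IBD segments whose point-wise coalescence-age
marginal is exactly Geometric(1/(2Ne)) — ages are drawn size-biased
(`T = G₁ + G₂ − 1`) precisely so the genome-fraction-weighted age law
is `P(age ≤ t) = 1 − (1 − 1/(2Ne))^t`, the model the estimator
inverts — and whose lengths are the recombination-clock expectation
100/(2rT) Mb. Tract-length dispersion around that expectation is
deliberately not modelled: it is what keeps the estimator's
length-to-age mapping identifiable at desk scale, while real data add
caller- and mutation-dependent blurring no small generator reproduces.

These choices mean passing tests demonstrate *internal consistency
and correctness of the estimators under their own assumptions*: sites
are unlinked (no LD except the explicitly planted ROHs), allele
frequencies are Beta rather than coalescent, annotation classes are
independent of frequency, and outgroup error is a simple fixed
substitution rate. They do not demonstrate robustness to reference
bias, genotyping error correlated with depth, linked selection, or
HMM-caller idiosyncrasies on real sequencing data.

## Problem sizes and runtime

The shipped tests use 1 500–20 000 sites, 8 individuals per
population, 50 Mb–3 Gb-scaled genomes (3×10⁸ bp per replicate for the
Ne recovery), 200 Wright–Fisher replicates for the purging rank-order
check and 50 for the neutral control — sizes chosen so the full suite
and the acceptance script each finish in minutes on a single core
while keeping every stochastic check comfortably powered.

## Known limitations

- No dominance- or selection-weighted load model: counts are proxies,
  as in the load literature the package follows.
- The window ROH caller has window-resolution boundary error
  (≤ 1 window per edge by construction; the tests quantify it) and no
  posterior model — use an external HMM caller for real data.
- Polarization supports exactly two outgroup species and no
  probabilistic ancestral-state reconstruction.
- The pipeline treats chromosomes as autosomes; sex chromosomes should
  be excluded via `excluded_chromosomes`.
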