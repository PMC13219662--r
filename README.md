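# loadscape

Conservation-genomics toolkit for quantifying the genetic load of
small, inbred populations from multi-sample genotype data, built for
study designs that contrast tiny island(-like) populations with a
large, diverse sister population and two outgroup species.

## What it computes

Starting from an already-called multi-sample VCF (biallelic SNPs,
indels and invariant sites), a sample-to-population table, per-site
effect annotations and per-site GERP conservation scores, the package:

- **Filters** sites and genotypes with GATK-style hard thresholds
  (QUAL < 60, QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < −20,
  ReadPosRankSum < −8; GQ/RGQ < 10 and per-sample depth outside
  (mean/3, 2·mean) mask single genotypes; SNPs within 5 bp of a
  high-quality indel and sites with > 25 % missing data are dropped).
- **Polarizes** alleles into ancestral/derived states using two
  outgroup species: the ancestral allele must be carried homozygously
  by ≥ 3 of 4 distant-outgroup individuals *and* all near-outgroup
  individuals; sites with any heterozygous outgroup are discarded, and
  analyzable sites must segregate (≥ 1 derived copy, not fixed) in the
  pooled ingroup.
- **Partitions the genetic load** per individual and mutation class
  (synonymous baseline, missense, nonsense, GERP > 4, and their
  combinations) into the **masked load** — the number of heterozygous
  genotypes, hidden from selection under recessivity — and the
  **realized load** — the number of homozygous-derived genotypes, with
  the bookkeeping identity `derived = masked + 2 × realized`; at the
  population level it counts derived alleles at high frequency
  (> 0.9) and total derived alleles per class.
- **Tests for purging** via the class-wise percent reduction
  `100 · (n_ref − n_focal)/n_ref` of derived-allele totals between a
  large reference and a small focal population, population GERP-score
  profiles (mean score, proportion > 4), and two-tailed Wilcoxon,
  Kruskal–Wallis, Kolmogorov–Smirnov and χ² tests (no
  multiple-testing correction).
- **Measures inbreeding and recent demography from ROHs**:
  F<sub>ROH</sub> (genome fraction in runs of homozygosity ≥ 1 Mb at
  P(ROH) > 0.9), ROH length-class fractions, the recombination-clock
  age of an ROH of length `L` Mb, `g = 100/(2 r L)` (default
  r = 2.8 cM/Mb), and epoch-wise effective population sizes by
  inverting `F_ROH,t = 1 − (1 − 1/(2 Ne))^t`. A deterministic
  window-based ROH caller is provided as a stand-in for external HMM
  callers, whose interval tables are also accepted.
- **Summarizes diversity**: per-individual heterozygosity over callable
  sites, per-population biallelic SNP counts (also for arbitrary
  subregions such as MHC loci), 50-kb site thinning, pairwise
  1 − IBS (allele-sharing) distances, and a deterministic
  neighbor-joining tree.
- **Simulates** fully labelled synthetic datasets with the same
  statistical structure (three ingroup populations in a 1 : 40 : 1400
  diversity ratio, outgroups fixed for the ancestral allele except at a
  known fraction of sites, class-dependent GERP scores, planted ROH
  tracts, and a forward Wright–Fisher purging scenario with recessive
  selection), so the entire pipeline is testable without external data.

All user-facing functions take/return tibbles and compose with the
pipe; results have `tidy()`/`glance()` methods and `plot_*()`/
`autoplot()` helpers. `run_pipeline()` orchestrates the full analysis
from a YAML config with plain-file handoff between stages.

## Worked example

```r
library(loadscape)
library(dplyr)

cfg <- sim_config(seed = 42, n_sites = 5000)
sim <- simulate_dataset(cfg, dir = tempfile())

gm       <- read_genotypes(sim$paths$vcf, sim$paths$populations)
filtered <- apply_site_filters(gm)
pol      <- polarize_dataset(filtered$matrix, sim$outgroups,
                             c("LC", "ST", "SI"))
polarization_summary(pol)
#>   status                      n
#> 1 discarded_fixed_derived   113
#> 2 discarded_no_consensus    163
#> 3 discarded_no_derived     1103
#> 4 polarized                3621

ann      <- annotate_polarized(pol, read_annotations(sim$paths$annotations))
load_ind <- individual_load(ann, filtered$matrix)
load_ind |>
  filter(class == "missense") |>
  group_by(population) |>
  summarise(masked = mean(masked), realized = mean(realized))
#>   population masked realized
#> 1 LC           0.25     783.
#> 2 SI         509.       576
#> 3 ST           7.5      792.
```

Of 5000 simulated sites, 3621 are analyzable after polarization (the
rest carry no derived allele in the ingroup, are fixed derived, or
lack an outgroup consensus). The load table shows the decoupling this
package is built to expose: the tiny `LC` population holds ~2000×
less masked (heterozygous) missense load than the large `SI`
population, while its realized (homozygous-derived) load is *higher* —
drift and inbreeding have converted segregating variation into
expressed load. The purging contrast on the same run:

```r
totals <- derived_allele_totals(ann)
percent_reduction(totals, "SI", "LC") |>
  select(class, total_reference, total_focal, percent_reduction)
#>   class              total_reference total_focal percent_reduction
#> 1 synonymous                   13352       13127              1.69
#> 2 missense                     13286       12526              5.72
#> 3 nonsense                      1171        1264             -7.94
#> 4 high_gerp                     1264        1120             11.4
#> 5 high_gerp_missense           1109          992             10.6
#> 6 high_gerp_nonsense            155          128              17.4
```

Reductions are measured against the synonymous baseline (1.69 % here,
attributable to drift alone); classes losing clearly more than the
baseline in the small population are candidates for purging. Single
small-dataset draws are noisy (the negative nonsense value above);
`simulate_purging_pair()` provides the replicated forward-simulation
version of this contrast with known selection coefficients.

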