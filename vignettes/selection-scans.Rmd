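---
title: "Haplotype-based selection scans with tropiscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based selection scans with tropiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropiscan)
library(dplyr)
```

## The scientific setting

tropiscan targets a recurring design in livestock population genomics: a
*derived* population (for instance a tropically adapted descendant of a
European breed) is compared with its *founder* population to locate genomic
regions carrying signatures of recent positive selection, while a second
*control* population of the same stock is used to discard signals that
predate the split, and a distant *donor* population (for instance a zebu
breed) may have contributed a few percent of the derived genome through
recent admixture. The pipeline covers four layers:

1. **Panel handling** — phased biallelic haplotype matrices read from VCF,
   with the standard site filters (missingness, minor allele frequency),
   naive frequency-based imputation, polymorphism-sharing summaries and
   per-individual heterozygosity.
2. **Windowed diversity and differentiation** — Watterson's
   $\theta_w$ and Hudson's $F_{ST}$ in consecutive non-overlapping windows
   (30 kb by default), with per-site sample-size corrections so missing
   data are handled without discarding sites.
3. **Haplotype-homozygosity scans** — EHH, EHHS and their integrals iHH and
   iES; the within-population iHS scan and the cross-population Rsb scan;
   a genome-wide label-permutation significance procedure; top-window
   selection; and exclusion of intervals shared with the control
   comparison.
4. **Candidate annotation** — donor-ancestry dosage summaries and a
   rank-based enrichment test, allele frequencies and fixation flags,
   gene-model consequence classification, and PWM-based prediction of
   transcription-factor-binding-site (TFBS) alteration.

Every stage is exercised on synthetic data with exact ground truth; the
generator is a first-class, tested module.

## Statistics

### EHH, EHHS, iHH, iES

For the carriers of one allele at a core SNP, the extended haplotype
homozygosity over the inclusive marker span from the core to marker $t$ is
the unbiased probability that two distinct carrier haplotypes are identical
over the span:

$$\mathrm{EHH}(t) \;=\; \frac{\sum_k n_k (n_k - 1)}{n_c (n_c - 1)},$$

where the $n_k$ are the multiplicities of the distinct carrier haplotype
strings and $n_c$ the carrier count. The site statistic EHHS pools both
alleles and renormalizes by the core-site homozygosity, so every curve
starts at 1; both are non-increasing because extending the span can only
refine the haplotype partition. Curves are truncated at the last marker at
or above a cutoff (default 0.05) or at the chromosome edge; iHH and iES are
the trapezoid areas of the two sides over physical distance, counting only
markers at or above the cutoff. A side that reaches the chromosome edge
while still above the cutoff is *edge-censored* and the integral is
reported NA rather than a biased partial area. The kernel is compiled
(C++): the permutation procedure re-runs the full genome scan dozens of
times and an interpreted implementation would dominate the runtime.

These are the "Tang-style" unbiased-pair-count forms. They admit an exact
brute-force oracle (materialize substrings, count identical pairs), which
the test suite runs on hundreds of random panels; the optimized kernel must
agree exactly, not approximately.

### Rsb and iHS

The cross-population score at SNP $s$ is
$\ln R(s) = \ln(\mathrm{iES}_{\mathrm{focal}}(s)/\mathrm{iES}_{\mathrm{ref}}(s))$,
standardized as $\mathrm{Rsb} = (\ln R - \mathrm{median}(\ln R))/\mathrm{SD}(\ln R)$.
Median-centring is the default because a genuine sweep tail drags the mean;
mean-centring is available. Positive Rsb means longer haplotype
homozygosity in the focal population — the side of the comparison where
recent selection specific to that population shows up. iHS is the
analogous within-population ratio of ancestral to derived iHH, standardized
within derived-allele-frequency bins (width 0.05, bins under 10 SNPs merged
with a neighbour). The ancestral allele defaults to REF; no polarization
beyond that is attempted.

### The permutation significance procedure

Per-SNP p-values come from reassigning *individuals* (both haplotypes
together, preserving phase) to two groups of the original sizes,
recomputing the scan genome-wide, and counting permutations whose statistic
at the same SNP is at least the observed one. This corrects for the
locally varying level of linkage disequilibrium that inflates raw scores
in some regions.

Two designs here deserve explanation:

* **Compared statistic.** Both the raw $\ln R$ and the standardized Rsb
  are exchangeable under label permutation, so either gives a calibrated
  null. They differ in power: the standardized score divides by each
  scan's own SD, and when real sweeps inflate the observed scan's SD the
  cross-scan comparison becomes conservative exactly at the sweep centres
  (in our simulations, centre-window p-values of 0.10–0.15 where the raw
  comparison gives 0). The raw $\ln R$ is therefore the default
  (`statistic = "lnr"`); the standardized variant is one option away.
* **Window-level behaviour.** Windows are scored by their maximum-Rsb SNP
  and retained when that SNP's permutation p is below $\alpha$ among the
  top-$N$ positive windows. Because the scoring SNP is a within-window
  maximum, its p-value is *not* uniform under the null: in panmictic
  simulations roughly 20% of windows are retained at $\alpha = 0.05$, even
  though the per-SNP p-values are exactly calibrated. This is a property
  of the procedure, not a defect of the implementation, and it is why the
  control-pair exclusion step matters: shared drift and this selection
  effect produce overlapping interval sets in both comparisons, and only
  signals exclusive to the focal comparison survive. The acceptance suite
  checks the window-level count against the procedure's own null rate,
  estimated by treating each permutation in turn as the observed scan
  (leave-one-out), which is exact under exchangeability.

The top-$N$ restriction is part of the procedure: at full scale one takes
a few thousand windows out of tens of thousands (a few percent). At the
simulated desk scale we use `top_n = 60` of ~666 windows (~9%) — the same
order of restriction; taking *all* positive windows instead lets the
control comparison's false retentions blanket the genome and erase true
sweeps through the exclusion step.

### Windowed diversity and differentiation

Watterson's estimator per window is
$\theta_w = \sum_s 1/a(n_s) \,/\, L$ over segregating sites $s$, with
$a(n) = \sum_{i=1}^{n-1} 1/i$ evaluated at each site's non-missing
haplotype count $n_s$ — the per-site correction that makes missing data
tolerable without dropping sites. $L$ is the full window length by
default; a callable-length vector can be supplied (both conventions are
defensible and the choice is exposed).

Hudson's $F_{ST}$ is computed as a ratio of sums across sites,
$\sum_s \mathrm{num}_s / \sum_s \mathrm{den}_s$ with
$\mathrm{num}_s = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$
and $\mathrm{den}_s = p_1(1-p_2) + p_2(1-p_1)$; it is robust to unequal
sample sizes and is the default (a Weir–Cockerham variant is available).
Under the Balding–Nichols model at divergence $F$ the estimator's
expectation is $F$ itself, which the acceptance suite verifies at
$F = 0.05$ with 50,000 sites.

### Ancestry enrichment and annotation

Donor-ancestry dosages (0–2 per SNP per individual, ELAI-style) are
summarized as window, individual and chromosome fractions (dosage/2). The
enrichment test comparing selected versus control windows is a one-sided
Mann–Whitney/Wilcoxon rank-sum test: exact enumeration over all
assignments of the observed values for group sizes up to 8 (correct under
ties, and verifiable against base R's `wilcox.test` in the untied case),
normal approximation with tie and continuity corrections otherwise. A
fully tied comparison carries no evidence and returns p = 0.5 by
convention.

Consequence classification is strand-aware against GFF3 gene models
(labels: upstream, utr5, utr3, splice_region, synonymous, missense,
intronic, intergenic). The upstream window is 5 kb (not a universal
standard; exposed as a parameter), splice regions are the terminal 2
exonic / 8 intronic bases of internal exon boundaries, and coding status
uses the standard genetic code on the CDS-projected codon. A change that
creates a stop codon is reported as missense — the label set deliberately
stays coarse, and the CDS partition property (every coding SNP is exactly
synonymous or missense) is enumerated exhaustively in the tests. SNPs may
carry several labels across transcripts; all are reported.

TFBS alteration calls scan every PWM window overlapping the SNP on both
strands, for both alleles. An allele is a hit when its best log-odds score
reaches `min + 0.8 (max - min)` of the PWM's attainable range (the
patser-style relative-score convention; the threshold is exposed because
published "custom script" thresholds are rarely stated). Calls are loss
(ref hit only), gain (alt hit only), change (both hit, score delta above a
threshold, default any difference) or none. PWM counts take a +1
pseudocount per cell; matrices already normalized to probabilities are
accepted unchanged; background defaults to uniform.

## The synthetic-data generator

`simulate_panel()` builds phased panels with controlled population
structure:

* **Shared ancestral pool.** One pool of founder haplotypes (default 24)
  is drawn from ancestral frequencies (uniform on 0.05–0.95). Each
  population's founder pool is this shared pool with *coherent* site-wise
  allele flips that move its marginal frequencies to Balding–Nichols
  draws around the ancestral value. Sister populations therefore share
  most haplotype block structure — the property that makes the
  label-permutation null meaningful. (An earlier design drew each
  population's founders independently; it matched the frequency targets
  but gave sister populations unrelated haplotypes, and the permutation
  null became wildly anti-conservative at the window level.)
* **Calibration.** The flips add measurable drift; the generator
  compensates with two fixed empirical constants (≈0.55/K extra drift at
  small F, a ×1.28 scale at donor-level F), so realized pairwise
  $F_{ST}$ lands near the targets: 0.045–0.055 for the taurine-like
  pairs (target 0.05) and ≈0.27 for taurine–donor (target 0.25).
* **Diversity contrast.** Population-private polymorphic sites are added
  with per-population weights; the donor's private sites rival the shared
  ones in number (as donor-exclusive SNP counts do in real data), giving
  donor $\theta$ about 1.7–2× the taurine level and the introgressed
  hybrid an intermediate value.
* **LD scale.** Sample haplotypes copy founders in blocks with
  exponential lengths (mean 20 kb default), producing EHHS decay on that
  scale.
* **Sweeps.** `implant_sweep()` overwrites the tract `locus ± tract/2` in
  a fraction β of haplotypes with one favored haplotype (hard) or several
  (soft). β = 0.9 and 500 kb tracts are the default study condition for
  power experiments. This creates the homozygosity signal without
  simulating selection dynamics, which is all the scan consumes.
* **Introgression.** Per recipient haplotype, non-overlapping tracts with
  exponential lengths (mean 150 kb in the studies here) are copied from
  random donor haplotypes until an individual-specific Beta-distributed
  target fraction is met; the drawn targets are rescaled so their mean is
  exactly the configured genome fraction (default 0.06, the middle of the
  4–8% range such studies report), and the final tract is trimmed to hit
  the target. Truth tracts and the exact per-SNP dosage matrix are
  recorded. `focus_intervals`/`focus_frac` concentrate tracts in chosen
  regions (used to build the enrichment-positive condition).

What the generator does **not** emulate: coalescent genealogies and
recombination-map heterogeneity, mutation-rate variation, genotyping
error, reference bias, and realistic SNP density (we simulate ~0.2–1
SNP/kb against ~16/kb in real whole-genome data). Passing tests therefore
demonstrate the statistical machinery's correctness and calibration under
a controlled haplotype-copying model, not performance guarantees on any
particular real dataset.

## Problem sizes used by the tests and the acceptance script

Simulation checks run at desk scale, chosen so the whole suite completes
in minutes on one core: oracle equivalence on 200 random panels (≤20
haplotypes, ≤50 sites); $F_{ST}$ recovery on 50,000 Balding–Nichols sites
with 15+12 diploids; null calibration on a panmictic 27-individual pool
split 15/12 over 2,000 SNPs (10 Mb at 0.2 SNP/kb) with 50 permutations;
power and exclusivity on 20 Mb genomes (0.4 SNP/kb) with three focal-only
sweeps and one shared sweep, 20 permutations and `top_n = 60`, 20
replicates in the test suite (8 in the acceptance script); enrichment and
recovery on 8 Mb two-population genomes, 20 (tests) or 10 (script)
replicates.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(
  chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
  pop_sizes = c(focal = 12, founder = 15, control = 15, donor = 10),
  sweeps = tibble::tibble(pop = "focal", chrom = "chr1", locus = 2.5e6,
                          beta = 0.9, tract_bp = 5e5),
  introgression = list(donor = "donor", recipient = "focal",
                       genome_fraction = 0.06, mean_tract_bp = 1.5e5),
  seed = 42
)
study <- simulate_study(cfg)
grid <- make_window_grid(cfg$chrom_lengths)

focal <- panel_pop(study$panel, "focal")
founder <- panel_pop(study$panel, "founder")
scan <- permute_rsb_pvalues(focal, founder, n_perm = 100, seed = 43)
cand <- select_candidate_windows(scan, grid, top_n = 60, alpha = 0.05)
glance(cand)
autoplot(cand)

wf <- window_donor_fraction(study$truth$dosage, grid)
enrichment_wilcoxon(wf$donor_fraction, cand$retained)
```

## Known limitations

* The permutation null assumes exchangeable individuals; with real
  population structure the per-SNP p-values absorb drift differences, and
  window-level retention rates well above α are expected (hence the
  control-pair exclusion step).
* Physical distance only; no genetic-map integration, no XP-EHH/nSL.
* The naive imputer is a frequency sampler, suitable for making panels
  complete before EHH computation, not a substitute for statistical
  phasing/imputation accuracy.
* Only the JASPAR pfm dialect is parsed; other PWM collections must be
  converted to it.
* Interval bookkeeping is 1-based inclusive internally; BED exports are
  0-based half-open.
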