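---
title: "Calibrated occupancy and competitive fitness: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated occupancy and competitive fitness: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesr)
library(tibble)
```

cohesr quantifies three kinds of measurement that recur in studies of
sister-chromatid cohesion in budding yeast: spike-in calibrated ChIP-seq
occupancy, competitive fitness from flow-cytometry competition assays, and
precocious sister-separation proportions from scored metaphase cells. This
vignette explains the underlying models, the parameters that matter, and the
design decisions taken where more than one reasonable convention exists.

## Spike-in calibrated ChIP-seq

### The calibration model

Ordinary ChIP-seq tracks are only internally comparable: immunoprecipitation
efficiency varies between samples, so read depth alone cannot say whether a
protein's chromosomal occupancy went up or down between conditions. Spike-in
calibration fixes this by mixing a constant quantity of a second species'
cells (here playing the role of *C. glabrata* added to *S. cerevisiae*
cultures, 1 part in 4) into every sample before crosslinking. Both the
whole-cell extract (WCE) and the immunoprecipitated (IP) libraries then
contain reads from both genomes, and four counts summarise each sample pair:

| count | sample | genome |
|-------|--------|--------|
| `Wc`  | WCE    | calibration |
| `Wx`  | WCE    | experimental |
| `IPc` | IP     | calibration |
| `IPx` | IP     | experimental |

The occupancy ratio is

$$OR = \frac{W_c \cdot IP_x}{W_x \cdot IP_c},$$

the IP yield of the experimental genome relative to the spike-in, normalised
by the actual mixing proportion observed in the WCE. Multiplying a raw depth
track by $OR \times 10^6 / N$ puts tracks from different samples on a common,
quantitatively comparable scale.

Two conventions here were genuinely open and are worth stating:

* **Orientation.** The ratio could be written either way up. cohesr uses the
  orientation in which more experimental IP signal (relative to spike-in)
  gives a larger OR, which is the natural reading of "calibrated occupancy";
  `occupancy_ratio(..., invert = TRUE)` provides the reciprocal for
  compatibility with pipelines that define it the other way.
* **The "per 1 million reads" denominator.** The track being scaled is built
  exclusively from IP reads that aligned to the experimental genome, so
  `total_reads` is taken to be `IPx` rather than the whole library size.
  Any other positive denominator can be passed explicitly.

### Read partitioning

Reads are assigned by the sequential two-genome strategy: align to the
calibration genome first, keep the leftovers, align those to the experimental
genome. cohesr reproduces this with *exact full-length matching on either
strand* (`assign_read()`, `partition_reads()`) rather than a mismatch-tolerant
aligner. At desk scale this keeps the behaviour provable — every synthetic
read has exactly one correct answer — and the sequential precedence (a read
present in both genomes counts as calibration) is encoded exactly. Positional
trimming (`trim_reads()`) implements the fixed rule used before alignment:
drop the first 10 bases, truncate after base 200, discard trimmed reads
shorter than 50 bases. Adaptive per-base-content trimming is a manual QC
judgement and is deliberately not automated.

Externally aligned data enters through `load_alignment_counts()`, which reads
the SAM text subset (primary records only, unmapped flag respected) and
tallies the same four counts by reference name.

### Tracks, meta-profiles and occupancy change

`pileup()` builds dense per-base depth (1-based inclusive coordinates, the
mpileup convention); `fill_gaps()` densifies a sparse pileup by writing an
explicit zero at every unlisted position, conserving total depth.
`meta_profile()` averages depth at each signed offset (up to ±60 kb by
default) from per-chromosome anchor points — the midpoints of the centromeric
CDEIII elements — and applies the OR / per-million calibration to the
averaged profile. Two boundary conventions are used and reported rather than
hidden:

* an offset that falls outside a chromosome simply loses that chromosome's
  contribution, and the mean is over contributing chromosomes only;
  `n_contributing` records the divisor at every offset so truncation is
  auditable;
* the anchor of an annotated element (~25 bp for CDEIII) is its midpoint
  base, computed from BED input by `read_anchors_bed()`.

`chromosome_median()` takes the median calibrated occupancy over *all*
positions of a chromosome, zeros included (even-length medians are the mean
of the two central values), and `occupancy_change()` compares two conditions
as per-chromosome ratios of those medians, summarised genome-wide by the
median of the ratios. A chromosome with zero median in the reference
condition yields an explicit `NA` ratio rather than an arbitrary value.

## The synthetic-data generator

Real sequencing data for this design is genome-scale; the generator instead
emulates the *structure* of the experiment at desk scale with exact ground
truth, so every pipeline stage is testable end to end.

* `gen_genome_pair()` draws random genomes (default two chromosomes of
  20 kb per species, read length 190 bases — the typical average read length
  of the single-end libraries this models) and certifies by a k-mer audit
  that no read-length subsequence is shared between species on either
  strand. Cross-species ambiguity is thereby eliminated *by construction*;
  the precedence rule for genuinely ambiguous reads is tested separately
  with hand-built genomes.
* `sample_experiment()` draws WCE reads uniformly with calibration-species
  probability 0.25 (the 3:1 mixing proportion) and IP reads from an
  `occupancy_landscape()` — baseline plus Gaussian peaks — with the IP
  calibration share governed by `ip_calibration_efficiency` ($\kappa$), the
  pull-down propensity of the spike-in species relative to one unit of
  landscape weight. The relative pull-down efficiency of the spike-in
  species is not measurable from published data, so $\kappa$ is a free
  simulation parameter (default 1). Under this model the analytic
  expectation of the OR is simply $\bar{w}/\kappa$, the mean landscape
  weight over valid start positions divided by $\kappa$; it is recorded in
  `truth$true_or` *before* sampling, and the count-based OR converges to it
  (within ±5% at $2\times10^5$ reads per sample in the acceptance suite).
* Reads are unstranded (both strands with equal probability) and error-free:
  there is no sequencing-error, quality or PCR-duplicate model. Passing
  tests therefore demonstrate correctness of the quantification given exact
  alignment, not robustness to base-calling noise or mapping ambiguity —
  those belong to the upstream aligner in real use.

`gen_competition()` inverts the fitness model below (deterministic totals,
binomial fluorescent/non-fluorescent split — the minimal counting-noise model
for cytometry, since no richer noise model is implied by the assay), and
`gen_cytology()` draws Bernoulli scored-cell tables.

## Competitive fitness from flow cytometry

Two strains carrying different fluorophores are co-cultured, diluted 1:1000
into fresh medium every 24 h, and sampled by flow cytometry at every passage.
With $r = \mathrm{nonfluorescent}/\mathrm{fluorescent}$ events and
generations per interval $g = \log_{10}(\mathrm{events}_{t24} /
\mathrm{events}_{t0}) / \log_{10} 2$, relative fitness is the ordinary
least-squares slope of $\log_e r$ against cumulative generations.

Conventions adopted where the procedure leaves room:

* **The regression abscissa is cumulative generations**, per-interval $g$
  summed from the day-0 sample (which defines $G = 0$; the pre-mixing growth
  period is excluded). Selection acts per generation, so the log-ratio is
  linear in accumulated generations, not in passage index.
* **$g$ uses total events of the mixed culture**, not genotype-specific
  counts.
* **Zero event counts abort** (`genotype_ratio()` raises an error advising
  deeper sampling) rather than being pseudo-counted; no smoothing rule is
  defensible without a stated convention.
* All provided passages enter the regression; `competition_points()` exposes
  the exact points so a subset can be refitted if desired.

Fluorophore expression itself can carry a fitness cost, so the slope
measured between isogenic strains carrying the two fluorophores is
subtracted from comparisons involving them (`correct_fitness()`). Replicate
summaries use the sample standard deviation over at least three biological
replicates (`summarize_replicates()` warns below three), and strain
comparisons use Welch's unequal-variance two-sided t test (`welch_test()`,
delegating to `stats::t.test`). No multiple-testing correction is applied:
the assay reports single pairwise comparisons.

## Cytology proportions

`percent_precocious()` converts scored-cell tables (metaphase cells with one
vs two GFP dots at a marked locus) into percentages. The 95% Wilson score
interval is attached as an uncertainty extension — such scoring is usually
reported as a bare proportion — and `compare_strains()` offers a two-sided
Fisher exact test on the 2×2 counts, likewise labelled an extension.

## Numerical and scale choices

Simulations in the test suite run at desk scale chosen so that every
stochastic check has comfortable statistical margin: genome pairs of
2 × 20 kb per species with 190-base reads; $2\times10^5$ reads per sample
for occupancy-ratio recovery (binomial theory puts the OR's relative
standard error near 0.7% there, against the ±5% acceptance band); $6\times
10^4$ reads per condition for the two-fold eviction recovery; 200 simulated
competition series per selection coefficient at 30 000 events per sampling;
2000 null simulations for the Welch type-I rate. Meta-profile code is
checked exactly against a brute-force double loop on 1000 random toy
fixtures (scaled values to $10^{-12}$ relative). All generators take an
explicit integer seed and are byte-identical under it.

Known limitations: exact matching cannot model mismatch-tolerant alignment
of real reads; the binomial cytometry noise model ignores instrument
carryover and gating error; landscape peaks are Gaussian, which is a
convenience, not a claim about real cohesin peak shape; and the genome-wide
occupancy-change summary assumes the same chromosomes are present and dense
in both conditions.
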