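---
title: "Methods: genomic signatures of psychrophily and how cryocomp computes them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic signatures of psychrophily and how cryocomp computes them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocomp)
```

`cryocomp` computes four genomic signatures used to contrast a focal group
of fungal genomes — typically psychrophiles — against a background panel.
This vignette documents the models, the parameters that matter, the
numerical conventions, and what the package's synthetic validation does and
does not establish.

## Orthogroup expansion and contraction

### Model

The input is an orthogroup-by-species matrix of gene counts, the output
format of orthology inference tools such as OrthoFinder, plus a
species-to-group assignment. Gene-family sizes differ wildly across
orthogroups, so raw counts are first placed on a common scale *per
orthogroup*: each count is converted to a standard normal deviate using the
orthogroup's trimmed mean and trimmed sample SD,

$$z_{gi} = \frac{x_{gi} - \bar{x}^{(t)}_g}{s^{(t)}_g},$$

with 25% of values removed from each tail (50% removed in total, the
"midmean"). Trimming makes the centre and spread robust to the very species
whose expansion we want to detect: a planted four-fold expansion in 11 of
52 species falls entirely in the discarded upper tail and cannot drag the
reference centre with it.

Group shift is then scored per orthogroup with a Welch-type statistic on
the normalized scores,

$$t_g = \frac{c_p - c_n}{\sqrt{s_p^2/n_p + s_n^2/n_n}},$$

where $c$, $s$, $n$ are group mean, sample SD and size for the focal ($p$)
and background ($n$) species. The statistic is used as a *ranking* score —
the 50 most positive (expanded) and 50 most negative (contracted)
orthogroups are selected — not as a hypothesis test, so no degrees of
freedom or p-values are attached. A second variant,
`t_formula = "paper_literal"`, omits the group sizes under the radical
($\sqrt{s_p^2 + s_n^2}$); it down-weights the small focal group's sampling
noise and ranks slightly differently. Both are first-class; `welch` is the
default because it is the standard form, and the variant used is recorded
in the result's metadata.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `trim_fraction_per_tail` | 0.25 | fraction trimmed per tail; 0.25 = midmean. "50% trimmed" is genuinely ambiguous between 25%-per-tail and the median; both are reachable through this parameter and the midmean reading is the default. |
| `zero_sd_policy` | `"zeros"` | orthogroups whose trimmed SD is 0 (constant middle) get all-zero scores, keeping the matrix shape stable for clustering; `"drop"` removes them. |
| `top_n` | 50 | orthogroups selected per direction. |
| `threshold` | 0.75 | per-species shift call at \|score\| > 0.75, strict. |

The per-species counts deserve a caveat: *t* is a group statistic, but
per-species expansion tallies require a per-species reading. The package's
explicit interpretation is that a species' orthogroup is shifted when its
own normalized score exceeds the threshold. Scores exactly at ±0.75 count
as neither direction.

Ties in the ranking are broken lexicographically by orthogroup id, and the
contracted list is drawn from orthogroups not already selected as expanded,
so the two lists are deterministic and disjoint even in degenerate
all-tied inputs.

### Species structure

Downstream of the scores, species are compared by the Pearson correlation
of their score vectors (optionally restricted to the top shifted
orthogroups), clustered with Ward linkage (`hclust` method `ward.D2`) on
the distance $d = 1 - r$, and ordinated by PCA of the column-centered
correlation matrix. $1 - r$ rather than $1 - |r|$ is used: anticorrelated
lifestyles should be far apart, not close. Zero-variance species get
correlation 0 with everyone and are flagged rather than dropped. PCA
component signs are fixed by making each component's largest-magnitude
loading positive, a determinism convention with no statistical content.

## Base composition

GC content is computed over unambiguous bases only — ambiguity codes and N
are excluded from numerator *and* denominator — so gap-rich assemblies are
not biased towards AT. Coding-sequence GC and GC3 are pooled over all
codons of all sequences (the codon-usage-tool convention), not averaged per
gene; a per-gene mode exists behind a flag. Trailing partial codons are
trimmed with a warning and counted, records shorter than one codon are
skipped with a warning, and stop codons are not excluded. Per-contig GC
histograms use half-open 2-percentage-point bins with a closed top bin.

Group comparisons of per-species metrics (genome size, GC, GC3, ...) use
classical one-way ANOVA plus Tukey-Kramer HSD, run per variable. A
multivariate test across the three GC variables jointly is deliberately out
of scope; per-variable ANOVA answers the questions the package asks and
keeps the output interpretable. Exactly degenerate layouts get explicit
sentinels (identical data: F = 0, p = 1; zero within-group variance with
separated means: F = Inf, p = 0), with a guard at MS~within~ <
10^-12^ x MS~between~ absorbing `aov()`'s floating-point residue.

## RIP scanning

Repeat-induced point mutation converts C to T in duplicated sequence,
preferentially at CpA dinucleotides. Three indices per window summarise the
signature: product = TpA/ApT (RIP creates TpA), substrate =
(CpA+TpG)/(ApC+GpT) (RIP consumes its substrate), composite = product −
substrate. Windows are 1000 bp at 500-bp steps; a window is RIP-positive
only when **all three** indices pass (product > 1.15, substrate < 0.75,
composite > 0, all strict). Runs of consecutive positive windows merge by
union into regions; regions strictly longer than 4000 bp are LRARs. The
genome-wide RIP percentage counts the union of positive-window bases, so
overlapping windows are never double-counted and the percentage cannot
exceed 100.

Conventions that the scanning literature leaves unstated are fixed
explicitly here: zero-denominator indices are set to 0 and the window
forced negative (conservative); contigs shorter than one window are
analyzed as a single whole-contig window and flagged `short`; trailing
partial windows on long contigs are not emitted. Because these conventions
are not published for the reference tools, exact base-level agreement with
them on real genomes should be expected to be approximate.

The configured index set is strand-symmetric — TpA and ApT are their own
reverse complements, and (CpA, TpG) and (ApC, GpT) are mutual
reverse-complement pairs — so forward-strand counting suffices; a test
asserts this invariance.

## K-mer ploidy diagnostics

Canonical k-mers (lexicographic minimum of a k-mer and its reverse
complement; odd k only, default 31) are counted over the input; windows
containing ambiguity codes are skipped. The depth histogram is smoothed
with a moving average (halfwidth 2), the initial descending flank — the
signature of sequencing-error k-mers in real spectra — is cut at its first
local minimum, strict local maxima are kept, and peaks closer than 25% of
their mean depth are merged keeping the taller.

A spectrum is *bimodal* when its two tallest peaks have a depth ratio in
[1.6, 2.4], bracketing the 2x expected between heterozygous (c/2) and
homozygous (c) k-mers in a diploid or dikaryon. Histogram bins are then
attributed to the nearest peak, giving the heterozygous distinct-k-mer
fraction f, and per-base heterozygosity is inverted from the spanning
model: a k-mer is heterozygous iff it overlaps ≥ 1 heterozygous site
(probability $1-(1-h)^k$ per window), and each such window contributes one
unique k-mer *per haplotype* while homozygous windows contribute one shared
k-mer — hence $h = 1 - (1 - f/2)^{1/k}$. This is a deliberately simple
spectrum reading in the spirit of mixture-model tools, not a replacement
for them: it is validated only against the package's own generative model
and slightly underestimates h (the f/2 correction maps to $p/(1+p)$ rather
than $p$), by about 10–15% relative at h = 1%, k = 21 — visible in the
acceptance output and inside the stated ±0.4-percentage-point band.

## The synthetic generators: what they emulate, and what they do not

All generators are pure functions of their arguments and a seed. Their
defaults *are* the package's reference validation conditions and were fixed
once, from the study design they emulate, not adjusted afterwards:

* `simulate_count_matrix()` — negative-binomial counts (variance
  $\mu + \mu^2/\theta$) for 2000 orthogroups across an 11-species focal
  group and a 41-species background (the group sizes of the motivating
  52-species comparison), baseline mean 3, dispersion 2, and 50 + 50
  planted four-fold expansions/contractions applied to the focal group's
  mean before sampling. What it omits: phylogenetic correlation between
  species, orthogroup-size heterogeneity, and presence/absence structure.
* `simulate_ripped_genome()` — i.i.d. background bases at 55% GC (the GC
  range where RIP substrate is plentiful) with two non-overlapping 8-kb
  regions passed through `rip_mutate()` at rate 0.9. `rip_mutate()` hits
  CpA (and TpG, the reverse-strand CpA) in a single pass over the original
  sequence, so mutations never cascade into newly created contexts. What it
  omits: real repeat families, RIP's processivity and flanking leakage, and
  any base composition structure beyond i.i.d.
* `simulate_cds()` — codons with uniform first/second positions and
  third-position GC pinned to a target; composition fixtures, not genes (no
  stop-codon avoidance, no codon-usage bias).
* `simulate_diploid_spectrum()` — k-mer-level diploid model: haplotype B is
  haplotype A with i.i.d. substitutions at the heterozygosity rate, each
  distinct k-mer of multiplicity m receives Poisson(m x coverage/2) depth.
  Defaults: 200-kb haplotypes, 1% heterozygosity, coverage 40, k = 21
  (k = 31 is the analysis default for real data; 21 keeps the validation
  spectra dense at this genome size). What it omits: reads, sequencing
  error (hence no real error flank at depth 1–3), and repeats.

Passing tests therefore demonstrate that the *statistics recover what the
models plant*, under clean i.i.d. noise — not that any real genome will be
as well behaved.

### Known behaviour under the reference conditions

Two honest calibration facts, both computed by the test suite and
acceptance script rather than asserted from theory:

* The null distribution of the Welch-type t under negative-binomial counts
  with unequal groups (11 vs 41) is left-skewed with mean ≈ −0.13, not 0:
  skewed counts induce correlation between a group's sample mean and SD.
* With a four-fold effect at baseline mean 3 and dispersion 2, the top-50
  lists recover a median of roughly 85% of planted expansions and ~77–80%
  of planted contractions (20 seeds); the heaviest-tailed nulls overlap the
  weakest planted signals, and contractions (mean 3 → 0.75 on small
  integers) carry less information than expansions. Detection of a planted
  signal this size is excellent but not near-perfect.

## Problem sizes

The validation suite runs entirely on simulated data sized for a single
CPU: 2000-orthogroup matrices (20 seeds), 50-kb oracle genomes (50 seeds),
200-kb RIP genomes (50 seeds), and 200-kb diploid spectra (20 seeds). These
sizes were chosen so each stochastic property is measured with usable
precision while the whole suite stays interactive; all of them scale up
linearly if a user wants tighter replication.

## Limitations

* The shift statistic ranks; it does not test. No multiple-testing
  machinery is provided, by design.
* The RIP scanner's conventions at zero denominators, short contigs and
  window unions are explicit choices; reference implementations do not
  publish theirs, so cross-tool agreement is approximate.
* The heterozygosity estimator is a one-line inversion, biased low by
  construction (documented above); use a full mixture-model tool for
  publication-grade estimates on real reads.
* Genome-size and repeat-content estimation, orthology inference itself,
  and functional annotation are out of scope: the package consumes their
  outputs.
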