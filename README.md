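# cryocomp

Comparative-genomics signatures of psychrophilic (cold-adapted) fungi, as an
R package. Rock-inhabiting fungi such as *Cryomyces* survive Antarctic
extremes, and their genomes carry detectable marks of that lifestyle:
expanded and contracted gene families, elevated GC content (especially at
third codon positions), traces of repeat-induced point mutation (RIP), and
k-mer spectra revealing unexpected diploidy or dikaryosis. `cryocomp`
implements these four analyses for anyone comparing a focal group of genomes
(psychrophiles or otherwise) against a background panel, together with
seeded synthetic-data generators so every stage can be validated against a
planted truth without downloading a single genome.

## The statistics at the core

**Orthogroup shift score.** Given an orthogroup-by-species gene-count table
(OrthoFinder `Orthogroups.GeneCount.tsv` dialect) each orthogroup's counts
are converted to standard normal deviates using that orthogroup's 50%
trimmed mean and SD (25% removed per tail, the midmean). Expansion or
contraction of the focal group *p* against the background *n* is scored with
a Welch-type t statistic on the normalized scores:

    t = (c_p − c_n) / sqrt(s_p²/n_p + s_n²/n_n)

where *c*, *s* and *n* are the group mean, SD and size. A
`t_formula = "paper_literal"` variant drops the group sizes under the
radical: `t = (c_p − c_n) / sqrt(s_p² + s_n²)`. The 50 most positive and 50
most negative orthogroups are the expansion/contraction candidates, species
are counted as shifted per orthogroup when |score| > 0.75, and species are
clustered with Ward linkage on correlation distance (d = 1 − r) of their
score vectors.

**RIP indices.** Sliding 1000-bp windows (500-bp step) are scored with the
classical dinucleotide indices: product = TpA/ApT, substrate =
(CpA+TpG)/(ApC+GpT), composite = product − substrate. A window is
RIP-positive when product > 1.15, substrate < 0.75 and composite > 0 (all
strict); runs of positive windows merge into regions, and regions longer
than 4000 bp are large RIP-affected regions (LRARs).

**Composition.** Genome GC (ambiguity codes excluded from numerator and
denominator), per-contig GC distributions, pooled coding-sequence GC and
third-codon-position GC3, plus one-way ANOVA and Tukey HSD comparisons of
any per-species metric across lifestyle groups.

**K-mer ploidy.** Canonical k-mer spectra (default k = 31), moving-average
peak detection, bimodal/unimodal calling via the het/hom peak depth ratio
(expected 2x), and a per-base heterozygosity estimate inverted from the
k-mer spanning model `h = 1 − (1 − f/2)^(1/k)` with f the heterozygous
k-mer fraction.

## Worked example

```r
library(cryocomp)

# plant 10 four-fold expansions and 10 contractions among 500 orthogroups,
# 11 focal psychrophiles vs 41 background species
sim    <- simulate_count_matrix(n_orthogroups = 500, n_expanded = 10,
                                n_contracted = 10, seed = 42)
norm   <- normalize_counts(sim$counts)
scores <- welch_t_scores(norm, sim$groups, "psychrophile")
head(rank_shifts(scores, top_n = 10), 3)
#> # A tibble: 3 × 4
#>   orthogroup     t direction  rank
#>   <chr>      <dbl> <chr>     <int>
#> 1 OG0000153   4.89 expanded      1
#> 2 OG0000500   4.59 expanded      2
#> 3 OG0000049   3.56 expanded      3
```

The t scores of the planted orthogroups (here ~3.5–4.9) stand clear of the
null bulk; 7 of the 10 planted expansions land in the top-10 list at this
small problem size.

```r
# RIP: two 8-kb repeat regions mutated at rate 0.9 inside a 200-kb genome
rip <- simulate_ripped_genome(seed = 1)
w   <- scan_rip_windows(rip$genome)
rg  <- call_rip_regions(w)
summarize_rip(rip$genome, rg$regions, rg$lrars)
#> <rip_summary>
#>   genome-wide RIP: 9.00% (18000 of 200000 bp in 2 region(s))
#>   LRARs: 2, mean composite 1.922
```

Both planted intervals (34434–42434 and 57487–65487) are recovered as
LRARs; the 9.0% estimate brackets the planted 8% because window unions
overhang the true region edges by up to one window.

```r
# diploid k-mer spectrum at 1% heterozygosity, coverage 40
sp <- simulate_diploid_spectrum(seed = 1)
glance(classify_ploidy(sp$histogram))
#> # A tibble: 1 × 5
#>   modality n_peaks het_kmer_fraction het_estimate     k
#>   <chr>      <int>             <dbl>        <dbl> <int>
#> 1 bimodal        2             0.340      0.00884    21
```

The spectrum is called bimodal with peaks at depths 20 and 39 (the het c/2
and hom c peaks) and heterozygosity is estimated at 0.88% against the
planted 1%.

`run_demo(output_dir, seed)` wires all four analyses into one deterministic
run and writes every table (normalized scores, top lists, correlation,
clusters, PCA, RIP windows/regions/LRARs, composition, k-mer histogram and
ploidy report) plus a planted-vs-recovered summary.

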