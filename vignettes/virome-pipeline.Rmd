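---
title: "Methods: from assembled viral contigs to populations, abundance, microdiversity and community structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from assembled viral contigs to populations, abundance, microdiversity and community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viropop)
```

## Scope and model of the data

`viropop` implements the downstream, post-assembly stages of a marine
virome analysis. Its inputs are the text artefacts that standard upstream
tools emit: assembled contigs (FASTA), pairwise alignments (PAF or BLAST
outfmt 6), per-base read depth (the 3-column `bedtools genomecov -d`
dialect), SNV calls (VCF with `AD` allele depths), and tabular host
evidence. Everything upstream — sequencing, assembly, virus identification,
read mapping, SNV calling — is out of scope and consumed as input.

Internally every coordinate is 0-based half-open; BLAST's 1-based inclusive
(and possibly reverse-strand) intervals are normalized on input, and
emitted BED is 0-based half-open. Percent identity is always stored as a
fraction in $[0, 1]$ to avoid $\times 100$ ambiguity between formats.

## Dereplication into viral populations

Viral contigs are dereplicated into species-rank *populations*: clusters
sharing $\ge 95\%$ average nucleotide identity (ANI) over $\ge 85\%$ of the
contig length, represented by the longest member. Two decisions here were
genuinely open and are fixed as follows:

* **Coverage denominator.** "The contig length" is ambiguous for a pair of
  unequal contigs; we measure alignment coverage on the *shorter* (member)
  contig, which matches the behaviour of the ClusterGenomes-style greedy
  tools this rule comes from.
* **Greedy, not transitive.** Contigs are sorted by length (descending,
  ties broken lexicographically by id); each unassigned contig seeds a
  population and absorbs every unassigned shorter contig that passes both
  thresholds *against the seed itself*. A contig that passes only via an
  intermediate member stays out. This matches the
  representative-selection semantics and makes the partition reproducible;
  the test suite checks it against an independent brute-force
  implementation of the same rule on hundreds of random instances.

ANI between a pair is the match-weighted mean over all their alignment
blocks, $\sum \text{matches} / \sum \text{aligned}$, which is robust to
split alignments; coverage uses the union of the aligned intervals.

**Breakage analysis.** For long-read representatives, fragmentation of
short-read assemblies is quantified by the union of member alignments on
the representative: every maximal uncovered run — terminal runs included —
counts as one breakage, and the covered percentage is reported. Counting
terminal runs keeps a simple conservation between `pct_aligned` and the
breakage count and treats an unassembled contig end the same as an
internal gap.

## Abundance and the presence rule

Reads are assumed mapped competitively and filtered to $\ge 90\%$ of read
length aligned at $\ge 95\%$ identity (both inclusive). Per-contig
abundance in a sample is **tpmean**: the mean per-base depth after
discarding positions strictly below the 5th or strictly above the 95th
percentile of the depth distribution. The percentile method is not fixed
by the statistic's name; we use nearest-rank on the sorted depth vector,
so constant tracks return the constant and single-position tracks are
well defined. Percentiles are computed per contig per sample, not pooled.

A population with **breadth** (fraction of positions covered $\ge 1\times$)
below 70% in a sample is assigned abundance exactly 0 — the presence rule
that suppresses false detections from conserved-region recruitment.
Values are then normalized per million mapped reads in the sample
("normalized by total reads"; the per-million unit is our documented
choice and is recorded in the matrix metadata). RPKM is provided for
isolate-genome screens, together with a relaxed 40% breadth cut-off, and
read sets can be subsampled to a fixed depth (default 5 million) so that
dataset size does not inflate presence calls.

## Hypervariable regions

A hypervariable region (HVR) is a maximal run of positions with depth
strictly below 20% of the *whole-contig* median (the dip itself included
in the median, as "whole contig" demands), at least 600 bp long, and
containing at least one exactly-zero position. The three criteria are
conjunctive: "zones of zero coverage" is interpreted as requiring a zero
inside the candidate region, which is the signature of a locus where the
mapped reference carries an allele absent from part of the population.
The strict `<` on the 20% threshold follows the wording "less than". The
top-N-by-abundance selection (default 50) and the thresholds are
parameters, not constants.

## Host prediction

Three independent evidence channels are combined additively per
(virus, MAG) pair:

| channel | tiers |
|---|---|
| prophage BLAST | 4: $\ge 98\%$ id and $\ge 90\%$ cov; 3: $\ge 90\%$/$\ge 75\%$; 2: $\ge 90\%$/$\ge 50\%$; 1: $\ge 90\%$/$\ge 30\%$ |
| tRNA match | 3: $= 100\%$ id; 2: $\ge 95\%$; 1: $\ge 90\%$ |
| WIsH | 2.5: $p \le 10^{-10}$; 2: $p \le 10^{-5}$ |

All thresholds are inclusive, consistent with the explicit $\ge 3$
assignment gate and $\le$ p-value bounds of the scheme. When one channel
has several rows for a pair only its best tier counts (no double
counting). Pairs totalling $\ge 3$ are putative host linkages. MAG bins
are scored `completeness - 2 * contamination` and gated at $\ge 70\%$
completeness, $\le 10\%$ contamination.

## Microdiversity ($\pi$)

SNV sites are filtered to quality $> 30$ (strict), an alternative allele
at frequency $> 1\%$ (strict) supported by $\ge 4$ reads; frequencies are
evaluated on the raw counts, before subsampling, since the filters are
defined on the called SNVs. Each surviving locus with depth $\ge 10$ is
subsampled to exactly $10\times$ by a draw without replacement from its
allele pool (multivariate hypergeometric); shallower loci are not
evaluable at the target and are excluded.

Per-site diversity uses the unbiased estimator
$$\hat\pi_s = \frac{n}{n-1}\Bigl(1 - \sum_a p_a^2\Bigr),$$
with $n = 10$ the subsampled depth and $p_a$ the subsampled allele
fractions. This equals the fraction of mismatching read pairs among the
$\binom{n}{2}$ pairs at the site (for the worked locus $\{A{:}5, C{:}5\}$,
$25/45 = 0.5\overline{5}$), and its expectation under Bernoulli read
sampling at population frequency $f$ is exactly the population
heterozygosity $2f(1-f)$ — the $n/(n-1)$ factor corrects the plug-in bias;
it does not inflate the expectation. The per-contig value averages
$\hat\pi_s$ over the *covered length* — positions with pre-subsampling
depth at least the $10\times$ target — so monomorphic covered sites
contribute zero; averaging over covered sites rather than SNV loci only
is what places genome-wide values in the $10^{-4}$ regime typical of
marine viral populations. Contigs enter the analysis only at breadth
$\ge 70\%$ and mean depth $\ge 10\times$.

Inference follows the resampling design of the field: the mean $\pi$ of a
sample group is bootstrapped (1000 replicates of 100 values drawn with
replacement, percentile 95% CI), and group differences are tested by
pooling, label shuffling and re-splitting at the original sizes, with the
two-sided add-one-corrected p-value
$p = (1 + \#\{|t^*| \ge |t|\})/(B + 1)$.

## Community ecology

Between-sample structure uses Bray–Curtis dissimilarity on cube-root
transformed abundances, PCoA by Gower double-centering of $-d^2/2$
(negative eigenvalues are reported but carry no coordinates — Bray–Curtis
is semi-metric), one-factor PERMANOVA with the standard pseudo-F and a
label-permutation null, pairwise group-centroid Euclidean distances over
the retained axes, SIMPER decomposition of between-group dissimilarity
into per-taxon fractions (ties broken by taxon id), and a bootstrap
(default $n = 10000$) percentile interval for the median number of
samples in which each population occurs. The PERMANOVA p-value includes
the observed statistic in the null set, so the smallest attainable value
at 999 permutations is exactly $0.001$ — the floor reported by
`adonis`-style software. The phrase "standard deviation and F-tests"
attached to Adonis in common usage has no separate technical meaning; only
the pseudo-F permutation test is implemented. Ordination ellipses are
presentation, available via the `plot` method, and carry no statistical
contract. The in-package implementations are cross-checked in the test
suite against `vegan::vegdist`, `stats::cmdscale`, `vegan::adonis2` and
`vegan::simper` on shared fixtures.

## The synthetic virome generator

Because none of the above needs raw reads, the package ships a generator
(`sim_config()` and the `simulate_*` functions) that produces every input
with exact ground truth:

* **Populations** are stars around a random consensus: member 1 *is* the
  consensus (full length, hence the true representative); other members
  are truncated (up to 10%) copies diverged at the configured identity
  (default 0.97). Divergence follows a shared-polymorphism model — 70% of
  a member's mutations come from a pool of segregating sites common to
  the population, 30% are private — so member-to-representative identity
  equals the configured value while member-to-member identity stays well
  above the 0.95 threshold, as in a real viral population cloud.
  Alignments are derived from the sequences themselves (exact mismatch
  counts over full overlaps), not from an external aligner, so the truth
  ANI is exact and unrelated populations share no alignment at all.
* **Coverage** is Poisson at a per-contig mean (default 40–80$\times$,
  a realistic virome recruitment depth) outside engineered dips; inside a
  dip the depth is held at the dip's floor. A zero floor produces a true
  HVR signature, a positive floor produces the zero-free decoy that the
  caller must reject; both are recorded in the truth table. Plateau dips
  make the expected call boundaries exact, which is what the recovery
  tests assert.
* **SNVs** are biallelic: site depth Poisson (default $100\times$),
  alternative count Binomial(depth, $f$). The truth records $2f(1-f)$,
  the analytic expectation of the estimator above under this read model.
* **Abundance matrices** are log-normal (sdlog 0.4 around per-taxon
  levels) with a known multiplicative group effect (default $8\times$) on
  a known taxon subset, so PERMANOVA power and SIMPER rankings have exact
  truth.

One global seed fans out to fixed per-component child seeds, so identical
configurations are bit-identical and single stages can be regenerated.

What the generator deliberately does **not** model: sequencing error and
read-level artefacts, chimeric assembly, strand or positional coverage
biases (GC, terminal drop-off), linkage between SNVs, and compositional
correlation structure between taxa. Green recovery tests therefore show
the *rules* are implemented exactly as defined, not that the rules are
robust to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Nearest-rank percentiles in `tpmean`; trimming is strict outside
  $[p_5, p_{95}]$. A constant track is its own tpmean.
* A contig with zero median depth is an error for the HVR caller (it
  should have been excluded by the presence rule upstream).
* Pairs with no alignment get ANI and coverage 0 (not an error); a pair
  of all-zero samples gets Bray–Curtis distance 0 with a warning; a
  distance matrix with all-zero dissimilarities makes pseudo-F undefined
  and errors.
* All resampling functions take an explicit `seed` and restore the
  caller's RNG state; `p`-values never return 0 thanks to the add-one
  correction.
* Clustering ties (equal lengths) are broken lexicographically by id;
  SIMPER ranking ties by taxon id.

## Problem sizes in the shipped checks

The test-suite simulations use desk-scale sizes chosen to give each check
sharp power: 200 random dereplication instances of up to 20 contigs
against the brute-force oracle; 1000 random tracks for the tpmean oracle;
a 50-population community for the presence rule; 10,000 loci per allele
frequency for $\pi$ recovery; 1000 exchangeable simulations for
permutation-test calibration; and an end-to-end demonstration
(`run_demo()`) on an 8-population, 8-sample virome that completes in a
few seconds and writes a deterministic report.

## Known limitations

* BLAST outfmt 6 carries no exact match count; `n_matches` is
  reconstructed as `round(pident/100 * length)`, exact only for gap-free
  alignments.
* The prophage-BLAST coverage denominator (viral contig vs MAG contig) is
  whatever the evidence table's producer used; the tier function consumes
  it as given.
* Read-mapping semantics of different filtering tools (e.g. BamM vs
  CoverM) are assumed equivalent at the $\ge 90\%$ length / $\ge 95\%$
  identity setting; depth files are accepted as pre-filtered.
* `read_vcf_snvs()` uses the first sample column of a VCF; multi-sample
  VCFs should be split upstream.
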