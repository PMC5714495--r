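---
title: "Methods: windowed genome scans of differentiation with divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed genome scans of differentiation with divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`divscan` implements the standard genome-scan design for a pair of
hybridizing species sampled both in allopatry and in a sympatric contact
zone — the setting of, for example, the common and Siberian chiffchaff, or
*Ficedula* flycatchers. Four populations are compared: `allo_A`, `allo_B`
(the two species where their ranges do not overlap) and `sym_A`, `sym_B`
(phenotypically assigned individuals from the contact zone, where
hybridization and backcrossing mix ancestries). The analysis asks three
questions:

1. How are SNPs partitioned into *shared*, *private* and *fixed* categories
   between the species, and how does sympatry change that partition?
2. How do diversity ($\theta_\pi$, $\theta_W$, Tajima's $D$),
   differentiation ($F_{ST}$), divergence ($D_{XY}$) and LD ($r^2$) vary
   along the genome in 10-kb windows, and how do autosomes differ from the
   Z chromosome?
3. Where are the *differentiation islands* — clustered runs of windows with
   exceptionally high standardized differentiation ($F_{ST}^Z$) — and which
   protein-coding genes and coding changes do they contain?

All inputs are standard formats: a multi-sample VCF with `GT:DP`, a
sample-to-population TSV, a genome layout TSV (chromosome, length,
autosome/Z class), a BED3 callable mask, and GFF3 + FASTA for gene models.

# Genotype filters and SNP categories

A genotype contributes to a population only when it is called and covered
by at least `min_depth = 5` reads. The **standard** profile keeps a site if
at least 7 individuals per population survive, in all four populations
simultaneously; the **strict** profile (used for fixed-difference effect
calls, where a single miscalled genotype converts a fixed difference into a
polymorphism) requires 9 individuals, in the two allopatric populations.
Polymorphism is judged on the retained genotypes: a population is
polymorphic when its retained alternate-allele count is strictly between 0
and its retained allele count. Categories are then: *fixed* (both
monomorphic for different alleles), *shared* (both polymorphic),
*private* (exactly one polymorphic), *monomorphic* (excluded from
category totals).

# Window statistics

Windows are non-overlapping 10-kb tiles per chromosome; the terminal
partial tile is kept but flagged and excluded from the outlier scan. All
per-bp quantities are normalized by the window's overlap with the callable
mask, not its nominal width, because the VCF stores variants only and the
mask defines where a monomorphic site could have been observed.

* Per-site diversity: $k(n-k)/\binom{n}{2}$ with site-specific retained
  allele count $n$ and alternate count $k$; summed and divided by callable
  bp. This equals the mean pairwise difference among the sampled alleles
  (property-tested against an $O(n^2 L)$ brute-force pair count).
* Watterson's estimator uses site-specific $n$:
  $\theta_W = \sum_{seg} 1/a_1(n_{site}) / L_{callable}$ with
  $a_1(n) = \sum_{i=1}^{n-1} 1/i$.
* Tajima's $D$ uses the classical variance constants, which require one
  fixed $n$ per window; we use the floored median retained allele count
  across the window's segregating sites. With depth ~Poisson(8) and ten
  diploids per population the retained count varies little within a
  window, so the choice is insensitive; it is documented rather than
  hidden.
* $F_{ST}$ is the Hudson-type estimator with sample-size-corrected
  numerator, aggregated as a **ratio of sums** over sites:
  $\hat F_{ST} = \sum_s \mathrm{num}_s / \sum_s \mathrm{den}_s$ with
  $\mathrm{num} = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
  \frac{p_2(1-p_2)}{n_2-1}$ and
  $\mathrm{den} = p_1(1-p_2) + p_2(1-p_1)$. This choice is deterministic
  from called genotypes and unbiased for the drift coefficient of a
  Balding–Nichols model ($E[\mathrm{num}]/E[\mathrm{den}] = F$), which is
  what the parameter-recovery tests exploit. Parity with
  likelihood-weighted estimators from genotype-likelihood pipelines is
  explicitly not claimed. Negative window values are retained: clipping at
  zero would bias the downstream Z-standardization.
* $D_{XY} = \sum_s [p_1(1-p_2) + p_2(1-p_1)] / L_{callable}$ — the mean
  between-population pairwise difference per callable bp, symmetric in its
  arguments by construction.
* LD is composite $r^2$: the squared Pearson correlation of unphased
  genotype dosages over individuals non-missing at both loci, for pairs
  < 100 kb apart where both loci have MAF > 0.2 among retained genotypes.
  Each pair is assigned to the window containing its left locus. Dosage
  correlation is the common deterministic choice for unphased data; EM
  haplotype estimation was considered and rejected because it adds an
  iterative component without changing any downstream decision.

# Outlier windows and differentiation islands

Window $F_{ST}$ is standardized per chromosome class —
$F_{ST}^Z = (F_{ST} - \bar F_{ST}) / \mathrm{SD}(F_{ST})$ — because the Z
chromosome's reduced effective population size shifts its baseline;
standardizing jointly would flag the whole Z chromosome instead of islands.
Outliers are windows whose score strictly exceeds the class's 99th
percentile, with the **nearest-rank** definition (value at rank
$\lceil 0.99 N \rceil$): with $N$ distinct scores this calls exactly
$N - \lceil 0.99N \rceil$ outliers, and ties at the threshold are *not*
outliers. Both conventions are stated because tie handling changes counts.

Clustering is assessed in blocks of 50 consecutive windows (0.5 Mb). The
probability of observing $k$ or more outliers in a block under random
scattering is the exact binomial tail $P(X \ge k)$, $X \sim B(50, p)$ with
$p$ the realized genome-wide outlier fraction (0.01 by construction of the
percentile rule). At the default thresholds this is
$P(X \ge 10) \approx 7.13 \times 10^{-11}$. Blocks are **sliding**
(step 1) rather than disjoint — a disjoint grid can split a 0.5-Mb cluster
across a boundary and miss it — and significant blocks are merged
transitively (overlapping or bookended, same chromosome) into regions,
reporting the minimum member-block p and counting each outlier window
once. Chromosomes with fewer than 50 usable windows are skipped with a log
message.

# Effect annotation

Each SNP receives exactly one location class with precedence
exon (CDS) > other (UTR or splice) > intron > upstream > downstream >
intergenic. Splice positions are the 2 intronic bases at each exon
boundary (canonical donor/acceptor); flanks are 5,000 bp, strand-aware.
Both values are common annotation-tool defaults, chosen once and
documented, not reconstructions of any specific tool configuration. For
fixed differences inside a CDS the affected codon is rebuilt respecting
strand and phase and translated with the standard nuclear code; calls are
property-tested against an oracle that re-translates the entire mutant
CDS. One transcript per gene (the first mRNA) is used; multi-transcript
resolution is out of scope.

# The simulator

`simulate_dataset()` emulates divergence in allopatry followed by
secondary contact:

* Ancestral frequencies are drawn from a folded neutral-SFS grid
  (frequencies $i/4n$, density $\propto 1/i$), which matches neutral
  expectations without coalescent machinery.
* Each species' frequency at a site is a Balding–Nichols draw
  $\mathrm{Beta}(p_0(1-F)/F,\ (1-p_0)(1-F)/F)$ around the ancestral
  $p_0$, with the window's drift coefficient $F$; $F \to 0$ is handled as
  the exact no-drift limit $p = p_0$.
* Drift is heterogeneous along the genome: baseline `F_base = 0.2`
  (chosen so that genome-wide allopatric Hudson $F_{ST}$ sits near the
  ~0.2 typical of such species pairs), with **contiguous islands** of
  `peak_len = 15` windows at `F_peak = 0.6` covering `peak_fraction = 5%`
  of autosomal windows. Islands are contiguous, not scattered single
  windows, because differentiation islands in real genomes are runs of
  linked windows and because cluster-recovery tests need runs of at least
  ten elevated windows to exist at all.
* The Z chromosome gets half the autosomal site density
  (`theta_z_factor = 0.5`, the empirical magnitude of Z-vs-autosome
  diversity reduction in birds) and a single homogeneous, higher drift
  coefficient `F_z = 0.3` with no islands — elevated differentiation
  across the whole chromosome but no *relative* outliers, which is exactly
  the observed Z behaviour under per-class standardization.
* Sympatric individual $i$ draws an ancestry proportion $q_i$ toward
  species B once, and genotypes come from the mixture frequency
  $q_i p_B + (1-q_i) p_A$. Defaults mimic the qualitative structure of
  contact-zone assignment plots: sympatric B individuals are strongly
  B-like ($q \sim \mathrm{Beta}(8,2)$, mostly > 0.75), sympatric A
  individuals range from pure A to mostly B
  ($q \sim \mathrm{Beta}(1,1)$). No quantitative admixture distribution is
  available to copy, so these are qualitative choices, made once.
* Depth is Poisson(8) per genotype; zero-depth genotypes are missing, and
  low-depth genotypes are *emitted* rather than dropped so the filter
  module is exercised. The callable mask drops 10% of each chromosome in
  50-kb chunks, forcing mask-aware normalization downstream.
* One seed determines everything; per-chromosome sub-streams are derived
  by fixed seed offsets, so datasets are reproducible chromosome by
  chromosome.

What the simulator does **not** model: recombination maps and coalescent
linkage (sites are exchangeable given their window), selection,
sequencing error, indels/multiallelics, phasing, and reference bias.
Passing recovery tests therefore demonstrate correctness of the
estimators and the scan logic under the generating model — not robustness
to every property of real resequencing data.

# Problem sizes and numerical choices

The test-suite simulations use genomes of 3–20 Mb (300–2,000 windows,
roughly 30k–400k genotype calls per dataset), sizes at which window means
are stable while a full run stays interactive. Drift recovery is asserted
within ±0.02 of $F = 0.2$ and ±0.01 of $F = 0$; island recovery requires
at least 90% of truth clusters of ≥ 10 contiguous elevated windows to be
returned as regions. In the island-recovery experiment outliers are called
at the 95th percentile — the percentile matching the simulated 5% island
coverage — since a 99th-percentile call can flag at most 1% of windows and
could never recover 5%-coverage islands regardless of implementation
correctness. Degenerate inputs are handled by flags, not fabricated
values: zero callable length, $S = 0$, zero FST denominator and
zero-variance dosages all yield `NA`, and a zero class SD in the
Z-standardization is an error rather than a silent division by zero.

# Known limitations

* Called genotypes only: no genotype-likelihood machinery, so numerical
  parity with likelihood-based pipeline output is not expected, only
  qualitative agreement of the landscape.
* The binomial clustering test treats windows as independent; linkage
  makes it anti-conservative as a hypothesis test. It is used, as in
  practice, as a ranking/screening device.
* One transcript per gene; splice calls cover only the canonical 2-bp
  donor/acceptor.
* Wilcoxon comparisons are reported as the rank-sum statistic (sum of
  midranks of the first sample); p-values under the normal approximation
  are deliberately not attached by default.
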