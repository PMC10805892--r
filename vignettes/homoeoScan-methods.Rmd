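---
title: "Detecting karyotype aberrations and homoeologous exchanges in allotetraploids"
author: "homoeoScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting karyotype aberrations and homoeologous exchanges in allotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeoScan)
library(GenomicRanges)
```

## The problem

An allotetraploid genome carries two diploid subgenomes inherited from two
progenitor species.  Meiotic irregularities between the corresponding
(homoeologous) chromosomes produce a spectrum of karyotype changes:
whole-chromosome aneuploidies (trisomy, monosomy), segmental deletions and
duplications, and homoeologous exchanges in which a segment of one
subgenome is replaced by the corresponding segment of the other.  In a
species with very low nucleotide diversity these events can be a major
source of standing genetic variation, and they are detectable from
ordinary short-read resequencing without any special library type.

`homoeoScan` implements the detection pipeline around two observables,
both computed per accession against a euploid reference accession:

1. **Homoeologous variant frequency.**  At *homoeologous sites* -- positions
   where the two subgenomes carry different alleles -- the fraction of
   reads supporting the referenced subgenome's allele has expectation

   $$f(c_A, c_B) = \frac{c_A}{c_A + c_B},$$

   where $c_A$ and $c_B$ are the copy numbers of the two homoeologs.  The
   balanced state (2,2) gives $f = 1/2$; a heterozygous exchange (3,1)
   gives $3/4$; a homozygous replacement (4,0) gives $1$.  Departures from
   $1/2$ are a *reduction of homoeologous heterozygosity* (ROH~H~).

2. **Depth of coverage (DOC) ratio.**  Per-homoeolog unique-mapping
   coverage in genomic windows, normalized first by the accession's own
   genome-wide median (to remove library size) and then by the same
   quantity in the euploid reference accession:

   $$\mathrm{doc}_s(w) = \frac{\mathrm{cov}_s(w) / \tilde m_s}
        {\mathrm{cov}^{\mathrm{ref}}_s(w) / \tilde m^{\mathrm{ref}}_s},
     \qquad E[\mathrm{doc}_s] = c_s / 2 .$$

   The *median* (not mean) is used for the genome-wide normalization so
   that the normalization itself is robust to the aberrations being
   detected; this holds as long as aberrant windows are a minority of the
   genome per subgenome.

Exchanges conserve total copy number ($c_A + c_B = 4$) and move frequency
and the two doc values in opposite directions; deletions and duplications
change $c_A + c_B$ and violate $\mathrm{doc}_A + \mathrm{doc}_B \approx 2$.
Combining the two observables separates every event class and its
zygosity.

## Window systems

Two window systems are used, mirroring how the observables behave:

* **Genomic windows of fixed non-repetitive content** (default
  $W = 100$ kb) for coverage.  A window closes at the base where its
  running unmasked total reaches $W$, so window *span* varies with local
  repeat content while its information content is constant.  Trailing
  masked bases attach to the next window; the final remainder window is
  kept and flagged `partial`, and all downstream statistics normalize by
  the actual `nonrepBp`, so the windows tile the chromosome.
* **Sliding windows of a fixed number of variant sites** (default 500
  sites advancing by 250, so consecutive windows share 250 sites) for the
  frequency scan.  Fixing the site count fixes the power of the
  chi-square statistic per window.  Windows are emitted until one reaches
  the last site; a chromosome with fewer than 500 sites contributes a
  single window of all its sites.

## The ROH~H~ scan statistic

For a window's sites with allele depths $(a_i, b_i)$, the statistic is the
per-site Pearson chi-square against the balanced expectation $p = 1/2$,

$$\chi^2 = \sum_i \frac{(a_i - b_i)^2}{a_i + b_i},
  \qquad \mathrm{df} = \#\{i : a_i + b_i > 0\},$$

summed over sites.  Under (2,2) with binomial read sampling the statistic
behaves like a chi-square with one degree of freedom per site, so the
window statistic is referred to the $\chi^2_{\mathrm{df}}$ upper tail.
Significance is Bonferroni-corrected over all windows of the genome at a
family-wise level $\alpha$ (default 0.05).  This construction is
deliberately simple and is verified in the test suite against an
independently coded brute-force oracle on small windows.

A window is *flagged* when its ROH~H~ tail probability falls below the
Bonferroni threshold **or** when either doc departs from 1 by more than
`docTol` (default 0.25, half the distance between adjacent copy-number
expectations).

## Copy-state fitting and mosaicism

For each flagged window the integer state grid $c_A, c_B \in 0..4$ with
$c_A + c_B \le 5$ is searched exhaustively, minimizing

$$R = w_f\,(\bar f - f(c_A,c_B))^2
    + w_d\,(\mathrm{doc}_A - c_A/2)^2
    + w_d\,(\mathrm{doc}_B - c_B/2)^2$$

with default weights $w_f = w_d = 1$ on the natural scales of both
observables.  Ties break toward the state closest to (2,2) in L1 copy
distance (parsimony).  The grid is capped at total copy 5 (trisomy);
higher amplifications are outside the grid and surface as persistently
high residuals.

Somatic mosaicism -- a fraction $m$ of cells carrying the aberrant state,
the remainder balanced -- produces intermediate signals.  Read pools mix
in proportion to cell fraction times copy number, so the effective copy
numbers are $m c + (1-m) \cdot 2$ per homoeolog and the frequency
expectation is their ratio (linear in $m$ exactly when the aberrant state
conserves total copy number).  After the pure-grid search a
one-dimensional fit of $m$ against every aberrant state is performed, and
the mosaic is reported instead of the pure state only when all three of
these hold:

* the mixture reduces the residual by more than `mosaicImprovement`
  (default 0.25);
* $\hat m$ lies strictly inside (0.15, 0.85) -- outside that range the
  pure states are not meaningfully distinguishable from the mixture;
* the best pure residual exceeds `mosaicMinResidual` (default 0.01).

The absolute floor deserves a comment, because the design here was
genuinely open.  Mixture families are *degenerate*: a pure (3,1) window is
observationally identical to a (4,0) mosaic at $m = 0.5$, and a pure state
that fits almost exactly can always be "improved" microscopically by an
equivalent mixture.  Without the floor, sampling noise alone decides
whether a clean heterozygous exchange is reported pure or mosaic.  With
it, the mosaic branch only activates when no integer state explains the
window.  For the same reason the mixture search runs jointly over all
aberrant states (the best pure state for a mosaic observation is often
(2,2) by parsimony), and equal-residual mixtures break ties toward the
aberrant state closest to balanced, which makes the (3,1)-at-$m$
description win over the equivalent (4,0)-at-$m/2$ one.

## Event segmentation

Flagged windows with the same fitted state merge into runs, tolerating
`gapTol` (default 1) intervening windows.  Windows that straddle a true
event edge see a diluted signal and can fit a different, intermediate
state; such short runs hugging a longer run are absorbed by it (dropped),
which removes edge artifacts without moving boundaries by more than about
one window.  Runs shorter than `minEventSize` (default 200 kb, the
stated reliability limit of the window sizes involved) are dropped.
Events spanning at least `aneuploidySpan` (default 95%) of the
chromosome's scannable extent -- first to last catalog site, since fully
masked chromosome ends carry no signal -- reclassify as whole-chromosome
aneuploidy.  Zygosity follows the fitted state: one copy away from (2,2)
is heterozygous, two or more is homozygous (for exchanges this reads on
$|c_A - 2|$: (3,1)/(1,3) heterozygous, (4,0)/(0,4) homozygous); an event
whose windows are mostly mosaic fits is reported mosaic with the mean
fitted $\hat m$.

## Genotype calling and diversity

The deterministic depth-ratio caller classifies each site by the
alternative-allele fraction $r = \mathrm{alt}/(\mathrm{ref} +
\mathrm{alt})$: homozygous reference for $r \le 0.1$, heterozygous for
$r \in [0.15, 0.85]$ (endpoints inclusive; the GBS rule set tightens this
to $[0.25, 0.75]$), homozygous alternative for $r \ge 0.9$, and missing
otherwise -- including depth below the minimum (10 reads; 5 for
low-coverage data) and the uncovered gaps $(0.1, 0.15)$ and
$(0.85, 0.9)$, where no call is defined.  Sites are retained only when
informative in strictly more than half of the individuals, and sites
also variant in the reference accession's self-alignment are removed as
assembly artifacts.

Windowed nucleotide diversity uses the unbiased per-site heterozygosity

$$\pi(w) = \frac{1}{W}\sum_{j \in w} \frac{n_j}{n_j - 1}\, 2\hat p_j (1 - \hat p_j),$$

with $n_j$ the called allele copies at site $j$ (missing genotypes reduce
$n_j$) and $W$ the window's non-repetitive content.  Introgressed
segments -- tracts derived from the donor species, recognizable as windows
of strongly elevated diversity -- are flagged per accession when the
window SNP count exceeds the baseline accessions' median $+\,k \cdot$MAD
(default $k = 10$), with an absolute floor of 5 SNPs that only binds for
degenerate all-zero baselines.  A threshold-on-counts rule was chosen
over an HMM deliberately: it matches how the contrast presents in window
count distributions and keeps every flag auditable.  Consecutive flagged
windows merge into blocks with the same gap tolerance as events.

## The synthetic generator

The generator emulates the statistical structure the scan assumes, not
reads: two homoeologous subgenomes of equal length with shared
coordinates; a repeat mask of alternating exponential runs (10 kb cycle)
following a per-region masked-fraction profile (default 0.5); diagnostic
homoeologous sites placed only at unmasked positions, each present
independently at `siteDensity` (default 0.005/bp, reflecting ~5%
subgenome divergence thinned to usable sites); Poisson total depth at
`coveragePerCopy` per chromosome copy (default 2x per copy, i.e. ~8x per
euploid accession -- the panel's depth distribution was not specified
upstream, so 8x was fixed once as typical of public low-coverage panels);
binomial allele sampling at the copy-ratio expectation perturbed by a
symmetric substitution error $\varepsilon$ (observed $f(1-\varepsilon) +
(1-f)\varepsilon$, default 0.001); and per-window Poisson coverage per
subgenome.  Reads from both homoeologs contribute to site depth, while
per-homoeolog window coverage is simulated separately -- mirroring an
analysis in which reads are aligned to each subgenome separately for
variants but unique-mapping coverage drives DOC.

The panel generator draws segregating sites from the neutral frequency
spectrum (derived-allele count $i$ with probability $\propto 1/i$; site
density $\pi a_n$ per unmasked bp), which makes realized diversity match
`panelPi` (default $3 \times 10^{-4}$) without calibration.  Introgressed
blocks add carrier-private alleles at the density that raises local
window diversity to `panelPi * introgressionPiMultiplier` (default 10).
This is a *window-level* emulation: real introgressed haplotypes would
place donor divergence on a shared haplotype background rather than as
independent private alleles, so haplotype-structure statistics (LD,
shared breakpoints) are outside what passing tests demonstrate.  Other
real-data features the generator does not model: mapping bias between
subgenomes, GC-dependent coverage waves, reference gaps, paralogous
collapse, and indels (there is no read-level simulation at all).
Consequently, green recovery tests show the *inference machinery* is
correct under its stated noise model -- not that real libraries meet that
model.

## Numerical choices and degenerate inputs

* All rates validated to [0,1]; zero-length chromosomes and densities
  yielding fewer than one site per chromosome are refused.
* A fully masked chromosome yields zero genomic windows; a window with
  zero total depth has undefined frequency and is flagged missing; a
  window with zero reference-accession coverage has undefined doc.
* Both allele counts zero at a site is a missing genotype, never an
  error.
* Single configured seed determines every draw (reference, truth,
  observables, panel); repeated runs are byte-identical.
* Coordinates are 1-based closed in memory (`GRanges` convention) and in
  VCF/TSV/reports; BED output is 0-based half-open via `rtracklayer`.

## Problem sizes used by the test suite

The recovery suites run on panels the package generates itself: 120
seeded replicates (20 per event class: heterozygous and homozygous
exchange, deletion, duplication, whole-chromosome trisomy, and a
half-mosaic exchange) on 2-3 chromosome pairs of 3 Mb at 2x per copy,
requiring >= 95% correct type and zygosity with boundary error at most
one window; 200 euploid replicates for the null control; convergence
checks at 10x per copy; and an 8 Mb, 20-accession panel for diversity
and introgression recovery.  These sizes were chosen as the smallest at
which the asymptotics the scan relies on (chi-square tails, median
stability) are comfortably in force.

## Known limitations

* Balanced or reciprocal exchanges do not change relative copy number
  and are invisible to both observables by construction.
* Events below ~200 kb, or on chromosomes with very few catalog sites,
  fall under the minimum-size filter.
* Tetrasomy and higher total copy numbers are outside the fitted grid
  and surface as unclassified high-residual windows.
* Mosaic fractions outside (0.15, 0.85) are indistinguishable from pure
  states at realistic depths and are reported as pure.
* The aneuploidy/segmental distinction uses a 95% span threshold over
  the scannable extent; a terminal event covering almost the whole
  chromosome is reported as aneuploidy.

## A minimal run

```{r demo, eval = FALSE}
res <- runPipeline(demoConfig(), outDir = tempdir())
res$scans$demo1$events
```
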