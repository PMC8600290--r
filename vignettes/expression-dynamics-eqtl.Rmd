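---
title: "Mapping eQTLs for expression dynamics in the field: models and methods"
author: "dyneQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping eQTLs for expression dynamics in the field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

A conventional eQTL study measures every line of a mapping population under
one condition and asks which marker genotypes explain expression differences.
That design cannot see loci whose effect is *dynamic* — visible only at dawn,
only in hot weather, or only at a particular developmental stage. dyneQTL
implements the alternative: sample a chromosome segment substitution line
(CSSL) panel sparsely across a whole growing season, model each parent's
expression dynamics as a function of the clock, development and weather, and
then ask, marker by marker, whether substituting the donor allele switches a
gene's dynamics from one parental model to the other.

The package covers the full workflow: simulating a realistic study
(`simulateDataset`), preprocessing counts (`preprocessExpression`), fitting
per-parent dynamic models (`fitGeneModels`), testing for parental
polymorphism (`polymorphismTest`), scanning markers and calling eQTLs
(`scanGenes`, `permutationPvalues`, `callEqtls`), and validating calls in
new environments and mosaic-genome backcross inbred lines (BILs)
(`predictNewEnvironment`, `improvementFraction`, `bilPermutationTest`).

# The expression model

For gene $g$ and parent $P$, observed $\log_2$ reads-per-million is modelled
as

$$ y_s = \mu + a\cos\left(\tfrac{2\pi h_s}{24}\right)
            + b\sin\left(\tfrac{2\pi h_s}{24}\right)
            + c\,\mathrm{sage}_s + d\,E_s + \varepsilon_s $$

where $h_s$ is the fractional hour of day, $\mathrm{sage}_s$ is *scaled age*
(days since sowing divided by the line's days from sowing to heading, so
heading is 1.0 regardless of genotype or transplant set), and $E_s$ is a
*gated-window* weather feature

$$ E_s = \frac{1}{60w}\int_{t_s - w}^{t_s} \max(x(u) - \theta,\, 0)\, du, $$

the average exceedance of variable $x$ (air temperature in °C or global
solar radiation in kJ m$^{-2}$ min$^{-1}$) above a gate $\theta$ during the
$w$ hours before sampling. The clock, age and environment terms are each
optional; the environment term uses exactly one feature chosen from a grid:

* variable ∈ {temperature, radiation};
* window $w$ ∈ {1, 2, 4, 8, 24, 48, 72} h — from immediate responses to
  multi-day integration;
* gate $\theta$ ∈ {min, q25, median, q75} of the variable's season-wide
  distribution (duplicates collapsed; for radiation the lower quantiles are
  all zero).

Fitting is weighted least squares with gene-level precision weights
(below). Each parent's model is fitted only on *background-concordant*
samples — the parent itself plus the CSSLs sharing its background, whose
genomes are mostly non-substituted; BILs are held out for validation.

## Term selection

All eight term subsets, crossed with every grid feature for subsets
containing the environment term, are fitted; the winner minimises

$$ \mathrm{IC} = n \ln(\mathrm{RSS}_w / n) + k_\mathrm{eff} \ln n, $$

where $k_\mathrm{eff}$ counts the coefficients plus two extra dimensions
when the environment term is present, because its window and gate are
themselves optimised over the grid. We deliberately use the BIC-type
$\ln n$ penalty rather than AIC's $2k$: with a $2k$ penalty the probability
of spuriously including one extra coefficient is
$P(\chi^2_1 > 2) \approx 0.16$ *per term*, and maximising the environment
term over a 56-point grid inflates that much further — in calibration runs
plain AIC recovered the true term set for only ~35% of genes at $n = 400$,
versus ~95% for the criterion above. The classic AIC is still reported in
every fitted model for reference.

Two numerical details. The ratio $\mathrm{RSS}_w/n$ is floored at $10^{-10}$
so that an exactly interpolating fit (noiseless data) yields a finite
criterion; ties then differ only in the penalty and resolve toward the
smaller model, with remaining ties going to the earliest candidate in a
fixed enumeration (fewer terms first, then grid order). Rank-deficient
designs (for example all samples at a single time point) are skipped with a
warning rather than fitted.

# Preprocessing

* **Sample filter**: keep samples with total read count strictly greater
  than $10^5$.
* **Gene filter**: drop genes detected (count > 0) in at most 20% of the
  kept samples; a gene detected in exactly 20% is dropped.
* **Normalisation**: $\mathrm{rpm} = 10^6 \times \mathrm{count} /
  \mathrm{total}$ with totals recomputed over the kept genes, and
  $\log_2(\mathrm{rpm} + 1)$; the pseudo-count keeps zero counts defined.
* **Precision weights**: one weight per gene, $w_g = 1/\max(v(m_g),
  10^{-6})$, where $v(\cdot)$ is a running median of per-gene mean squared
  residuals over equal-size mean-rank bins (~50 genes per bin). Gene-level
  weights are the simplest scheme consistent with weighting by measurement
  reliability; because they are constant within a gene they leave each
  gene's least-squares coefficients unchanged and only matter where
  residuals are pooled across genes (the BIL test's error totals).
* **Weather**: minute resolution by linear interpolation
  (`interpolateMeteo`); *dark periods* are maximal intervals with radiation
  strictly below 0.3 kJ m$^{-2}$ min$^{-1}$.

# Polymorphism test

Whether the two parents differ in a gene's dynamics is tested with
$T = \mathrm{RSS}_w(\text{shared}) - \mathrm{RSS}_w(\text{separate})$, where
both use the same design (the union of the two parents' selected term sets,
with the environment feature of the lower-IC parent): "shared" is one fit on
all background-concordant samples, "separate" fits the two background groups
independently. Because the groups' designs nest the shared fit, $T \ge 0$.

Significance comes from permuting background labels at the *line* level —
samples of one line always move together, preserving within-line
correlation — and refitting the group models under every labeling. The
refit is essential: evaluating fixed fitted models would compare an
in-sample quantity (each parental model is fitted on its own background)
against out-of-sample permutations and is drastically anti-conservative (in
a complete-null calibration it flagged 54 of 60 genes; the refitting
construction flagged none). Benjamini–Hochberg adjustment across genes at
FDR 0.05 flags polymorphic genes; per-parent clock/age/environment
dependence flags report term membership in each parent's selected model.

# The marker scan

For a polymorphic gene, each marker $m$ induces an *assignment*: every line
is predicted with the parental model matching its allele at $m$ (samples
follow their lines). The scan statistic is the reduction in weighted
residual error relative to the background assignment,
$T_m = \mathrm{RSS}_{BG} - \mathrm{RSS}_m$; parental predictions are
computed once and aggregated per line, and the background assignment is
always retained as an explicit candidate, so the candidate-set minimum
never exceeds $\mathrm{RSS}_{BG}$.

## Permutation calibration and FDR

The null permutes the allele column across lines, *stratified by
background*: alleles are shuffled among P1-background lines and among
P2-background lines separately, preserving each stratum's substitution
count. The stratification mirrors the training design — each parental model
is fitted on its own background's samples, so only lines within a
background are exchangeable under the null; an unstratified shuffle mixes
in-sample and out-of-sample lines and mis-calibrates the null.

Marker-level p-values $p_m = (1 + \#\{T^{null} \ge T_m\})/(B+1)$ are
reported for inspection, but gene-level significance uses the max-T
construction: per permutation, the maximum of $T$ over all markers, which
absorbs the marker multiplicity within a gene exactly (linked markers are
heavily correlated, so counting them as independent tests would be both
wrong and, at permutation resolution $1/(B+1)$, unable to reject at all).
BH across genes on the max-T p-values controls FDR at the gene level — the
natural unit here, since a gene either has a detected eQTL or not.

## Blocks, cis/trans, multiple eQTLs

Within a called gene, markers exceeding the gene's familywise null
threshold (the 95th percentile of the max-T null) are grouped into blocks
of contiguous markers with *identical assignment signatures* — allele
columns that agree across all scanned lines are mathematically
indistinguishable in a CSSL panel, so one call is emitted per block,
represented by the member with maximal $T$ (ties to the smallest
position). A call is *cis* when its representative marker lies on the
gene's chromosome within 2 Mb (configurable) of the gene, else *trans*;
note that at the default marker density (~2.6 Mb spacing) the 2 Mb window
is close to the localisation limit, so cis labels are conservative.

When a gene has several significant blocks, a forward selection starts from
the max-T block and accepts an additional block only if the combined
assignment strictly lowers the residual error. The combined assignment is a
per-line majority vote over the selected blocks' representative markers,
with ties resolved toward the line's non-background (donor) allele. The
donor tie-break is load-bearing: if ties instead followed the top block,
then with two blocks every line would either be unanimous or fall back to
the top block, the combined assignment would provably equal the top block's
assignment alone, and a second eQTL could never be selected.

# Evaluation

* **Cross-environment prediction**: fitted parental models (never refitted)
  predict expression under a new season's weather; for each eQTL-influenced
  gene, the eQTL model picks parental models from the multi-eQTL
  assignment, the background (BG) model from the line's background. A gene
  counts as *improved* when its weighted squared error is strictly smaller
  under the eQTL model; ties count as not improved, and genes whose two
  assignments agree everywhere are excluded from the improved fraction.
* **BIL permutation test**: BILs carry mosaic genomes the scan never saw.
  The observed statistic is the total weighted prediction error over
  eQTL-influenced genes with each gene's model chosen by the BIL's alleles
  at its eQTL markers; the null permutes the BIL's allele vector across
  markers (preserving allele counts), and the empirical p uses the +1
  correction so it is never zero. With ≤ 7 markers the test can enumerate
  all permutations exactly (`exhaustive = TRUE`, p = #{null ≤ obs}/N,
  identity included). Reference totals under pure-P1 and pure-P2 models are
  reported alongside.
* **Enrichment**: two-sided 2×2 Fisher exact tests per annotation term with
  BH adjustment; a term annotating every gene (or none) is reported as
  neutral (odds ratio 1, p 1).

# The synthetic-data generator

`simulateDataset` emulates the study design the analysis assumes, and emits
the ground truth needed for recovery tests. Defaults (one call to
`simConfig()`):

* **Genome/panel**: 12 chromosomes × 12 markers (30 Mb chromosomes); 2
  parents; 40 CSSLs per background whose donor segments *overlap* (length
  ≈ 2 × markers/segments, evenly spaced starts) so each marker is covered
  by about two lines per background, as in real reciprocal panels where
  adjacent lines share boundary regions — with non-overlapping segments
  each marker has a single informative line per stratum and a permutation
  that realigns the two backgrounds' substituted lines (probability ≈
  1/40) reproduces the full observed max-T, flooring the attainable
  p-value; 2 Takanari-style BILs at 18% ± 5 points donor fraction via a
  two-state Markov chain along the markers.
* **Design**: 2 transplant sets sown 14 days apart; 8 bihourly sampling
  days (12 time points from 16:00 to 14:00 the next day) spread over a
  150-day season; per day and set, lines are drawn lowest-count-first so
  per-line totals differ by at most one and no line is sampled twice in a
  day. Heading days are drawn per (line, set) around parent means of 100
  (P1) and 90 (P2) days (SD 3), so the ~10-day parental difference
  exercises the scaled-age adjustment.
* **Weather**: minute-resolution temperature = seasonal trend + diurnal
  sinusoid (peak 14:00, amplitude 4 °C) + AR(1) noise; radiation = daylight
  half-sinusoid × daily cloud factor, exactly zero at night.
* **Transcriptome**: 300 focal genes with baseline $\log_2$rpm in 6–10, of
  which 20% are polymorphic (25% of those trans-controlled), plus 700
  filler genes extending into the high-expression housekeeping tail
  (baseline 6–14) with deliberately modest dynamics. The filler mass
  matters: real libraries are normalised over ~24,000 genes, so an eQTL's
  fold change barely moves totals; with only a few hundred simulated genes
  the totals would become genotype-dependent and leak a
  background-correlated shift into every gene's log2rpm (in early
  calibration runs this flagged *every* null gene as polymorphic). For the
  same reason the age and environment covariates are centred at their
  training-schedule means inside the generator, so a planted coefficient
  never doubles as a huge intercept offset that would let a single gene
  dominate library totals.
* **Effects**: polymorphic genes differ in intercept by 3–5 noise SDs
  (sign random; half additionally redraw their clock component);
  environment effects are scaled to a target signal-to-noise ratio (1–3 by
  default). Noise is Gaussian on the log2 scale (SD 0.5) and counts are
  `round(max(2^y - 1, 0) * librarySize / 1e6)` with library sizes uniform
  in 0.5–3 million reads; a negative-binomial resampling of the same means
  is available via `countModel = "nbinom"`.
* **Planted truth**: cis genes are controlled by their nearest marker;
  trans genes by a random marker on another chromosome. A validation
  season reuses the planted parameters, feature definitions and covariate
  centres under new weather (`simulateExpression(..., truth = )`).

What the generator does *not* emulate: linkage disequilibrium beyond the
segment structure, genotyping error or residual heterozygosity, batch or
flow-cell effects, realistic rice genome coordinates, and (by default)
count overdispersion beyond lognormal rounding. Passing tests therefore
demonstrate correctness of the machinery under the stated generative
assumptions, not robustness to everything real field data can contain.

# Problem sizes used in the tests

The packaged test-and-acceptance runs use the default design above (384
samples, 1000 genes, 200 scan permutations, 500 polymorphism permutations;
about one minute end to end), a 200-gene complete-null calibration at 500
permutations, a noiseless 40-gene exact-recovery fit, a 100-gene
signal-to-noise-2 feature-identification fit, a 3-day validation season,
and a 2000-permutation BIL test. These sizes were chosen to give stable
Monte-Carlo margins (binomial SE below ~2 percentage points on the reported
fractions) while staying desk-scale.

# Known limitations

* Gene-level weights ignore the mean-variance trend *within* a gene across
  expression levels; observation-level weights would need replicated
  conditions the sparse design does not provide.
* The scan's resolution is the assignment-signature block; linked markers
  inside one substituted segment cannot be separated, and cis/trans labels
  inherit the marker spacing.
* The multi-eQTL combination rule (majority vote, donor tie-break) is one
  defensible choice among several; with two blocks it reduces to "donor
  model iff donor allele at either block".
* Permutation p-values are bounded below by $1/(B+1)$; gene-level BH
  therefore needs enough permutations relative to the number of scanned
  genes (500 polymorphism permutations for ~1000 genes at FDR 0.05).
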