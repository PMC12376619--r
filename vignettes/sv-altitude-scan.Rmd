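---
title: "Methods: structural-variant population genetics for high-altitude cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant population genetics for high-altitude cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`svaltiscan` implements the population-genetic core of a long-read
structural-variant (SV) adaptation study: building a nonredundant cohort
catalog from per-sample call sets, scanning it for unusually differentiated
SVs between a high-altitude target group and lowland controls, locating SV
hotspots, and classifying SVs that may have introgressed from a donor
species (yak into highland cattle being the motivating system). This
vignette explains each model, its assumptions, the tunable parameters, and
the choices made where the methods literature leaves the design open.

```{r setup}
library(svaltiscan)
```

## Data model

Everything is tabular. An SV catalog is a tibble (one row per variant,
1-based inclusive coordinates, insertions and break-ends as point events
with `end == start`, lengths stored unsigned and re-signed on VCF export).
Genotypes are an integer dosage matrix (SV x sample) with `NA` as a
first-class missing state excluded from every allele count, matching how
force-called `./.` genotypes are treated in cohort pipelines. A population
manifest assigns each sample a population and one of three roles: `target`
(the focal, putatively adapted group), `control`, and `donor`.

## Catalog construction

Calls from different callers (per sample) or different samples (per
cohort) are clustered by breakpoint distance: two same-type, same-
chromosome calls link when *both* start and end lie within
`max_breakpoint_dist` (default 500 bp), and clusters are the transitive
closure of these links (single linkage, the behaviour of the SURVIVOR
family of merge tools; the linkage rule is configurable policy, not an
assumption baked into the code). Consensus filtering keeps clusters
supported by at least two callers; cohort merging keeps one representative
per cluster, from the earliest sample in the stated order, which also
defines the cumulative growth curve. Sharing classes use presence (at
least one ALT allele) with the major threshold `ceiling(N/2)` — 42 of 84.

Region annotation follows the usual precedence exonic > intronic >
upstream/downstream > intergenic, with a 5 kb flanking window (the common
annotator default; the choice only shifts counts between the two weakest
categories). Transposable-element (TE) tagging of deletions and
duplications requires 80% *reciprocal* overlap with a repeat interval —
the overlap must cover 80% of the SV *and* 80% of the repeat — while
insertions, whose sequence is not anchored in the reference, take their
labels from a sidecar table produced by a repeat annotator on the inserted
sequences.

## Differentiation scan

Per-SV FST uses the Weir–Cockerham (1984) variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals), with $\hat\theta = a/(a+b+c)$. Negative estimates are
retained — clamping them would bias the genome-wide moments the scan
depends on. Sites monomorphic across the compared groups have no defined
$\hat\theta$ and are excluded pairwise. Windowed FST aggregates components
as a ratio of sums, $\sum a / \sum (a+b+c)$, over 50 kb windows with 25 kb
steps — never a mean of per-site ratios, which overweights noisy sites.

The di statistic for SV $s$ is

$$d_i(s) = \sum_j \frac{\hat\theta_{ij}(s) - \mu_{ij}}{\sigma_{ij}},$$

the sum over comparison populations $j$ of the genome-wide standardized
pairwise FST of the focal group $i$. The focal unit defaults to the pooled
target group contrasted with each control population separately (the
grouping used when one adapted cohort is compared against several lowland
breeds); a per-target-population mode is available. Outliers are flagged
by a one-sided upper Z test on the di values, $P < 0.001$, i.e.
$Z > 3.09$.

A caveat the package documents rather than hides: the per-site
$\hat\theta$ sampling distribution is strongly right-skewed, so the
normal-quantile Z test is anti-conservative — on label-permuted synthetic
cohorts it flags roughly 1.4% of SVs at nominal $\alpha = 0.001$, and
large real scans show the same order of inflation. The di outlier list is
therefore an enrichment ranking, not a calibrated family of hypothesis
tests; users needing calibrated error control should permute labels and
use the resulting empirical distribution.

## Hotspot detection

Each SV contributes one point, the midpoint `floor((start+end)/2)` (the
breakpoint itself for insertions and break-ends). Per chromosome, a
Gaussian kernel density (bandwidth 500 kb, i.e. the kernel sd) is
evaluated on a 10 kb grid and compared with `n_perm = 200` uniform
re-placements of the same number of midpoints. The observed density at
each grid point gets an empirical p against the *pooled* null density
values of its chromosome, with the +1 pseudo-count, giving a resolution of
$1/(1 + n_\mathrm{perm} \cdot n_\mathrm{grid})$; pooling is what makes the
subsequent Benjamini–Hochberg correction across the genome meaningful,
since per-grid-point nulls of 200 permutations can never clear a
genome-wide FDR threshold on their own. BH-significant grid points
(`alpha = 0.05`) are merged into runs, extended by half a bandwidth on
each side and clipped to the chromosome. The 500 kb default bandwidth
makes recovered hotspots about a megabase long, the scale reported for
cattle SV hotspots.

Enrichment of an annotation in hotspots uses a Z score against a
randomization null, and the right null depends on what the annotation is.
For tracks *independent of the SV catalog* (conserved elements, genes) the
default relocates the *hotspot intervals* (lengths and chromosome
assignment preserved, uniform non-overlapping placement), preserving the
annotation's own clustering; a `permute_points` null that re-draws the
annotation uniformly is also provided and follows the binomial intuition
exactly. For annotations that are a *subset of the catalog itself* — TE-
derived SVs above all — both of those nulls confound the question with raw
SV density: hotspots contain several times the background SV density by
definition, so any SV subset looks "enriched" there even when its tagging
*rate* inside hotspots is lower. The `permute_labels` null resolves this
by resampling which catalog midpoints carry the label, positions held
fixed, thereby testing the labelled fraction inside hotspots against the
genome-wide fraction; it is what the pipeline uses for the TE report, and
it is the only null under which planting *fewer* TE tags inside hotspots
correctly yields a negative Z. The p value is the one-sided normal tail in
the direction of the deviation, so enrichment and depletion are reported
symmetrically.

## Introgression classification

A candidate donor-introgressed SV must be fixed among called donors
(ALT frequency $\ge$ 1.0 — "fixed" tolerates missing donor genotypes but
not non-ALT ones), absent from every called control genotype, carried by
at least one target sample, and have at least 80% called genotypes in each
role group. Tightening any threshold can only shrink the candidate set.

Validation asks whether the carriers' haplotypes cluster with the donors
in a neighbor-joining tree of the SV's flanking-SNP allele-sharing
distances ($d = 1 - \mathrm{IBS}$, phase-free). The rule is: some edge of
the unrooted tree must split the leaves into a side holding every donor
and every carrier but no non-carrier cattle. This formulation matters:
carriers of a genuine introgression are typically heterozygous (one
donor-derived haplotype) and therefore sit on the stem *between* the
cattle mass and the donor clade — inside that bipartition, but outside
the donors' own minimal clade. A rule demanding carriers inside the
minimal donor clade rejects essentially every true heterozygous carrier;
the bipartition rule validates >95% of simulated true introgressions
while rejecting donor-unrelated windows.

## The cohort simulator

The simulator is the package's test bed and defines the conditions under
which every property above is demonstrated:

* **Positions** — a uniform background plus `n_hotspots = 5` Gaussian
  clusters of `sv_per_hotspot = 150` SVs (positional sd 100 kb) on a
  3 x 50 Mb genome; compact enough for interactive use while leaving
  hotspots well separated (centers at least 5 Mb apart, away from
  chromosome ends).
* **SV types** — DEL 0.403, INS 0.539, DUP 0.029, INV 0.012, BND 0.017,
  the mix observed in large long-read cattle catalogs.
* **Genotypes** — Balding–Nichols: ancestral frequency
  $p \sim U(0.05, 0.95)$, population frequency
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F = 0.1$ (cattle-breed
  scale differentiation), dosages $\mathrm{Binomial}(2, p_k)$. SVs
  monomorphic across the cattle samples are redrawn (capped at 20
  rounds), because a cohort catalog only contains variants somebody
  carries.
* **Planted signals** — 50 differentiated SVs (target-side ancestral
  frequency shifted by $\Delta = 0.6$), 50 introgressed SVs (donors
  homozygous ALT, controls homozygous REF, each target sample a
  heterozygous carrier with probability 0.3), TE labels with probability
  0.6 inside vs 0.2 outside hotspots.
* **Cohort layout** — three target populations, two controls, one donor
  population (46 samples) by default; the differentiation-scan checks use
  a layout mirroring the motivating study, 3 x 12 targets vs 4 x 12
  controls.
* **Flanking SNPs** — two haplotype pools diverged at each site with
  probability 0.3 (a strongly diverged donor species), per-haplotype
  mutation noise 0.02, ~100 sites per 50 kb two-sided window.
* **Noise** — missingness 2% by default; genotype error replaces a call
  with one of the other two states uniformly, across *all* samples, since
  donor and control genotypes come from the same calling pipeline in real
  cohorts. Under 5% error the strict donor-fixation policy loses most
  true candidates (one flip among ~22 donor+control genotypes suffices;
  survival $\approx 0.95^{22} \approx 0.32$) — an inherent property of an
  exact-fixation filter, visible in the acceptance report rather than
  hidden by an error model that spares exactly the samples the filter
  inspects.

What the simulator does *not* emulate: linkage disequilibrium and
recombination within windows, coalescent haplotype structure, caller-
specific breakpoint jitter, reference bias, or sequence-resolved
insertions. Passing tests therefore demonstrate the correctness and
calibration of the *methods* under their stated models, not performance on
any particular real cohort.

## Numerical conventions

1-based inclusive coordinates internally, converted at the BED boundary;
percentages rounded half-even to two decimals, with headline carrier rates
also reported as integer percentages; empirical p values always use the
+1 pseudo-count; NJ follows ape's Saitou–Nei implementation, exact on
additive distances; all randomized procedures take explicit seeds and the
pipeline is a pure function of (inputs, parameters, seed).

## Problem sizes

The shipped checks use cohorts of 500–7,500 SVs and 46–100 samples, 100
random genotype configurations per oracle comparison batch (1,000 in the
acceptance run), 200 hotspot permutations, and 100–1,000 enrichment
draws — sizes chosen so a complete run stays interactive on one CPU while
keeping Monte-Carlo noise well inside the asserted margins.

## Pipeline

```r
res <- run_pipeline("out", sim = sim_config(), seed = 1)
res$summary$hotspot_n
res$summary$introgression_candidates
```

`run_pipeline()` executes the toggled stages, writes one TSV per stage and
a `summary.json` whose every number is an aggregation of one of those
tables, and logs one line per stage. Re-running with the same seed
reproduces the outputs byte for byte.
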