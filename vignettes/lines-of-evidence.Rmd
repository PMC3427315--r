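---
title: "Delimiting insular species and subspecies with independent lines of evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting insular species and subspecies with independent lines of evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxlines)
```

## The problem and the model

Allopatric island populations routinely show deep mitochondrial divergence
next to marginal nuclear and morphological differentiation. Any single
criterion then gives an unsatisfying answer: mitochondrial distance alone
over-splits, morphology alone under-splits. The lines-of-evidence framework
(Miralles and colleagues' operationalisation of integrative taxonomy,
building on the candidate-species vocabulary of Vieites and colleagues)
treats the three data classes as independent witnesses and converts the
count of supporting witnesses into a rank:

* a candidate (or a guide clade of candidates) supported by **two or more**
  lines of evidence is ranked as a **species**;
* a candidate supported by **exactly one** line against its within-clade
  sibling is a **subspecies**;
* a candidate supported by none is not taxonomically distinct.

`taxlines` implements the three line criteria, the UCS/CCS/DCL candidate
designations, and the hierarchical rank assignment, together with the
supporting machinery (p-distances, haplotype networks, multivariate
morphometrics) and a calibrated simulator so the full pipeline is testable
without any external data.

The assumptions are those of the source workflow: candidates are allopatric
(the sympatry criterion is recorded as not applicable, never as false);
markers are pre-aligned; the mitochondrial line is read from one configured
marker (default `cytb`) and the nuclear line from configured nuclear
marker(s) (default `Rag2`); and the guide clade structure is either supplied
by the user (normally from a multilocus phylogeny) or derived by UPGMA
clustering of pooled mitochondrial distances.

## The three lines, operationally

**mtDNA — independent parsimony networks.** Haplotypes are collapsed from
the alignment (missing data — `N`, IUPAC ambiguity codes and, by default,
gaps — match anything under the default `missing-as-wildcard` policy; a
`strict` policy is available for reproducibility checks). Pairs of
haplotypes are joined when their mutational step distance (Hamming distance
over comparable sites) does not exceed the 95% connection limit, and the
connected components of that graph are the networks. The criterion is
*exclusivity*: a candidate passes when every component carrying its samples
carries no other population's samples. A candidate split over two exclusive
components still passes; a single shared haplotype fails both carriers.

**The connection limit.** Statistical parsimony (Templeton, Crandall & Sing
1992) joins haplotypes only while the connection is credibly free of
superimposed change. We compute the parsimony probability under a
transparent uniform-hits model: j substitution events land independently and
uniformly on the L sites, and the connection is parsimonious when all events
strike distinct sites, giving

$$P_j \;=\; \prod_{i=0}^{j-1}\Bigl(1 - \frac{i}{L}\Bigr),$$

with $P_0 = 1$ by convention. $P_j$ is strictly decreasing in $j$ and
non-decreasing in $L$; the limit $j_{max}$ is the largest $j$ with
$P_j \ge 1 - \alpha$ (default $\alpha = 0.05$). For typical mitochondrial
fragments this estimator is one to a few steps more conservative than the
historical TCS program, whose exact internal estimator was never fully
documented; because small differences in $j_{max}$ can matter near the
boundary, every `ConnectionLimit` carries its full probability table and the
reports print it, so the limit is auditable rather than a black box. In the
island setting the decision is far from the boundary on either side:
within-island pairs sit well below the limit, between-island pairs several
times above it.

```{r}
connectionLimit(700, marker = "cytb")
```

**nDNA — haplotype exclusivity with a slightness guard.** The nuclear line
requires (i) no haplotype of the configured nuclear marker(s) shared with
the comparison set and (ii) a total of at least `minNuclearSubstitutions`
distinguishing substitutions (the minimum step distance between candidate
and comparison haplotypes, summed over markers). The default of 2 encodes
the judgment that a single substitution per marker is not distinctive enough
to carry a line of evidence; setting it to 1 reproduces the strict reading
under which every exclusivity counts. Both knobs are echoed into the rank
rationale strings so a report shows which judgment produced which rank.

**Morphology — fixed diagnosability.** A qualitative character is fixed
between two groups iff the observed state sets are disjoint (and both
non-empty). Metric and meristic characters are quantitative-diagnosable
under the default `range` mode iff the observed ranges are disjoint;
alternatively Amadon's 75% rule is applied in both directions. The 75% rule
is operationalised against the fitted normal central 99% interval
(mean ± 2.576 sd) rather than the raw observed range, because museum series
are small and raw ranges are unstable; the raw-range mode remains available.
Characters flagged `graded` (clinal, e.g. male coloration) or
`sex-limited` are data annotations in the morphology table header and are
excluded from diagnosis unless requested — whether coloration counts is a
property of the dataset, not of the code. Bilateral characters
(`*_L`/`*_R` pairs) are averaged before analysis.

MANOVA (Wilks' lambda with the standard F approximation, complete cases
only, dropped specimens logged) and pairwise Hotelling T² tests describe
overall differentiation; with one character the pairwise test reduces
exactly to the two-sample t-test and the overall test to one-way ANOVA.
CVA is computed as the generalized eigen-decomposition of the between-group
scatter against the pooled within-group covariance, scores scaled to unit
pooled within-group variance. Axis signs are indeterminate: each axis is
normalised so its largest-magnitude loading is positive, and comparisons
with published loadings should be made by rank of |loading| only. A singular
within-group scatter is ridge-regularised with a logged warning.

## Designation and ranking

Candidates distinguishable by molecular characters alone are UCS; a
taxonomically relevant character (or sympatry without admixture, not
applicable here) confirms them as CCS; admixture — proxied by shared
mitochondrial haplotypes with the comparison set — or explicitly slight
differences demote to DCL. Rank assignment then proceeds hierarchically:
guide clades are evaluated against the other clades (two or more lines →
species), and candidates inside a species clade are evaluated against their
siblings (one line → subspecies; two or more → elevation to a separate
species, the "strict application" outcome; none → synonymy). Singleton
clades take their rank directly. Setting any line from false to true can
never lower a rank, and the output is a deterministic, order-invariant
function of the profiles and the grouping.

Where the morphology line should be judged — against all candidates outside
the clade or only against the sister — is genuinely open in the source
workflow; the package defaults to clade scope for standalone profiles and
always uses sibling scope for the within-clade rank decisions, and exposes
`morphologyScope` for the alternative.

## What the simulator emulates

`comoroPreset()` encodes the study conditions of the motivating system:
four island populations in two clade pairs, protein-coding mitochondrial
markers with three divergence tiers (expected pairwise uncorrected
p-distance within populations ~0.5%, chosen so the realized within-island
*maxima* sit near the published "1.2% or less"; between sisters 5.4%/7.7%
for cyt b; between clades 9.5%), a COI marker whose clade divergence
straddles the 8.3% lamprophiid barcoding threshold, a slower 16S-like
marker whose sister divergence falls below the connection limit (so the two
least divergent islands share a network there, as observed), three nuclear
markers carrying exactly one substitution each on different branches
(613 bp Rag2 separating Anjouan; 468 bp PRLR separating the clades; 626 bp
c-mos separating Grand Comoro), and a morphology table mirroring the
published summary statistics: overlapping morphometric and meristic
distributions, a loreal-contact character fixed between but not within
clades, occasional 17 midbody scale rows everywhere except Anjouan, and
graded/sex-limited male coloration characters.

Sequences evolve along the fixed population tree with Poisson branch
substitution counts calibrated so expected pairwise p-distances hit the
tiers; substitutions prefer previously untouched sites (minimising
homoplasy, so p-distance tracks step distance), falling back to multiple
hits with a warning only when a scenario exhausts its sites. No
Jukes–Cantor correction enters anywhere, because the calibrated quantities
are uncorrected p-distances. Per-marker mtDNA alignment lengths are not
printed in the source (only the multilocus total), so the preset uses
representative lengths (cyt b 700, COI 658, 16S 500, ND4 700); sequence
sample sizes (5/6/6/5) are likewise representative, while morphology sample
sizes (6/7/19/11) follow the published table.

What the simulator does *not* emulate: rate heterogeneity among sites,
homoplasy at realistic levels, indel evolution, coalescent genealogical
noise, correlated characters, and measurement error structure. Passing
tests on the preset therefore show that the pipeline's logic recovers the
intended structure under calibrated divergences — not that it is robust to
every property of real data. One consequence of the single-draw Poisson
branch model is sizable seed-to-seed variance in realized divergences; the
pipeline's default guide grouping pools all mitochondrial markers
(length-weighted, mimicking the multilocus concatenation behind published
guide trees) rather than clustering one marker, which makes the grouping
stable in ~98% of seeds. In roughly 2% of seeds a meristic character's
observed ranges are disjoint between the two smallest island samples by
chance, creating a spurious within-clade morphology line — small-sample
behavior the range-disjunction operator genuinely has.

## Numerical choices and degenerate inputs

* Pairwise deletion is the default missing-data policy for distances
  (matching common practice in distance software); complete-case deletion
  against the whole matrix is available. A pair with zero comparable sites
  is an error, not a zero.
* Summaries are reported in percent rounded to one decimal, mirroring how
  such values are printed; raw fractions are retained internally and used
  by all downstream computation.
* The threshold comparison is inclusive at the boundary: a maximum exactly
  equal to the threshold "meets" it.
* Greedy wildcard haplotype merging resolves ties in input order and fills
  missing positions of a representative from later members; the order
  dependence is documented rather than hidden.
* UPGMA agglomeration breaks equidistant merge ties lexicographically on
  the clusters' leading members, making the guide grouping deterministic.
* Hotelling pairs whose group sizes cannot support covariance estimation
  are flagged `untestable` rather than returning silent `NA`s.
* Amadon's rule with zero variance in the comparison sample degenerates the
  99% interval to a point.
* All simulation entry points take explicit seeds (sub-seeds derived per
  marker), restore the caller's RNG state, and are byte-reproducible.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated data:
a 100-replicate end-to-end recovery study (22 sequences across 7 markers of
468–700 bp, 43 morphology specimens per replicate), 500-replicate MANOVA
null calibration, and brute-force cross-checks on alignments of up to 8
haplotypes. These sizes were chosen to put Monte-Carlo error well below the
assertion margins while keeping a full run in minutes on one core.

## Known limitations

The connection-limit estimator is deliberately simple and somewhat
conservative relative to historical TCS output; analyses whose decisions
sit near the limit should inspect the exposed probability table. The nDNA
line inherits the configured marker choice: a different nuclear marker set
can change candidate-level outcomes, as the strict-reading example shows.
Rank assignment presumes a two-level guide structure (clades of
candidates); deeper hierarchies must be analysed level by level. Nothing in
the package performs alignment, model-based tree inference, or
nomenclatural acts.
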