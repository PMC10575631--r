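---
title: "Prioritizing proteins from label-free spectral counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing proteins from label-free spectral counts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralcounts)
```

## The problem

Label-free shotgun proteomics quantifies a protein by its spectral count:
the number of MS/MS spectra assigned to its peptides in one LC-MS/MS run.
In a two-condition comparison -- for example brain organoids derived from
patients with creatine transporter deficiency against organoids from a
healthy donor -- the analyst wants a short, interpretable list of proteins
that are both statistically altered and biologically central to the
perturbed pathways. Spectral counts are awkward inputs for this: they are
sparse (many zeros), overdispersed (variance grows roughly like
$\mu + \phi\mu^2$), and the group sizes are small (typically 8 runs per
condition), so naive t-tests are dominated by unstable per-protein
variance estimates.

`spectralcounts` implements a complete prioritization cascade for this
setting:

1. protein inference from peptide evidence (two-peptide rule) and a
   detection-based inclusion filter;
2. a calibrated generalized-log variance-stabilizing transform;
3. differential abundance with a reproducibility-optimized test statistic
   and permutation inference;
4. absolute gene-set enrichment with leading-edge extraction;
5. a protein-frequency statistic over the leading edges of significant
   pathways, a percentile cutoff, fold-change and spectral-count filters,
   and disease-library over-representation.

Every stage is driven by a planted-truth simulator, so the whole cascade
can be scored against known ground truth without any external data.

## Ingestion and filtering

A protein enters the count matrix only if at least two distinct peptides
were identified for it (`aggregate_proteins()`, `min_peptides = 2`), the
standard guard against one-hit-wonder identifications. A protein is then
kept only if it was detected (count > 0) in at least four samples anywhere
in the matrix (`variation_filter()`, `min_detected_samples = 4`). The
detection filter is applied globally, not per condition: a protein
reproducibly present in only one group is exactly the kind of candidate
the comparison should keep.

## Normalization

`glog_normalize()` separates two concerns.

**Calibration.** Each sample $j$ is mapped onto a common scale by an
affine fit $q_j \approx o_j + s_j\,q_{\mathrm{ref}}$ of its nonzero-count
quantiles on a reference quantile curve, fitted robustly
(`MASS::rlm`). The reference is the across-sample *median* of the
per-sample quantile curves, so a single aberrant run cannot drag the
anchor, and rescaling one sample changes (essentially) only that sample's
own $(o_j, s_j)$. Calibrated values are $x' = (x - o_j)/s_j$.

**Generalized log.** Calibrated values are transformed by
$$h(x') = \operatorname{asinh}\!\left(\sqrt{\phi}\,x'\right)/\sqrt{\phi},$$
where $\phi$ is the overdispersion of the count model
$\operatorname{Var} = \mu + \phi\mu^2$, estimated from the calibrated
matrix by a trimmed-mean moment fit of $(v_i - m_i)/m_i^2$ over rows with
adequate abundance. The map is linear below the crossover abundance
$1/\phi$, where shot noise dominates and a log would explode the variance
of small counts, and logarithmic above it, where the $\phi\mu^2$ term
dominates and log-scale variance is constant at $\phi$; the outer
$1/\sqrt{\phi}$ puts the high-abundance standard deviation near 1. It is
smooth and strictly increasing on all reals, so the occasional slightly
negative calibrated value is handled without special cases and raw count
order is preserved within each sample.

We considered the textbook count transform
$2\phi^{-1/2}\operatorname{asinh}\sqrt{\phi x}$, but its infinite slope at
zero amplifies calibration jitter in the many near-zero cells of spectral
count data; on simulated negative-binomial matrices the smooth family
above keeps the regression slope of row SD on row mean within $\pm 0.05$
(the package's flatness criterion) at dispersions up to about 0.5, which
is where typical spectral-count data live. At dispersion $\gtrsim 1$ the
low-count discreteness is too coarse for any single two-parameter
transform and a residual trend of order +0.1 remains; this is a known
limitation. Under strong planted signal the moment estimate of $\phi$
absorbs some between-group variance and overshoots; this only compresses
the transform slightly and does not affect ranking.

## Differential abundance

The test statistic family is
$$d_g = \frac{|\bar{x}_{g,1} - \bar{x}_{g,2}|}{\alpha_1 + \alpha_2 s_g},$$
with $s_g$ the pooled standard error. $(\alpha_1, \alpha_2) = (0, 1)$ is
the absolute ordinary t statistic; $(1, 0)$ is the absolute mean
difference. Instead of fixing the member of the family a priori,
`rots_optimize()` chooses $(\alpha, k)$ to maximize the reproducibility
Z-score
$$Z_k(\alpha) = \frac{R_k(\alpha) - R_k^0(\alpha)}{\mathrm{sd}_k(\alpha)},$$
where $R_k$ is the mean overlap of the top-$k$ lists across $B$ bootstrap
pairs (samples resampled with replacement within each condition,
preserving group sizes), and $R_k^0$ is the same quantity after permuting
the group labels. Ties are broken toward smaller $\alpha_1$, then smaller
$k$. The default grids are $\alpha_1 \in \{0, 0.01, 0.05, 0.1, 0.5, 1, 2,
5\}$ with $\alpha_2 = 1$, plus the $(1, 0)$ member, and $k \in \{25, 50,
100, 200, 400\}$, with $B = 500$ bootstrap pairs and $P = 1000$
permutations; tests and the bundled study use smaller $B$ and $P$ (50-100)
after checking that the selection and the p-value calibration are stable
at those sizes.

Significance is assessed by group-label permutation with a *pooled* null:
$$p_g = \frac{1 + \#\{d^0 \ge d_g\}}{1 + nP},$$
pooling the null statistics of all $n$ proteins across all $P$
permutations, with add-one smoothing so no p-value is ever 0. When the
design admits at most $P$ distinct label assignments the implementation
enumerates all of them exactly once, making the small-sample test exact.
The permutation FDR at threshold $d_g$ is the mean per-permutation count
of null statistics $\ge d_g$ divided by the observed count $\ge d_g$,
clipped to $[0,1]$ and made monotone along the ranking. Proteins are
selected at $p < 0.05$ (strict) and $\mathrm{FDR} \le 0.25$ (inclusive).

Two calibration facts drive the test suite: under a null simulation the
fraction of $p < 0.05$ sits in the binomial band $[0.035, 0.065]$ at
2,000 proteins, and planted shifts of 2 pooled SD in an 8 vs 8 design are
recovered with recall above 0.9 at realized false-discovery proportions
near 0.2. The pooled null assumes rows are exchangeable after
normalization; on strongly overdispersed counts with many planted
effects, the realized false-discovery proportion of the *count-scale*
study can exceed the nominal FDR bound even though the type-I error stays
calibrated -- the filter cascade downstream is what restores precision
(see the end-to-end numbers in the README).

## Absolute GSEA

Proteins are ranked by $|d|$ (descending; ties break by protein id, or by
a recorded seeded shuffle). Ranking by magnitude rather than signed
statistic is what makes the analysis "absolute": a pathway whose members
move coherently in *both* directions still concentrates at the top of the
list. For a set $S$, walking down the ranked list accumulates
$|r_i|^p / \sum_{j \in S} |r_j|^p$ at members and $-1/(N - |S|)$ at
non-members; the enrichment score is the running-sum value of maximal
absolute deviation ($p = 1$ by default; $p = 0$ recovers the classical
Kolmogorov-Smirnov statistic). The positive and negative extrema are
small rationals that can tie in magnitude exactly, so the implementation
takes the *earliest* peak, judged within $10^{-9}$ so floating-point
noise cannot flip the reported sign.

The null distribution is generated by gene-label permutation: $P$ random
sets of the same size. With four-ish samples per group, sample
permutations are far too few to resolve $p < 0.05$; gene-label
permutation stays well-defined at any design size (a sample-permutation
mode is deliberately not offered for this reason).
$\mathrm{NES} = ES / \overline{|ES^0_{\text{same sign}}|}$ and
$p = (1 + \#\{|ES^0| \ge |ES|\})/(1 + P)$. Sets overlapping the ranked
universe in fewer than 3 proteins are skipped with a warning. Nominal
p-values (not FDR-adjusted across sets) at $p < 0.05$ define the
significant pathways, mirroring common practice for this cascade; the
frequency statistic downstream is itself a cross-pathway aggregation, so
per-set multiplicity correction would be redundant for its purpose.

The *enriched component* (leading edge) of a significant set is its
members at or before the running-sum peak (for positive ES; at or after
it for negative ES) -- the proteins actually driving the enrichment. An
alternative reading would take all set members present in the data; the
leading edge is the default because it is the subset with evidential
support, and the other reading is recoverable by the caller from the set
definitions.

## Prioritization cascade

`frequency_table()` counts, for every protein, the significant pathways
(pooled over collections and contrasts) whose leading edge contains it --
a centrality measure over the perturbed pathway landscape.
`percentile_select()` keeps proteins at or above the nearest-rank 90th
percentile of the frequency distribution; nearest-rank with inclusive
ties is deterministic and conservative (it never drops a protein that
ties the threshold). Pooling across collections (rather than per
collection) is the default because the frequency is meant to measure
recurrence across *all* studied gene sets.

`fold_change()` reports the count-scale ratio of group means under the
signed-ratio convention ($r$ if $r \ge 1$, else $-1/r$), with each group
mean floored at one spectrum -- a mean below one spectral count is
background, and the floor makes ratios against near-absent proteins
finite without distorting well-measured ones. Candidates must satisfy
all three filters: top-percentile frequency, $|fc| \ge 3$ (inclusive, so
a protein at exactly 3-fold passes), and a total spectral count of at
least 10 across the contrast samples (inclusive). The filters are
independent flags, so their order is immaterial; the table records each
flag separately so the funnel can be audited.

Finally, `term_overrepresentation()` tests the candidate list against
disease-annotation libraries by the one-sided Fisher exact
(hypergeometric tail) test. The universe is the set of *quantified*
proteins after filtering, not the genome: undetectable proteins could
never have entered the query, and using the genome would inflate every
p-value. `disease_frequency()` then counts, per candidate, the
significant terms containing it; candidates with at least one term form
the clinically related subset.

## The simulator

`simulate_counts()` draws protein baseline means log-normally
(median 8 spectra, log-sd 1.2 -- chosen to reproduce the sparse,
low-count regime of a 16-run organoid study quantifying ~4,000 proteins),
negative-binomial counts with dispersion 0.5, and independent thinning
(detection probability 0.85) for the zeros. A 10% subset of proteins is
shifted by 2 log2 units (4-fold) up or down in every patient condition.
`simulate_peptides()` partitions each protein's counts multinomially over
1-5 peptides, so protein inference can be tested as an exact round trip;
`simulate_genesets()` plants 10% of 500 sets with ~70% of members drawn
from the differential proteins. The planted truth (differential ids,
directions, planted set names) is written as a JSON sidecar so any run
can be scored afterwards.

What the simulator does *not* emulate: shared peptides between proteins
(each peptide belongs to one protein), structural zeros tied to biology
rather than detection, correlated proteins within complexes, batch
effects, and run-order drift. Passing the end-to-end tests therefore
shows the cascade recovers planted signal under idealized independence
assumptions, not that it is robust to every pathology of real data.

## Numerical choices and degenerate inputs

* All randomness flows from one root seed through named substreams
  (`substream_seed()`), so stages can be re-run independently yet
  reproducibly, and two runs with one seed are byte-identical.
* $\alpha_1 = \alpha_2 = 0$ is rejected (degenerate denominator); a zero
  pooled SE with $\alpha_1 = 0$ yields $d = 0$ when the mean difference
  is also zero, `Inf` otherwise.
* The FDR curve is made monotone by a suffix-minimum along the ranking;
  p-values are monotone in $d$ by construction of the pooled null.
* An all-zero sample cannot be calibrated and raises an error naming the
  problem; empty evidence tables, empty frequency tables, and empty
  candidate lists propagate as empty results rather than errors wherever
  a downstream stage can still proceed.
* Gene sets equal to the whole universe are rejected (the miss increment
  would divide by zero).
* In tests, the Poisson-limit moment check uses 16 samples per group:
  with 8 per group, the chi-square spread of a sample variance over 16
  observations alone would place ~7% of genuinely Poisson rows outside
  the [0.5, 2] variance-ratio band, so the band at 95% coverage is only
  diagnostic at larger replicate counts.

## Problem sizes used by the tests

The test suite runs the full default study (4,000 proteins, 16 samples,
500 gene sets) twice for the determinism and recovery checks, with
$B = 50$-$100$ bootstrap pairs and $P = 60$-$1000$ permutations depending
on the check; statistic calibration uses 2,000-protein designs with 100
permutations. These sizes keep the whole suite within a few minutes while
leaving the binomial/Monte-Carlo tolerances meaningful; they are stated
here so a reader scaling the package up knows which constants were
exercised.

## Known limitations

* The FDR reported per protein is a permutation estimate; its realized
  false-discovery proportion can exceed the nominal level on strongly
  overdispersed count data (see above). Interpret it as a ranking
  device, as the cascade does, rather than a guarantee.
* Exact reproduction of any particular historical analysis of this kind
  is out of scope: peptide-spectrum matching, search-engine scoring, and
  the precise variant of the reproducibility optimization used elsewhere
  are not specified tightly enough to replicate number-for-number.
* Disease-library content is user-supplied; the package tests the
  procedure (Fisher tails, frequency counting) against oracles, not the
  biological adequacy of any particular library.
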