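---
title: "Methods: phylogroup quantification, enterocolitypes, and virulence scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogroup quantification, enterocolitypes, and virulence scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colitype)
library(dplyr)
```

`colitype` analyses the internal structure of commensal *Escherichia coli*
populations: the relative abundance of the four main phylogroups (A, B1,
B2, D) measured by phylogroup-specific quantitative PCR in fecal samples,
the classification of samples into recurring abundance patterns
("enterocolitypes"), the ordination of categorical sample descriptions by
correspondence analysis, and the virulence-gene content of B2 strains.
This vignette records the models, the tunable parameters, and the design
choices behind each stage.

## The measurement model and its inversion

A sample yields five absolute counts (CFU per gram of feces): a 16S-based
total *E. coli* count and four probe counts. The B1, B2 and D probes target
their phylogroup directly. Phylogroup A has no specific probe; its
proportion is defined by subtraction,

$$p_A = 1 - p_{B1} - p_{B2} - p_D, \qquad p_g = \frac{\mathrm{count}_g}{\mathrm{total}},$$

and the yjaA probe, which amplifies the A1 subgroup together with B2,
recovers the subgroup split as $p_{A1} = (\mathrm{yjaA} - B2)/\mathrm{total}$
and $p_{A0} = p_A - p_{A1}$.

Because each probe is measured with independent error, the probe sum can
exceed the total. `compute_proportions()` therefore:

* clamps a negative $p_A$ (or $p_{A1}$) to 0 and flags the sample
  (`flag_clamped`); closure $\sum_g p_g = 1$ is guaranteed (to $10^{-9}$)
  only for unflagged samples;
* caps any single probe proportion above 1 and flags it (`flag_capped`);
* treats a zero total count as "no *E. coli* detected"
  (`ecoli_present = FALSE`, proportions `NA`) — a valid observation that is
  excluded from composition analyses, not an error. A zero total combined
  with non-zero probe counts, by contrast, is a malformed record and is
  rejected.

Detection is compositional, not absolute: a probe-based phylogroup counts
as detected from 0.1 % of the population upward, phylogroup A — measured
only through the subtraction — from 15 % upward. Both thresholds are
inclusive ($\ge$), reading the threshold as the smallest detectable value.
Undetected phylogroups keep their numeric proportion but are categorized
"absent" downstream. `ct_to_count()` exposes the standard-curve formula
$\mathrm{count} = 10^{(CT - b)/m}$ ($m < 0$) for callers who start from
cycle thresholds; no instrument files are parsed.

## Categories, classes and the enterocolitype rule

Per-sample phenotypes use fixed boundary conventions:

| variable | rule |
|---|---|
| abundance category | dominant $> 0.50$ (strict); intermediate $[0.10, 0.50]$ (closed); minor $< 0.10$; absent = undetected |
| CFU class | high $> 10^7$ (strict); low $< 10^6$ (strict); intermediate otherwise (both boundaries inclusive) |
| diversity class | high iff all four phylogroups detected |
| B2 exclusivity | $p_{B2} > 0.90$ (strict) |

The five enterocolitypes were originally delineated as clusters of an
ordination over host groups. As a reusable per-sample operation this
package defines them by a deterministic rule — the dominant phylogroup
crossed with the host domain, with the exclusivity test taking precedence
in humans:

* human and $p_{B2} > 0.9$, or human and B2 dominant → **E4**;
* human and A dominant → **E5**;
* animal and B2 dominant → **E1**; B1 dominant → **E2**; A dominant →
  **E3**;
* otherwise **unassigned** (including a dominant D, which defines no type).

CFU class and diversity are reported alongside but deliberately do not
gate the assignment: they are characteristics of the types, not criteria,
and using them as criteria would make the rule reject borderline samples
that the dominance pattern classifies cleanly.

## Indicator tables and correspondence analysis

`build_indicator_table()` encodes records as 0/1 variables in a fixed,
documented order so tables are byte-reproducible. The 32-column animal
layout comprises 14 phylogroup-category variables (DA, DB1, DB2, DD, IA,
IB1, IB2, ID, MB1, MB2, MD, AB1, AB2, AD), the three CFU classes, the two
diversity classes, the nine animal species, the two habitats and the two
diets. There is intentionally no minor-A or absent-A column: phylogroup A
below 10 % is not resolvable through the 15 % subtraction threshold, so
such samples simply contribute no 1 in the phylogroup-A variable group
(every other variable group has exactly one 1 per row, which the tests
assert). The 33-column strain layout encodes the three origin groups, the
eight B2 subgroups plus "unassigned", the 20 virulence genes, and a
virulence score of 9 or more.

`fit_ca()` is a from-scratch correspondence analysis: with
$P = X/n$, row masses $r$ and column masses $c$, it decomposes the
standardized residuals

$$S_{ij} = \frac{P_{ij} - r_i c_j}{\sqrt{r_i c_j}}$$

by SVD rather than eigen-decomposing a distance matrix — numerically
stabler and identical in its axes. Total inertia is $\sum S_{ij}^2$, which
equals the Pearson $\chi^2$ of the table divided by $n$; the test suite
verifies this identity against an independently coded $\chi^2$ oracle on
hundreds of random tables. Numerical conventions: the trivial axis of the
uncentred problem never appears (centring removes it); singular values
below $10^{-12}$ of the largest are truncated; the number of axes is capped
at $\min(n, p) - 1$; each axis's sign is fixed by forcing its
largest-magnitude row coordinate positive, so repeated fits are identical.
A table of perfect independence yields a valid zero-axis result; all-zero
rows or columns are rejected by name. Both principal ("symmetric map") and
standard coordinates are returned; `project_supplementary()` places
held-out rows via the transition formula (row profile × column standard
coordinates), under which fitted rows reproduce themselves and the
column-mass profile lands at the origin.

## Virulence scoring and group comparisons

The virulence score of a strain is the number of genes present among the
20 tested; a group's mean score therefore equals the sum of its per-gene
prevalence fractions, an identity the tests check exactly. The packaged
reference prevalences (`reference_prevalences()`) use the gene nomenclature of
the published prevalence table (papGIII, kpsMTII, aer). Of its three
columns only the animal column (n = 13) is internally consistent: its
printed percentages reconstruct to integer counts whose mean is exactly
83/13 = 6.38, whereas the two human columns' percentage sums (10.20 and
9.20) do not reproduce the printed summary scores (10.45 and 9.40) — the
printed values may include separately scored adhesin alleles. The package
therefore anchors its checks on the animal column only, and computes means
(the $\pm$ notation and the exact animal-column match indicate the printed
"median" scores are means). `sd_score` uses the $n-1$ denominator.

For 2×2 prevalence comparisons the default inference is the exact
hypergeometric test — group sizes of 10–20 strains are too small for the
$\chi^2$ approximation — with the $\chi^2$ statistic (continuity
correction switchable) reported alongside. The exact two-sided p-value
sums the probabilities of all tables with the observed margins that are no
more likely than the observed one; the tests verify it against brute-force
enumeration on every 2×2 table with group sizes up to 15. Score vectors
are compared with the two-sided Wilcoxon rank-sum test (two groups) or the
Kruskal–Wallis test (more); when every value is tied there is nothing to
rank and p = 1 by convention. Per-gene p-values are reported uncorrected,
matching how such tables are conventionally published; callers can apply
`p.adjust()` downstream.

## The synthetic-data generator

`simulate_cohort()` draws, per community template: a host species
(uniformly from the template's species pool; habitat and diet follow from
a fixed lookup), a latent composition from a Dirichlet distribution with
mean equal to the template composition, a total load from
$10^{\mathcal N(\mu, \sigma)}$ in log10 CFU/g, and measured counts in
which every probe (including the 16S total) is multiplied by an
independent $10^{\mathcal N(0, s)}$ error and probe counts below 0.1 % of
the measured total are censored to zero. The yjaA count is A1 + B2 before
noise. Defaults:

| parameter | default | rationale |
|---|---|---|
| template compositions | E1 (.15,.05,.70,.10), E2 (.15,.60,.05,.20), E3 (.60,.20,.05,.15), E4 (.02,.01,.95,.02), E5 (.60,.15,.10,.15) | illustrative mixtures realizing each type's dominance pattern; configurable, **not** measured cohort values |
| log10 CFU mean ± sd | E1 5.5 ± 1.0, E2 6.5 ± 0.5, E3 7.3 ± 0.5, E4/E5 7.89 ± 0.52 | the published low/intermediate/high load gradient; the human values are the published human load |
| Dirichlet concentration | 200 | gives the dominant group a between-host SD of ≈ 0.035 — clear dominance structure with realistic spread |
| measurement noise $s$ | 0.03 log10 units | ≈ 0.1-cycle replicate SD on a −3.32-slope curve, typical intra-assay qPCR reproducibility |
| A1 fraction of A | 0.5 | the A0/A1 split is unquantified in the source data; configurable |

Randomness uses one root seed and per-sample substreams derived by a
Lehmer-hash of (seed, template index, sample index, stream), so the same
seed reproduces a cohort bitwise and enlarging a cohort never perturbs
existing samples. A template mean with an exact zero pins that phylogroup
at zero (the Dirichlet dimension is dropped).

What the generator emulates: between-host compositional spread around
type-specific mixtures, the load differences between types, multiplicative
qPCR error and its censoring at the limit of detection, and
marginally-correct Bernoulli gene panels. What it does not: clonal
substructure within phylogroups, the minority phylogroups C/E/F and
non-*E. coli Escherichia* that a real assay misassigns, correlation
between genes on shared pathogenicity islands, and any association between
composition and gene content. Passing recovery tests therefore show that
the pipeline inverts its own stated measurement model — not that real
cohorts would classify as cleanly.

## Problem sizes and verification

The test suite regenerates every fixture in code. The headline checks run
at: 500 samples per enterocolitype template for recovery (zero-noise
recovery ≥ 99 %, default-noise ≥ 90 %; observed ≈ 99.8 % and ≈ 97 %),
200 random tables for the correspondence-analysis oracle ($10^{-8}$
tolerance), exhaustive 2×2 enumeration up to group size 15 ($10^{-12}$),
the 13-strain reconstructed animal panel for the 6.38 mean score (2
decimals), and 1000 null simulations for rank-test calibration (within 3
binomial SE of $\alpha = 0.05$). `scripts/acceptance.R` recomputes the
same quantities from a fresh seed.

## Limitations

* Enterocolitype assignment is a deterministic dominance rule, not a
  clustering; samples with no dominant phylogroup stay unassigned rather
  than being attributed to the nearest type.
* The 15 % subtraction threshold makes minor/intermediate phylogroup A
  partly unobservable by design; the indicator coding reflects this
  asymmetry.
* The packaged 43-strain panel is synthetic (marginals only); conclusions
  about gene co-occurrence cannot be drawn from it.
* Proportions are retained at full precision throughout; percentages are a
  display concern only.
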