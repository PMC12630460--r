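---
title: "Measuring phytochemical diversity with phytodiv: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phytochemical diversity with phytodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

phytodiv quantifies the chemical diversity of groups of plant compounds —
typically the compounds reported from the species native to one botanical
region — and relates it to the phylogenetic diversity of the species
producing them. This vignette explains the measures, the assumptions behind
them, the knobs that matter, and what the bundled synthetic-data generator
does and does not emulate.

## The data model

The atomic record is a *compound occurrence*: an accepted species name, a
standardized structure string, one of the seven NPClassifier biosynthetic
pathways (fatty acids, polyketides, shikimates-phenylpropanoids, terpenoids,
alkaloids, amino acids/peptides, carbohydrates), and the set of WGSRPD
Level-3 regions the species is native to. Occurrence data of this kind are
presence-only: they say a compound has been reported from a species, never
how abundant it is. Every design choice downstream follows from that
constraint.

Records fan out to *all* native regions of their species — the only reading
consistent with grouping compounds "by the native distributions of species"
when per-region occurrence evidence is unavailable. Within a region,
compounds are unique by standardized structure; a structure arriving with
two different pathway labels keeps the first and warns, since a silent
majority vote could mask upstream curation errors.

Structure standardization reduces multi-fragment strings (salts, solvates)
to the fragment with the most heavy atoms. Ties break to the
lexicographically smallest canonical fragment so results are deterministic.
Canonicalization itself is pluggable (`ob_canonicalizer()` provides an Open
Babel backend); the default is the identity, which keeps the package free of
a hard chemistry dependency and is exactly right for the synthetic structure
identifiers the generator emits.

## Compound-level disparity

With pairwise Tanimoto distances $d_{ij} = 1 - |A_i \cap A_j| / |A_i \cup
A_j|$ between fingerprint bit sets, the package reports, per region with $N$
compounds:

$$\mathrm{FAD} = \sum_{i=1}^{N}\sum_{j=1}^{N} d_{ij}, \qquad
\mathrm{MFAD} = \mathrm{FAD}/N, \qquad
\mathrm{APWD} = \mathrm{FAD}/(N^2-N).$$

The double sum runs over *all ordered pairs* (the diagonal contributes
zero), so FAD is twice the unordered-pair sum — this is implemented exactly
as defined, which matters when cross-checking against packages that sum each
pair once. FAD grows with both richness and disparity; MFAD partially
corrects for group size; APWD is the mean pairwise distance, a pure
disparity measure in $[0,1]$. A one-compound group has FAD = MFAD = 0 and an
explicitly missing APWD. Functional Hill numbers are deliberately absent: on
presence-only data with equal weights $1/N$ they reduce to functions of FAD
and add nothing.

Two empty fingerprints are placed at distance 0 (with a warning): nothing
distinguishes them, and treating them as maximally distant would reward
missing data with apparent diversity.

## Pathway-level diversity

Collapsing compounds onto the seven pathways gives counts from which
relative abundances $p_i$ can be formed, enabling abundance-style metrics:
Shannon $H = -\sum p_i \ln p_i$, Gini–Simpson $G = 1 - \sum p_i^2$, and
Pielou evenness $J = H/\ln P$ with $P$ the number of pathways present. $J$
is undefined at $P = 1$ and is reported as an explicit null, which
propagates through the CSV output as an empty cell rather than a zero — a
region dominated by one pathway is *uneven*, but a region where only one
pathway was ever sampled is *uninformative about evenness*.

Because sampling effort varies enormously between regions, the package also
reports the coverage-adjusted (bias-controlled) Shannon estimator

$$H_{bc} = -\sum_{i=1}^{P} \frac{p_i C \,\ln(p_i C)}
{1-(1-p_i C)^{N}}, \qquad C = 1 - \frac{f_1}{N},$$

where $f_1$ counts pathways observed exactly once. Terms with $p_i = 0$ are
omitted throughout (the $x \ln x \to 0$ convention), and the boundary case
$p_iC = 1$ is evaluated by the same limit. When every pathway is a singleton
($C = 0$) the estimator degenerates and is reported null, mirroring the
handling of $J$. Doubleton-based coverage estimators exist but are not
implemented; on data of this shape they move the estimates very little.

## Rarefaction

As an alternative control for effort, every metric is also computed rarefied:
the mean over 1000 subsamples of 7 compounds drawn without replacement
(subsampling a finite deduplicated compound set with replacement would
manufacture duplicates the data model forbids). The subsample size equals
the number of pathway classes — the smallest size at which all seven could
in principle co-occur — and is the reason regions with fewer than 7
compounds are discarded up front. For FAD, each unordered pair survives
subsampling with probability $m(m-1)/(N(N-1))$, so the rarefied mean
estimates $m(m-1)\cdot\mathrm{APWD} = 42\cdot\mathrm{APWD}$; this
combinatorial identity is one of the package's standing self-checks.

One subsample set is shared by all metrics within a region (redrawing per
metric would cost more and change no mean); replicates where a metric is
undefined are dropped from that metric's mean, with the null fraction
reported. Each region draws from its own random stream, derived from the
master seed and a hash of the region code, so results never depend on the
order in which regions are processed.

## Phylogenetic diversity and its decoupling from richness

Faith's PD of a region is the total branch length of the minimal subtree
spanning the region's species. By default the subtree is rooted at the
species' most recent common ancestor — a single species has PD 0 — because
whether to charge a group for its stem lineage back to the tree root is a
modelling choice, not a fact; `include_root = TRUE` selects the other
convention, and the choice is echoed in the run metadata.

PD and species richness are strongly coupled, so the package also reports
SR-independent PD: the residual of PD after a LOWESS fit (locally linear,
robustified; smoothing fraction 2/3 with 3 robustifying iterations — the
classical defaults of Cleveland's method as implemented in `stats::lowess`)
of PD on SR across regions. Residualization refuses to run on fewer than 10
regions, where the residuals would mostly reflect the fit's own noise. Tied
SR values receive identical fitted values.

## Association analysis and outlier flagging

Metric columns are normalised with the Yeo–Johnson transformation, the power
$\lambda$ chosen by maximising the Gaussian profile log-likelihood over
$[-5, 5]$ with Brent's method. Associations are Spearman rank correlations
with two-sided p-values — exact by full permutation enumeration below 10
pairs, the usual t-approximation otherwise — with pairwise deletion of
nulls so that missing $J$ values do not shrink unrelated comparisons.
Because the transformation is strictly monotone, Spearman correlations are
identical before and after it (a property the test suite asserts to
1e−12); the transformed scale matters only for the LOWESS outlier step,
which is why normalisation precedes it. Raw p-values are the primary
output, matching common practice for correlation panels; a Holm-adjusted
column is emitted alongside for convenience.

Outlier flagging fits a LOWESS curve of each metric on PD and flags regions
whose residual z-score (sample SD) exceeds 2 in absolute value: "high"
regions are more chemically diverse than their evolutionary history
predicts, "low" regions less. If the residual spread is numerically zero the
step reports no outliers rather than amplifying rounding noise.

## What the synthetic generator emulates — and what it does not

`simulate_study()` produces occurrence tables, distribution tables,
fingerprints and a Yule tree with the statistical signatures the analysis
assumes:

* **Compounds per species** follow Fisher's log-series (θ = 0.93 by
  default), chosen because compiled phytochemical datasets are dominated by
  species with one to three reported compounds next to a long tail of
  intensively studied taxa; at the default, about 61% of species carry ≤ 3
  compounds. A zero-truncated negative binomial is available
  (`cps_dist = "ztnb"`) for less extreme skew; no parameterization of it
  reproduces both the ≤ 3 mode and the long tail simultaneously, which is
  why the log-series is the default.
* **Pathway frequencies** are globally uneven (terpenoids and alkaloids
  dominating), and each region draws its own mixture from a Dirichlet
  centred on the global one. The concentration parameter is the evenness
  dial: large values give even, mixture-like regions, small values give
  spiky single-pathway regions, and mean region evenness increases
  monotonically with it.
* **Regions** get lognormal weights, so a few mainland-like regions absorb
  most species and many island-like regions stay small — exercising the
  minimum-group-size filter. Codes are drawn from the bundled WGSRPD list so
  the validator path runs warning-free.
* **Fingerprints** are sparse random bit sets (64 of 2048 bits). They carry
  no chemical information, which has a visible consequence: Tanimoto
  distances concentrate near $1 - $ (expected bit overlap), so synthetic
  APWD values sit in a narrow high band. Passing tests on synthetic data
  therefore demonstrate the *machinery* (identities, estimators,
  determinism, rank relationships), not the chemical realism of any
  particular APWD value. Real analyses should supply fingerprints from a
  chemistry toolkit via the fingerprinter hook.

The generator also does not model biogeographically realistic ranges,
phylogenetic signal in chemistry (a species' compounds are independent of
its position in the tree), or correlated sampling effort between neighbour
regions.

## Numerical and scale choices

Default problem sizes were picked so the whole pipeline stays interactive:
the standard scenario (500 species, 30 regions, 3000-compound library, 1000
rarefaction replicates) runs in seconds, and the distance matrix — the only
$O(N^2)$ object — is built per region from a sparse incidence
cross-product and released before the next region. The test suite uses
smaller scenarios (tens to low hundreds of species, 30–200 rarefaction
replicates) except where a contract is about the full default, and sizes
its Monte-Carlo assertions (replicate counts, concentration levels) so the
expected effects exceed three standard errors of the estimator under test.

Other conventions: all entropies are in nats; coverage, APWD, $G$ and $J$
are unitless fractions; PD is in the branch-length units of the input tree.
Degenerate inputs are handled by explicit rules stated above (nulls for
undefined metrics, warnings for empty fingerprints and unknown region
codes, hard errors only where silent continuation would corrupt results —
duplicate tree labels, constant vectors offered for normalisation, groups
smaller than the subsample).

## Known limitations

* Presence-only data cap what any evenness or entropy statistic can mean;
  $H$, $H_{bc}$ and $G$ here measure the spread of *reported* compounds over
  pathways, which conflates chemistry with study effort. The
  coverage-adjusted estimator and rarefaction mitigate but cannot remove
  this.
* The Level-3 code list bundled for validation is a curated subset; unknown
  codes are accepted with a warning by design, so validation is advisory,
  not authoritative.
* LOWESS residualization removes the SR trend only as well as a smoother
  can; with strong curvature and few regions, residual means can drift from
  zero, and residual-based outlier flags inherit that.
* The exact Spearman p-value enumerates all $n!$ rank permutations and is
  therefore limited to $n < 10$, precisely the range where the
  t-approximation is least trustworthy.
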