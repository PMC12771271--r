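---
title: "Anchoring variant-set association statistics on a genomic axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring variant-set association statistics on a genomic axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(archipelago)
```

## The problem

Single-variant GWAS results live naturally on a Manhattan plot: each test has
a chromosome and base-pair position. Variant-set association tests (VSATs) —
SKAT-O on a gene, a burden test on a protein pathway, a DeepRVAT gene score —
return one P value per *collapsed group* of variants and therefore have no
intrinsic genomic coordinate. Plotted alone they can only be ranked by
association strength or by some arbitrary set ordering, which discards all
positional information and makes it hard to see how a set-level signal
relates to the individual variants beneath it.

This package assigns every set-level P value a *representative* genomic
coordinate and draws both layers on one axis, with edges linking each
significantly enriched set to its constituent variants. A third, optional
layer carries per-variant annotation P values combined by the Cauchy
combination test (ACAT), the STAAR-style hierarchy.

## The anchoring model

Let the genome axis place chromosomes end to end: a variant on chromosome
$c$ at position $b$ gets the cumulative coordinate
$x = \mathrm{offset}(c) + b$, where $\mathrm{offset}(c)$ is the summed
extent of all preceding chromosomes plus any inter-chromosome padding
(default 0 bp — contiguous blocks). Two extent conventions are offered:

* **observed** (default): extent of $c$ is the largest position seen on $c$
  in the data, so the axis adapts to the input;
* **fixed**: reference lengths (hg19 or hg38 tables are bundled), so axes
  from independently produced files are directly comparable.

A set $S$ with member variants at cumulative coordinates
$x_1, \dots, x_k$ is anchored at their arithmetic mean
$\bar{x}_S = \frac{1}{k}\sum_i x_i$. The anchor always lies inside the
closed interval of its members' coordinates; a set built mostly from
chromosome 1 variants lands near its chromosome 1 members, while a
genome-wide set lands near the centre of the axis. Members referenced by
the membership table but absent from the variant table are excluded from
the mean with a warning count (real summary-statistics and membership
files routinely disagree); a set with no resolvable member is dropped with
a warning rather than failing a biobank-scale run, unless a hard error is
requested.

## Ranked dispersion

Anchors of genome-wide or regionally overlapping sets can collide near the
axis centre. Dispersion separates set points while keeping the left-to-right
order of their anchors. The strongest association has priority: sets are
processed in ascending P order (ties broken lexicographically by set ID so
layouts are reproducible), and the globally strongest set always keeps its
exact anchor.

The placement rule fixes the left-to-right order first (anchor order; for
exact anchor ties the weaker point is sided toward the part of the axis
with more free span, toward $+\infty$ on an exact tie). Each point is then
placed at its anchor clamped into the feasible interval implied by the
already-placed points, where a placed point $j$ ranks $r$ order-steps away
reserves $r \cdot \texttt{min\_gap}$ of room. Reserving a gap *per
intervening rank step* — rather than a single gap against each placed
neighbour — is what guarantees the feasible interval is never empty and
that the finished configuration has every pairwise gap at least
`min_gap`. A naive "move the minimal distance from the nearest placed
point" rule can trap a later point between two placed neighbours that are
between one and two gaps apart, with no feasible position left.

`min_gap` defaults to 0.5% of the axis span, capped at
$\mathrm{span} / (m - 1)$ for $m$ sets: an all-pairs separation of 0.5% is
geometrically impossible once more than 200 sets share the axis, so the
cap keeps the default feasible at any density while preserving the
intended visual separation for sparse data. An explicitly requested
infeasible gap raises an error that suggests the largest feasible value.
Two other modes are available: `none` (identity — anchors are authentic
genome positions) and `even` (equal spacing over the anchor range in
anchor-rank order, for heavily clustered data).

## Significance and edges

The threshold is Bonferroni over the number of set tests,
$\alpha / n_{\text{sets}}$ (e.g. $0.05/250 = 2\times10^{-4}$), the only
multiple-testing procedure offered because it is the one the visualised
workflows use; an explicit threshold can be substituted. Comparison is
strict: a set exactly at the threshold is *not* flagged. Edges link each
set point to its member variant points; by default they are drawn only for
the significantly enriched sets, because in dense plots the full edge set
(one per set-member pair, e.g. 5,000 edges for the default synthetic data)
is unreadable. Both behaviours are exposed.

An alternative reading of "mapping the set position to each variant" —
copying the set's x onto its member variants — is available as
`copy_set_x_to_variants = TRUE`, off by default; only the edge
interpretation matches the layered figure.

## The ACAT annotation layer

For annotation-informed tests, each variant's P value is itself an
aggregate of annotation-layer P values. The combination is the weighted
Cauchy test:

$$T = \frac{\sum_i w_i \tan\{(0.5 - p_i)\pi\}}{\sum_i w_i}, \qquad
p_{\mathrm{ACAT}} = \frac{1}{2} - \frac{\arctan T}{\pi},$$

valid under arbitrary dependence. The implementation uses the exact Cauchy
tail, not the small-p approximation, so combining $k$ identical values
returns that value to machine precision — a property the tests rely on.
Numerically, $\tan\{(0.5-p)\pi\}$ is evaluated as
$\cos(\pi p)/\sin(\pi p)$ via `cospi`/`sinpi`, and for $T > 1$ the tail is
computed as $\arctan(1/T)/\pi$; both choices avoid catastrophic
cancellation at the extremes (the direct form loses half the significand
for $p \approx 10^{-8}$). P values outside $[10^{-15}, 1-10^{-15}]$ are
clamped with a warning because the tangent diverges at 0 and 1. Weights
are normalised to sum to one before combining, making weight rescaling
exactly neutral.

Layer summaries: `layer_means()` averages each layer over variants (the
per-layer mean is the "hierarchy of contribution" drawn as horizontal
lines in the drill-down panel — the mean over variants per layer, not over
layers per variant, matching the panel semantics); `variant_spread()`
gives each variant's min–max range across layers; `layer_correlation()`
reports Pearson correlation of $-\log_{10} p$ between layers. Correlation
is computed on the $-\log_{10}$ scale, not raw P, because annotation tools
are expected to agree on the association scale, where the relationship is
closer to linear; highly correlated layers are the norm since many
annotation tools share population-frequency inputs.

## What the synthetic generator emulates

`simulate_dataset()` reproduces the structure of the dense synthetic study
conditions: 5,000 independent variants partitioned into 250 disjoint sets
of 20, positions uniform over fixed hg19 chromosome lengths on autosomes
1–22, GWAS P values uniform on $(0.05/100,\, 1)$, and set-level P values
log-normal (defaults $\mu = \ln 0.3$, $\sigma = 1$, truncated above at 1 —
unstated in the source conditions, chosen once to populate the
$(0.005, 1]$ band) floored at $0.05/10$. A sparse preset gives 500
variants in 25 sets. Minor allele frequencies, when requested, are uniform
on $(0.001, 0.5)$.

A floored log-normal with floor $0.005$ can never produce a set passing
the $0.05/250 = 2\times10^{-4}$ threshold, so enriched sets must come from
a separate mechanism: `n_spiked` sets (default 2) are overwritten with P
values uniform below a tenth of the Bonferroni threshold. This makes
"exactly `n_spiked` significant sets" a deterministic property of the
generator at its defaults.

`simulate_annotations()` builds $-\log_{10} p$ additively,
$y_{vl} = s_v + e_{vl}$ with $s_v \sim \Gamma(\rho,\ 1/\ln 10)$ shared
across layers and $e_{vl} \sim \Gamma(1-\rho,\ 1/\ln 10)$ per layer. Gamma
additivity makes each marginal $\mathrm{Exp}(\ln 10)$ — i.e. uniform P
values — while the between-layer Pearson correlation of $-\log_{10} p$
equals $\rho$ exactly in expectation, with no calibration step.

All randomness flows through R's Mersenne-Twister generator (inversion
normals, rejection sampling) seeded from one integer, and the caller's
random state is saved and restored, so outputs are reproducible
field-for-field and cross-checkable.

The generator does **not** emulate linkage disequilibrium, genotypes,
phenotype models, winner's-curse effect-size inflation, or the empirical
P-value distributions of any real cohort. Passing tests therefore
demonstrate that the geometry, counting and combination machinery are
correct, not that any biological signal would be recovered from real
data; real-data behaviour depends entirely on the upstream association
tooling whose tabular outputs this package consumes.

## Numerical and interface choices

* Layout TSVs serialise numeric fields with `%.17g`, which round-trips
  IEEE doubles exactly; the raw P is stored and $-\log_{10} p$ is computed
  at layout time, never at parse time.
* P values of exactly 0 in inputs (underflowed biobank statistics) are
  clamped to the smallest positive double with a warning, not rejected.
* Chromosome labels are normalised (strip `chr`, uppercase, `M` → `MT`)
  so hg19- and hg38-dialect files mix safely; no liftover is attempted, so
  inputs must share one build.
* Column mapping auto-detects the common summary-statistics dialects
  (`SNP/CHR/BP/P`, `ID/CHROM/POS/PVAL`, lowercase variants, the usual
  `AF/MAF/freq` spellings), case-insensitively, first hit wins; explicit
  mappings override and must exist.
* Rendering is validated through its `render_report` counts (points,
  edges, trimmed outliers), never pixels: image bytes legitimately differ
  across graphics backends, the structural claims do not. An explicit
  `y_cap` filter trims extreme $-\log_{10} p$ outliers and reports how
  many points it removed.
* The 16 built-in colour themes are designed in-package; theme 1
  ("classic") follows the conventional scheme of blue set points over
  alternating yellow/orange variant points.

## Problem sizes in the test suite

The suite exercises the full 5,000-variant / 250-set recipe for count,
edge and determinism properties, 1,000 random sets for the anchoring
oracle, 20–25 random configurations of up to 80 points for the dispersion
contract, and $n = 1000$ variants for annotation-correlation recovery;
smaller instances (hundreds of variants) cover IO round-trips and
rendering. These sizes keep every oracle brute-forceable while covering
the defaults end to end.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_params(seed = 7))
lay <- assemble_layout(sim$variants, sim$sets, sim$membership)
lay
#> <archipelago_layout> 5000 variant point(s), 250 set point(s)
#>   (2 significant at p < 0.0002), 40 edge(s)
render_archipelago(lay, plot_options(theme = "classic"), "archipelago.png")
```

## Known limitations

* No genotype-level input (VCF/BGEN): the tool consumes association
  summary tables only, by design.
* Anchors are means, so a set with members on chromosomes 1 and 22 anchors
  mid-genome where it has no members; dispersion mitigates overlap but the
  anchor of a genome-wide set is inherently a compromise.
* Observed-mode axes depend on the variants present; use fixed mode when
  layouts from different files must be superimposable.
* The Bonferroni threshold assumes the number of set tests is the right
  denominator; correlated sets (nested pathways) make it conservative.
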