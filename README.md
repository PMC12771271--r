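# archipelago

Layered Manhattan-style visualisation of variant-set association tests
(VSATs) alongside single-variant GWAS results.

## The problem

Gene- or pathway-level tests that collapse variants before testing —
SKAT-O, burden tests, DeepRVAT gene scores, UTR collapsing analyses —
return one P value per variant *set* and therefore have no genomic
coordinate. They are usually plotted by rank, disconnected from the
variants they summarise. This package gives each set-level P value a
meaningful x-axis position: the arithmetic mean of the cumulative genomic
coordinates of its member variants,

    x(S) = mean( offset(chrom_i) + pos_i ,  i in S )

so set-level and variant-level associations appear together on one
Manhattan-style axis ("archipelago" plot), with edges linking each
significantly enriched set to its constituent variants. The significance
threshold is Bonferroni over the number of set tests (alpha / n_sets, e.g.
0.05 / 250 = 2e-4). Overlapping set anchors are separated by ranked
dispersion: strongest association first, every pairwise gap at least
`min_gap`, anchor order preserved. An optional third layer carries
per-variant annotation P values combined by the Cauchy combination test
(ACAT):

    T = sum_i w_i * tan((0.5 - p_i) * pi) / sum_i w_i
    p_ACAT = 1/2 - arctan(T) / pi

It is aimed at statistical geneticists who already have variant-level and
set-level association tables (any TSV/CSV dialect with a header, optionally
gzipped) plus a set-membership table, and want one integrated, customisable
figure.

## Worked example

```r
library(archipelago)

# seeded synthetic dataset: 5,000 variants, 250 disjoint sets of 20
sim <- simulate_dataset(sim_params(seed = 7))
lay <- assemble_layout(sim$variants, sim$sets, sim$membership)
lay
#> <archipelago_layout> 5000 variant point(s), 250 set point(s) (2 significant at p < 0.0002), 40 edge(s)

rep <- render_archipelago(lay, plot_options(theme = "classic"), "archipelago.png")
rep
#> <render_report>
#>   points = 5250
#>   variant_points = 5000
#>   set_points = 250
#>   edges = 40
#>   trimmed = 0
#>   layers = 2
#>   significant_sets = 2
#>   theme = classic
#>   path = archipelago.png

write_layout(lay, "layout.tsv")   # full-precision TSV, round-trips exactly
```

5,250 points are drawn in two layers; the threshold 0.05/250 = 2e-4 flags
the 2 enriched sets the generator plants, and with significant-edge
highlighting on, 2 sets x 20 members = 40 edges connect them to their
variants. For real data, replace the simulated tables with
`read_variant_table()`, `read_set_results()` and `read_membership()` —
column names are auto-detected across the common GWAS dialects
(`SNP/CHR/BP/P`, `ID/CHROM/POS/PVAL`, ...) or set via `column_mapping()`.

The annotation layer:

```r
m <- simulate_annotations(sim$membership[[sim$spiked[1]]], n_layers = 4, rho = 0.3, seed = 1)
acat_combine_matrix(m)        # one combined P per variant
layer_means(m)                # per-layer contribution hierarchy
layer_correlation(m)          # between-layer correlation of -log10 p
render_acat_panels(lay, m, sim$spiked, "drilldown.png")
```

## Command line

A thin launcher is installed at `inst/cli/archipelago`:

```sh
archipelago simulate --preset default --seed 4 --out-dir fixtures/
archipelago plot --gwas fixtures/gwas.tsv --vsat fixtures/vsat.tsv \
    --sets fixtures/membership.tsv --out fig.png --layout-out layout.tsv
archipelago acat --annotations fixtures/annotations.tsv --out-prefix anno
```

Exit codes: 0 success, 1 data error, 2 configuration error. A
`--config file` of `key: value` lines may supply any flag; explicit flags
override it.

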