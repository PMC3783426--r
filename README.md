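# bathydelim

Multi-criterion molecular species delimitation with bathymetric structure,
for multi-marker DNA surveys of deep-sea taxa.

Supposedly cosmopolitan deep-sea invertebrates — the scavenging amphipod
*Eurythenes gryllus* is the classic case — routinely turn out to be
complexes of divergent lineages segregated by depth rather than geography.
Delimiting those lineages from mitochondrial (COI, 16S) and nuclear (28S)
alignments takes several mutually checking lines of evidence, which this
package implements as one pipeline:

- **K2P distances and the barcoding gap.** Pairwise divergences under the
  Kimura 2-parameter model, `d = -½·log((1-2P-Q)·√(1-2Q))` with transition
  and transversion proportions `P` and `Q` (pairwise deletion of
  gap/ambiguous sites); clade-wise intra/interclade summaries; a *barcoding
  gap* is an empty interval between the highest intraclade and lowest
  interclade distances.
- **The 4× criterion.** Clusters are independent species-level lineages when
  every between-cluster distance strictly exceeds 4× the larger of the two
  clusters' maximum intracluster distances.
- **Statistical-parsimony haplotype networks.** Haplotypes linked while the
  step count stays within the 95% parsimony-probability connection limit
  (gaps optionally a fifth state); unconnected components are candidate
  species.
- **Single-threshold GMYC.** A mixed Yule–coalescent likelihood locating the
  threshold time `T` separating between-species branching (rate `λ₁·n^p₁`)
  from within-species coalescence (rate `λ₂·n^p₂` per cluster) on an
  ultrametric tree, with a likelihood-ratio test (χ², df = 3) against the
  one-process null.
- **Depth structure.** A scan for depth cuts that separate all clades into
  disjoint shallow/deep sets, plus bathyal/abyssal summaries of networks
  against a configurable 3,000 m cut.
- **Synthetic data.** A coalescent-within-Yule, K80 sequence generator
  (`make_dataset()`) reproducing the statistical structure the analyses
  assume — interclade divergences an order of magnitude above intraclade,
  clades confined to depth strata — so everything runs with no downloads.

## Worked example

```r
library(bathydelim)

ds <- make_dataset(sim_config(seed = 42))   # 9 species, 45 specimens
dm <- distance_matrix(ds$alignments$COI, model = "K2P")

barcoding_gap(dm, ds$partition)
#> <gap_report> max intra = 0.007647 | min inter = 0.05888 | gap PRESENT

four_x(dm, ds$partition)
#> <four_x_report> 36 clade pairs; global PASS (factor 4)

haps <- collapse_haplotypes(ds$alignments$`16S`, ds$metadata)
nets <- build_networks(haps, connection_limit(489))
#> <parsimony_networks> 9 networks (connection limit 4 steps)

depth_break(ds$partition, ds$metadata)
#> <depth_break_report> break between 2508 and 3092 m

fit <- fit_gmyc(ds$tree); null <- fit_null(ds$tree)
gmyc_lrt(null, fit)
#> <gmyc_lrt> 2*dlnL = 38.85138, df = 3, p = 1.866e-08
```

Reading: the highest within-clade COI divergence (0.8%) sits far below the
lowest between-clade divergence (5.9%), so a barcoding gap is present and
every clade pair clears the 4× rule; the 16S haplotypes fall into nine
unconnected parsimony networks (two bathyal, seven abyssal); no clade spans
any depth cut between 2,508 and 3,092 m, bracketing the 3,000 m
bathyal–abyssal transition; and the mixed branching model beats the
single-species null decisively on the true genealogy (here with 10 delimited
entities — one species is split, the usual direction of GMYC error under
sparse within-species sampling).

The `analysis/` directory runs the same stages as a numbered workflow
(`01_simulate.R` … `05_combined_report.R`), writing tables, networks
(GraphML/TSV) and JSON reports under `results/`.

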