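# tetranet

Tetramer-compatible motif analysis of protein–protein interaction
networks.

Plant MADS-domain transcription factors are thought to regulate their
targets as tetramers — the "quartet model" — in which every protein binds
two others in the complex. On an undirected interaction network whose
nodes are proteins and whose edges are experimentally supported physical
interactions (self-loops marking self-interaction), a heterotetramer
leaves a characteristic footprint: a 4-node subgraph containing the
4-cycle *C₄*. `tetranet` asks, for a given network, whether such
**tetramer-like subgraphs** — 4-node sets whose induced subgraph embeds
*C₄* — are more abundant than expected by chance, and whether the genes
encoding them are preferentially co-expressed.

The package provides, as reusable building blocks:

* a complete **catalogue of connection patterns**: all isomorphism
  classes of connected graphs on 2–4 nodes with optional self-loops
  (3, 10 and 50 classes; 63 in total), built by exhaustive enumeration
  with brute-force canonical certificates;
* an exact **subgraph census**: every connected *n*-node set is
  classified by the isomorphism class of its induced subgraph, and
  embedded counts ("at least these interactions") derive from the
  induced ones by pattern containment;
* a **degree-preserving switching null model**: edge pairs are
  repeatedly rewired (s ∼ U[100·E, 200·E] successful swaps, self-loops
  carrying two stubs), with an optional variant that also conserves the
  number of self-interactions; significance is the empirical
  p = #{replicates ≥ observed}/N, with Benjamini–Hochberg adjustment
  across patterns;
* **co-expression statistics**: presence calls by thresholding log₂
  expression (> 4 by default), joint-tissue queries through a
  protein→gene map, uncorrected Pearson χ² association tests, a
  resampling null for the fraction of co-expressed subgraphs, and
  tissue-count Mann-Whitney comparisons;
* **prospective tetramers** (tetramer-like sets whose genes share at
  least one expressed tissue), clade partitioning (MIKC / non-MIKC),
  balanced-clade resampling, degree-matched subnetwork sampling, and
  **retrodiction** of candidate redundant proteins by substitution
  counting;
* a **synthetic-data generator** that plants vertex-disjoint 4-cycles
  in a random network with a matched expression matrix, so the entire
  pipeline is testable end to end without external data.

## Worked example

```r
library(tetranet)

## a synthetic study: 40 proteins, 120 interactions + 4 self-loops,
## 8 planted tetramer-like quartets, 20 tissues
study <- generate_synthetic_study(synthetic_config(seed = 1))
study$network
#> ppi_network 'synthetic': 40 nodes, 124 edges (4 self-loops)

## how abundant are tetramer-like subgraphs, against the switching null?
mt <- motif_test(study$network, "tetramer", ensemble_size = 1000, seed = 1)
mt
#> motif_test: network 'synthetic', statistic 'tetramer', 1000 randomized replicates
#> null model: degree-preserving switching (s ~ U[100E, 200E])
#>        pattern observed  mean median    sd   se p_label p_adjusted
#>  tetramer_like      140 140.4    140 14.86 0.47   0.512      0.512

## are tetramer-like sets preferentially co-expressed?
fn <- fraction_coexpression_null(study$network, study$calls,
                                 study$gene_map, reps = 1000, seed = 1)
fn
#> fraction-of-co-expression null
#>   observed fraction (tetramer-like sets): 0.05714  [8 of 140 sets]
#>   resampling null: 1000 samples of 140 from 3771 connected 4-sets
#>   null mean 0.01128, range [0, 0.04286];  empirical p <0.001

## which 4-sets are prospective tetramers?
prospective_tetramers(study$network, study$calls, study$gene_map,
                      study$annotation)
#> prospective tetramers: 8 co-expressed tetramer-like sets (132 never co-expressed) in 'synthetic'
#>    p1  p2  p3  p4 n_tissues clade_class
#> 1 P01 P04 P34 P39         3   MIKC-only
#> ...
```

Reading the output: the network holds 140 tetramer-like 4-sets. Their
*count* is unremarkable for this density (empirical p ≈ 0.5 — at 120
edges on 40 nodes, randomly rewired networks contain just as many; see
the vignette for when the count itself carries signal). Their
*co-expression*, however, is strongly structured: 5.7% of tetramer-like
sets share an expressed tissue versus 1.1% expected from random
connected 4-sets (empirical p < 0.001), and the 8 co-expressed sets —
exactly the planted quartets — surface as prospective tetramers, all
MIKC-only because planting was restricted to that clade.

On a real network the same calls apply unchanged: read the edge list
with `read_edge_list()`, the expression matrix with
`read_expression_matrix()`, filter to proteins with expression data via
`expression_filtered_network()`, and run `run_pipeline()` or the
individual stages.

## Package layout

| file | contents |
|---|---|
| `R/network.R` | network data model, edge-list and three-hybrid I/O |
| `R/catalogue.R` | pattern catalogue, certificates, containment |
| `R/census.R` | induced / embedded censuses, 2NTP/3NTP counts |
| `R/nullmodels.R` | switching randomization, ensembles, `motif_test()` |
| `R/expression.R` | expression calls, gene maps, network filtering |
| `R/association.R` | χ² tests, resampling nulls, rank comparisons |
| `R/tetramers.R` | prospective tetramers, clades, retrodiction |
| `R/synthetic.R` | planted-motif study generator |
| `R/pipeline.R` | `run_pipeline()` orchestration and reports |
| `src/tetranet.cpp` | compiled switching and subset-census kernels |

See `vignettes/tetramer-motifs.Rmd` for the methods: the null model and
its variants, the counting conventions, the synthetic-data design, and
known limitations.
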