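---
title: "Counting tetramer-compatible motifs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting tetramer-compatible motifs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetranet)
```

## The question and the model

MADS-domain transcription factors act, under the quartet model, as
tetramers in which each protein binds two partners through distinct
interfaces. On a pairwise interaction network this predicts that 4-node
subgraphs containing the 4-cycle — every member bound to two others —
should be unusually common if tetramer formation constrains the
network's wiring. `tetranet` formalizes and tests this prediction.

Three assumptions underlie the whole analysis:

1. **Pairwise sufficiency.** Edges represent the potential of two
   proteins to interact; interactions observed in three-hybrid assays
   are interpreted as two pairwise interactions through the bridge
   protein (unless a direct bait–prey interaction is already known, in
   which case the record is considered explained and contributes
   nothing).
2. **Co-expression as a necessary condition.** A tetramer can only be
   functional where all four encoding genes are expressed; sharing at
   least one tissue is therefore used as a coarse filter, not as
   evidence of complex formation.
3. **Degree structure as the null.** Chance is defined by networks with
   the same node set, the same number of interactions and the same
   per-protein interaction counts, differing only in who binds whom.

## Counting conventions

The unit of counting is the **node set**, never the embedding. Each
connected \(n\)-set (\(n \in \{2,3,4\}\)) is classified once, by the
isomorphism class of its induced subgraph, self-loops included;
*embedded* counts (sets having *at least* a motif's interactions) are
obtained by summing induced counts over all classes that contain the
motif. This makes the identity

\[
\texttt{count\_tetramer\_like} \;=\; \sum_{P \,\supseteq\, C_4}
\texttt{induced count}(P)
\]

hold exactly; the pipeline asserts it on every run. Self-loops
participate in classification (a triangle with and without a
self-interaction are different classes) but never in connectivity: a
set is connected iff its loop-free induced subgraph is one component.

Isomorphism at these sizes is decided exactly by brute force: the
canonical certificate of a graph is the lexicographically minimal
edge-set encoding over all \(\le 4! = 24\) node relabelings, prefixed
with the node count. Exhaustive enumeration plus certificate
deduplication yields 3, 10 and 50 classes for sizes 2, 3 and 4 with
self-loops (1, 2 and 6 without); 20 of the 50 size-4 classes embed the
4-cycle and are the *tetramer-like* classes. Pattern identifiers
(`p4-17` etc.) are assigned by size and certificate order, so they are
stable across runs and machines.

The census itself enumerates all \(\binom{n}{k}\) subsets — exact, and
at the intended scale (networks of some tens of proteins, about 1.6M
4-subsets for 80 nodes) a question of seconds, because each subset
reduces to a bit code over its member pairs and loops that is tabulated
in compiled code and classified through a precomputed code-to-class
table. Approximate or sampling-based censuses are deliberately out of
scope.

## The switching null model

Randomized reference networks are produced by double-edge swaps: pick
two edges, exchange two of their ends (both pairings equally likely),
reject any proposal that would duplicate an existing edge or merely
recreate the removed pair. The number of *successful* swaps is drawn
uniformly from \([100E, 200E]\) — counting successes rather than
attempts guarantees the prescribed amount of mixing regardless of the
rejection rate. A self-loop carries two stubs, so a swap of \((A,B)\)
and \((C,D)\) with \(A = D\) legitimately creates a self-interaction;
consequently the default ensemble varies in self-loop count while
conserving every node's stub degree. The `preserve_self_loops` variant
additionally rejects proposals that would create or destroy a
self-interaction, for analyses (such as the 2NTP/3NTP homodimer
patterns) whose statistic is driven by self-loop placement. Degenerate
networks that admit no legal swap (a triangle, for example) are
returned unchanged after a capped number of attempts.

Significance is empirical: \(p = \#\{\text{replicates} \ge
\text{observed}\}/N\), reported as \(<1/N\) when no replicate reaches
the observed count. Ensemble summaries pair the sample standard
deviation (\(N-1\) denominator) with the standard error
\(sd/\sqrt{N}\). Across patterns, p-values are adjusted by
Benjamini–Hochberg (the field default for motif scans; Bonferroni is
available) at the conventional 5% level. Every stochastic operation
takes an explicit seed, and ensemble replicate \(i\) is re-seeded as
`seed + i`, so ensembles are reproducible and independent of
evaluation order.

## Expression and association

A gene is called expressed in a tissue when its log₂ value is strictly
greater than the threshold, 4 by default — the established cutoff for
the developmental expression atlas this analysis style was built
around. Replicate averaging is assumed done upstream
(`collapse_replicates()` helps when it is not). Splice variants map to
one gene through the protein→gene map; proteins absent from the map
fall back to identity mapping, reported once per call. Expression
filtering removes proteins without expression rows and then proteins
left without any interaction, mirroring how an expression-restricted
network is constructed.

Association between tetramer-like membership and co-expression uses the
uncorrected Pearson χ² on 2×2 tables — no Yates correction, the choice
that reproduces the reference analyses including tables with a zero
cell. The fraction-of-co-expression null draws, per replicate, as many
connected 4-sets as there are tetramer-like sets, uniformly **without
replacement** (a "sample of \(k\) subgraphs from \(m\)" is read as a
subset; with-replacement sampling is available as an option). The
tissue-count comparison reports both the raw Mann–Whitney \(U\) of the
tetramer-like group and the tie-corrected normal-approximation \(z\),
because a lone "U" is ambiguous between the two conventions.

One calibration caveat is worth knowing. The resampling p-value is
uniform under the null *for an exchangeable group of 4-sets* (the test
suite checks this by Kolmogorov–Smirnov). The tetramer-like group
itself is not exchangeable: overlapping 4-sets share proteins, their
co-expression indicators are positively correlated, and the group
fraction is therefore over-dispersed relative to the resampling null.
The p-value remains a valid one-sided tail probability of the stated
null, but it is anti-conservative with respect to a null that respects
protein sharing; very small p-values on real data deserve that caveat.

## Retrodiction

For a protein X, every prospective tetramer \(\{X,A,B,C\}\) is compared
against the list for sets \(\{Y,A,B,C\}\); Y scores one substitution
per such pair, provided the co-expression condition holds. The default
condition is the strict reading: at least one tissue in which the genes
of **all five** proteins (Y plus the original four) are expressed. The
looser reading — Y shares at least one tissue with each of X, A, B, C
separately, possibly different tissues — is available via
`pairwise_overlap = TRUE`. Substitutes are ranked by count, ties broken
lexicographically and all reported.

## The synthetic study design

`generate_synthetic_study()` emulates the statistical structure the
analysis assumes, not any real organism's data. Defaults: 40 proteins,
120 interactions of which 32 form 8 vertex-disjoint planted 4-cycles,
4 self-interactions, 20 tissues. Planting is vertex-disjoint so ground
truth is unambiguous. The tissues are partitioned into one block per
planted set; within its block a set is jointly expressed per tissue
with probability `p_in = 0.9` and is silent elsewhere, while background
genes are expressed independently with `p_out = 0.2` per tissue. This
block design is what creates the intended contrast: a planted quartet
almost surely shares a tissue (probability \(1-(1-p_{in})^{b}\) for a
block of \(b\) tissues), whereas any other 4-set — background proteins,
or members of two different quartets — co-expresses only through the
\(p_{out}^{4}\) background coincidence, about 3% over 20 tissues. At
the extremes the contrast is deterministic: `p_in = 1, p_out = 0` makes
exactly the planted sets co-expressed; `p_in = 0` silences them
entirely. Expression *values* are drawn from narrow bands around 8
(expressed) and 1 (silent) so that thresholding at 4 recovers the
designed calls exactly; all randomness lives in the calls. 85% of
proteins are annotated MIKC and planted sets are placed inside that
clade, mirroring the predominance of MIKC proteins among tetramer
candidates.

What the generator does **not** emulate: realistic degree
distributions (background edges are uniform, real interactomes are
heavy-tailed), tissue ontologies or expression dynamics, correlated
measurement noise, or overlapping complexes (an overlap-allowing
planting mode exists only as a stress test via direct network
construction). Passing tests on synthetic data therefore validate the
machinery — counting, nulls, calibration, recovery — not any biological
claim.

A consequence of the chosen default density deserves emphasis: at 120
edges on 40 nodes, randomly wired degree-matched networks already
contain on the order of 140 tetramer-like sets, so 8 planted quartets
(a +8 shift against a null standard deviation near 15) are **not**
detectable as a count excess; the switching-null test on the default
fixture is expectedly non-significant, and the planted signal is
carried entirely by the co-expression layer, where the contrast is
strong (observed fraction ≈ 0.06 versus null ≈ 0.01). Count-level
detection of planted motifs requires a much sparser background (around
40–60 total edges at this node count), which the null-calibration
checks use deliberately small networks to demonstrate. This mirrors
the real analytical situation: the abundance signal of a dense,
clustered interactome is a property of its global wiring, while the
expression filter is what isolates biologically coherent quartets.

## Numerical choices and degenerate inputs

* Certificates refuse sizes above 4; no general canonical-labeling
  machinery is included, by design.
* `empirical_p` flags below-resolution results instead of reporting a
  bare 0, and the label (`"<1e-04"` for \(N = 10^4\)) is what reports
  print.
* Medians use the mid-point rule for even ensemble sizes.
* Degree-matched subnetwork sampling uses *exact* equality of sorted
  stub-degree multisets — the strictest reading of "same connectivity
  distribution" — and reports its acceptance rate; zero acceptances
  yield an empty result with a warning, not an error.
* Three-hybrid records whose bait–prey edge already exists contribute
  nothing; degenerate all-equal records are rejected. Whether a
  partially-known bridge should still contribute its missing edge is
  unresolved in the field's descriptions; emitting both bridge edges
  and deduplicating makes the choice harmless.
* Prospective-tetramer lists and pattern tables are deterministically
  sorted (lexicographic on member ids; certificate order) so outputs
  diff cleanly across runs.
* All seeds are plain 32-bit integers; derived seeds are `seed + i`.

## Problem sizes in the test suite

The suite exercises: oracle-equivalence of the census against a
per-subset brute-force classifier on random networks of up to 12 nodes
(200 networks in the acceptance checks); conservation laws of the
switching randomization over 10³ trials; the default 40-node planted
fixture with a 10³-replicate ensemble; and 50-seed calibration runs at
ensemble size 200, where the resolution of 1/200 comfortably separates
p-values above and below 5%. These sizes were chosen to keep each check
statistically meaningful while the whole suite remains quick enough to
run habitually.

## Known limitations

* Exact enumeration limits motifs to 2–4 nodes; 5-node patterns would
  need genuinely different machinery.
* The census scales as \(\binom{n}{4}\); beyond a few hundred nodes the
  ensemble loop becomes the bottleneck.
* Mutually exclusive interaction interfaces are invisible to the
  analysis: a prospective tetramer may be structurally impossible if
  one protein binds two partners through the same domain.
* The co-expression filter uses presence calls only; quantitative
  co-variation, and anything below the expression threshold, is
  ignored.
* Printed Mann–Whitney statistics in legacy analyses of this kind are
  ambiguous between \(U\) and \(z\) conventions; this package always
  reports both and never claims to match a bare historical "U".
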