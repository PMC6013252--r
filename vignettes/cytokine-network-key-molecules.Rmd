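---
title: "Methods: cytokine PPI networks and key-molecule selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytokine PPI networks and key-molecule selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cppinet)
```

## The problem and the model

Cytokines drive the pathology of inflamed synovium by signaling through
membrane receptors into cytoplasmic transducer cascades that activate
transcription factors. Because the cascades share transducers, they form
a network, and the interesting molecules are the ones that are both
*topologically central* in that network and *differentially expressed*
between disease and control tissue. `cppinet` operationalizes this idea
as a fixed pipeline over three kinds of input: multi-source interaction
tables, a subcellular localization resource, and case/control expression
datasets each available in two normalization variants.

The pipeline's stages and their governing parameters:

| Stage | Parameter | Default | Meaning |
|---|---|---|---|
| co-expression filter | `r_threshold` | 0.7 | signed Pearson *r* an edge must exceed (strict `>`), in disease samples |
| co-expression filter | `min_datasets` | 1 | datasets in which the threshold must be exceeded |
| DE calling | `p_threshold` | 0.05 | two-sided t-test level (strict `<`) |
| DE calling | `fc_threshold` | 1.5 | linear fold-change gate (strict `>`, or `< 1/1.5` for down) |
| centrality cut | `fraction` | 0.20 | per-measure top fraction, tie blocks included |
| key rule | `clauses` | (3,3) OR (2,4) | (min centrality measures, min DE datasets) |
| clustering | distance/linkage | 1−Pearson / average | sample clustering for the therapy analysis |

All thresholds are strict inequalities: an edge with *r* exactly at the
threshold, or a gene with fold change exactly 1.5, does not pass.
Correlation is computed on the normalization variant tagged `A` (the
RMA-standing variant) and on disease samples only; both are config
switches (`coexpression_config()`).

## Design decisions where the design was open

**Identifier mapping.** Many-to-one identifier mappings are allowed;
one-to-many mappings resolve to the first mapping in file order with a
warning. This is deterministic and auditable; any other rule would need
information the mapping files do not carry. Records with an unmappable
endpoint are dropped and counted per source, never imputed.

**Localization.** "Plasma membrane or cytoplasm" is read as a predicate
on each endpoint, and an edge is kept only if *both* endpoints pass
(directly annotated or whitelisted). A membrane+cytoplasm interactome is
meant to carry receptor-to-TF signal flow; an edge with one
out-of-compartment endpoint cannot do so.

**Signed co-expression.** The threshold is `r > 0.7`, not `|r| > 0.7`:
anti-correlated pairs are excluded. Co-expression here is evidence that
two interactors are simultaneously present in the tissue, which
anti-correlation argues against. Only pairs that are PPI edges can
survive the filter, so the implementation computes edge-restricted
correlations; the per-edge *r* table is emitted for audit.

**CPPIN edge rule.** The assembled network is the SPPIN-induced subgraph
on the selected node set (cytokines, receptor genes, TF subunit genes,
intermediates, neighbors), plus one explicit cytokine–receptor edge per
spec pairing. Induced-subgraph semantics retains all experimentally
supported links among selected nodes; `assemble_cppin(induced = FALSE)`
restricts to seed-incident edges instead. Cytokine labels may collide
with gene symbols; collisions are handled by role tags, never renaming.
Receptor or TF genes absent from SPPIN go to a skip report — they are an
expected outcome of aggressive filtering, not an error.

**Centrality conventions.** Betweenness is left unnormalized (each
unordered pair counted once) because only ranks feed the selection.
Closeness on a disconnected graph sums distances within the node's
component (the plain definition is undefined across components); a
harmonic variant is available. Eigenvector centrality uses shifted power
iteration on `A + I` — same eigenvectors, but convergent on bipartite
components where the unshifted iteration oscillates — with nonnegative
sign fixing and max-1 rescaling; on disconnected graphs the component
with the largest spectral radius dominates and other components decay to
zero. The top-fraction cut takes `ceiling(fraction·n)` nodes per measure
and, under the default tie policy, the whole score-tie block straddling
the boundary; with low-resolution scores (integer degrees) this can
extend the set well past the nominal fraction, which is why the
key-molecule rule demands agreement across measures *and* expression
evidence.

**Dual-normalization reconciliation.** Each dataset is analyzed in both
normalization variants. A direction is called only when the variants
agree, or when one crosses the fold-change gate and the other sits below
it; an up/down conflict is `not_de`. The p-value requirement is enforced
in *every variant whose fold change crossed the gate* (default
`p_rule = "crossing_variants"`); requiring p in at least one variant is
available behind a flag. Fold changes are ratios of arithmetic group
means on the linear scale, with log2-tagged matrices unlogged first.
No multiple-testing correction is applied by default: the rule is an AND
of a per-gene test, a fold-change gate and a cross-dataset replication
requirement, and only the centrality-selected genes are tested.

**Therapy analysis.** "Clustered with controls" is operationalized as:
at the k = 2 cut of the dendrogram, the disease sample sits in a cluster
whose control count exceeds its disease count. Distance and linkage
(1−Pearson, average) are deliberate defaults — only cluster membership is
consumed downstream, and correlation distance ignores per-sample
location shifts, which is the dominant nuisance in expression profiles.
`remove_and_rerun()` drops the flagged samples, recomputes DE with the
identical rule, and partitions the selection into retained and
additional genes; a dataset left with fewer than two disease samples is
excluded from the counts with a warning.

**Overlap significance.** The Monte-Carlo null draws key-set-sized node
samples uniformly from all CPPIN nodes (no role exclusions) and computes
both statistics exactly as the observed ones, removing overlaps before
counting direct links. Empirical p-values are reported raw (`r/n`, the
comparison surface) and with the add-one correction `(r+1)/(n+1)`. The
overlap statistic depends only on membership, so it has a hypergeometric
closed form (`hypergeometric_tail()`, direct summation) used as an
independent cross-check; the direct-link statistic is graph-dependent
and has no closed form here.

## The synthetic cohort: what it emulates and what it does not

`generate_fixture()` produces the complete input stack with recorded
ground truth. Its defaults are the package's reference study conditions:

- **Network.** 12 cytokines and 8 transcription factors (one to two
  receptor genes per cytokine, one to six subunit genes per TF) yield
  ~100 receptor→subunit pairings, each connected by a planted
  transduction chain of 1–2 interior transducers. Twelve interiors are
  hubs: they form an interconnected core ring and carry 12 interactor
  neighbors each — ten are the planted key molecules, two model
  therapy-sensitive genes. With chain lengths ≤ 2 every planted chain is
  geodesic in the scaffold (cross-pair detours cost ≥ 3 hops), so the
  planted intermediates are recoverable exactly; longer chains are
  allowed but void this guarantee.
- **Sources.** Six mock databases alternating symbol and accession
  namespaces; every planted edge gets one clean symbol-namespace
  emission, duplication (10%) and self-loops (2%) are layered on top,
  and accession endpoints are corrupted to unmappable identifiers at 5%.
  Background interactions (edges with at least one endpoint outside the
  co-expressed scaffold) appear at 0.4% of eligible pairs.
- **Expression.** Five datasets with the group sizes of a realistic
  synovial cohort (disease/control 5/9, 12/9, 12/4, 13/10, 10/10), each
  in two variants: variant B is an affine transform of variant A plus
  small independent noise, mimicking a concordant second normalization.
  Co-expression is induced by a latent tissue factor shared by scaffold
  genes, with loading `λ = σ·sqrt(r/(1−r))` so planted pairs correlate at
  the target *r* = 0.9; the factor is centered within each group so
  co-expression cannot masquerade as differential expression. Key hubs
  carry a ±1.5 log2 effect (mixed directions — correlation-based sample
  clustering needs a non-constant disease signature); minor transducers
  get sporadic 1–2-dataset effects; therapy-sensitive hubs get a smaller
  0.75 log2 effect that drug-masked samples dilute below the fold-change
  gate until those samples are removed.
- **Masking.** Datasets 2 and 4 have half their disease samples planted
  with control-like profiles (no DE effect, factor retained), dataset 3
  a single one — the drug-effect signature the clustering stage must
  find. Masking intentionally inflates disease-group variance in those
  datasets, so per-dataset DE calls there are genuinely harder; the
  five-dataset selection rule absorbs this.
- **Determinism.** RNG sub-streams are split per artifact (network,
  background, sources, localization, one per dataset), so changing
  `n_datasets` does not perturb the network; fixed seeds give
  byte-identical written fixtures.

What the generator does **not** emulate: probe-level microarray
structure, batch effects, dependence between datasets, literature
curation noise in the signaling table, or realistic degree
distributions of the full human interactome (the scaffold is
hub-structured by design). Passing recovery tests therefore demonstrates
that the pipeline's logic is correct and well-calibrated under its own
assumptions — not that those assumptions hold for any particular real
tissue.

## Numerical choices and degenerate inputs

- Zero-variance vectors make Pearson *r* undefined: `pearson_r()`
  returns `NA` and such edges contribute no evidence. Zero variance in
  both t-test groups marks the gene untestable (`not_de`).
- Eigenvector iteration converges when the L1 change of the normalized
  iterate drops below `tol` (default 1e-10); non-convergence is an
  error, never a silent partial result. Edgeless graphs score 0.
- Ties at the centrality cut are broken by inclusion (default) or by
  node name under `strict_count`, keeping every run deterministic.
- Identical samples cluster into an arbitrary but deterministic
  partition (distance 0 everywhere); `cutree` label assignment is
  stable for fixed input.
- The resampler restores the caller's RNG state, and empty target lists
  return p = 1 with an explicit flag rather than NaN.

## Problem sizes

The shipped tests run the full pipeline on 500-gene cohorts (about 100
samples across five datasets, twice-normalized) and on 150-gene variants
for stage-level checks; oracle equivalence uses 200 random graphs of up
to 12 nodes for path/betweenness/closeness enumeration and graphs up to
50 nodes against dense eigendecomposition; the null-calibration
simulation uses 10,000 genes; the acceptance script averages five
end-to-end cohorts and draws 200,000 Monte-Carlo samples. These sizes
were chosen to exercise every code path with comfortable statistical
margins while keeping a complete run in the low minutes on one core.

## Known limitations

- All-shortest-path enumeration is exponential in pathological graphs
  (dense same-length path families); signaling-scale networks are far
  from this regime, but the package makes no attempt to cap path counts.
- The co-expression filter treats datasets as exchangeable evidence
  (`min_datasets` of any); it does not model dataset quality or sample
  overlap.
- The key rule consumes DE *counts*, not directions: a gene up in two
  datasets and down in two others counts as DE in four. Direction
  consistency is reported (consensus and per-dataset calls) but not
  enforced, matching the selection's purpose of flagging perturbed nodes.
- Monte-Carlo p-values below 1/n_samples are reported as 0 in the raw
  convention; the add-one estimate bounds them away from zero and is the
  one to quote when the observed statistic is extreme.
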