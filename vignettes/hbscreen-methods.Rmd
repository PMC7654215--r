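---
title: "Methods: hub-bottleneck screening of drug-modulated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub-bottleneck screening of drug-modulated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hbscreen` re-implements, as one seeded pipeline, a multistep in silico
screen for genes mediating the effect of a drug combination in cancer
cells. This vignette documents the models and procedures, the parameters
that matter, what the synthetic-data generators do and do not emulate, and
the design decisions taken where the procedure admitted more than one
reasonable reading.

## 1. Rank-product calling of constitutively expressed genes

The screen starts from replicated intensity arrays for a cell line. Genes
that are consistently abundant across replicates are "constitutively
expressed" and become the seed list for the protein-interaction network.

Within each array, genes are ranked by **descending** intensity (rank 1 =
highest; midranks on ties), and the rank product of a gene is the
geometric mean of its ranks across arrays. Small RP means consistently
high expression — the direction is deliberate, since the screen calls
*presence*, not differential expression. Probe-level data are first
collapsed to genes by the arithmetic mean per sample
(`collapse_probes()`).

Significance (`rp_significance()`) uses a pooled permutation null: gene
labels are permuted independently within each array `n_perm` times and all
rank products recomputed. Because the within-array rank multiset is fixed,
one permutation is equivalent to drawing a fresh random rank assignment
per column, which is how the null is generated. The p-value is the
smoothed pooled tail probability

$$p(g) = \frac{1 + \#\{RP^0 \le RP(g)\}}{1 + n_{perm}\cdot n_{genes}},$$

so p is never exactly zero, and `pfp(g) = p(g)\,n/\mathrm{rank}(p(g))`
estimates the proportion of false positives at each gene's cut. The
calling rule is `p <= alpha` with `alpha = 0.01` by default; whether the
historical workflows applied the 0.01 rule to p or to pfp is not
documented, so both are implemented (`call_on = "p"` or `"pfp"`) with p as
the stated default. When several replicated series are available,
`combine_calls()` takes the union of the per-series calls by default
(an intersection switch exists); union is a documented convention, not an
inference about any particular historical analysis.

Properties asserted by the tests: validity (the fraction of null genes at
p ≤ 0.01 sits inside the exact binomial 99% band), agreement with the
exhaustive (3!)² permutation enumeration on a 3-gene/2-array instance,
monotonicity of p in RP, permutation equivariance, and monotonicity of RP
under intensity decreases.

## 2. The network chain

All networks are simple undirected `igraph` objects with a `kind`
("protein"/"chemical") vertex attribute and a `confidence` edge attribute
in [0, 1]. Edge tables are read in two dialects (0–999 integer combined
scores, divided by 1000, or unit-interval scores; `auto` decides by
whether any score exceeds 1), with duplicate undirected pairs collapsed to
the **maximum** confidence (conservative for downstream ≥-thresholding)
and self-pairs dropped, both logged.

- `build_network(table, 0.400)` keeps edges with confidence **≥** the
  cutoff. The boundary is inclusive because the conventional "medium
  confidence 0.400" filter of the interaction databases is inclusive;
  boundary tests rely on this being exact. Nodes are endpoints of
  retained edges, so isolated inputs vanish (centrality on isolated nodes
  is degenerate, and edge-list exports carry no isolated nodes anyway).
- `attach_chemicals()` adds chemical nodes and their passing
  chemical–protein edges; edges to proteins absent from the network are
  dropped with a logged count, so attaching two chemicals grows the node
  set by exactly two.
- `select_disease_genes()` applies a confidence cutoff (default 1, the
  maximal-confidence filter) and truncates to `top_n` (default 1000) after
  sorting by confidence descending, identifier ascending. The identifier
  tiebreak is arbitrary but deterministic; the source procedure specified
  no tiebreak.
- `intersect_networks()` keeps nodes present in both inputs and edges
  whose node pair is present in both, with the **minimum** of the two
  confidences. Matching is by identifier and node pair only — the
  historical intersection operation intersects topology, not weights. An
  edge whose endpoints are common but which exists in only one network is
  *excluded*; published node/edge counts cannot distinguish the two
  readings, so the both-networks rule is the documented default. An empty
  intersection is a degradation (warning), not an error.

## 3. Centrality and hub–bottleneck classification

Degree is the adjacency count. Betweenness is the Freeman/Brandes
pair-fraction form on unweighted shortest paths,

$$C_B(v) = \sum_{s<t,\; s\ne v \ne t} \frac{\sigma_{st}(v)}{\sigma_{st}},$$

endpoints excluded, unnormalized, confidences ignored for paths,
disconnected pairs contributing zero. This is the variant computed by the
standard Cytoscape centrality plugins whose output the procedure consumed;
whether those historically counted endpoints is not fully documented, so
endpoint exclusion — the standard definition — is used, and the brute-force
test oracle enumerates shortest paths independently to pin the choice
down. Chemical nodes participate in centrality and may be classified H-B
(they are highly connected nodes in their own right); a flag excludes them
from the *report* if desired, but they always participate in paths.

A node is a **hub** when its degree **strictly** exceeds the mean degree
over all analyzed nodes, and a **bottleneck** when its betweenness
strictly exceeds the mean betweenness ("high compared to the average" is
read as exceeding it). Strictness matters at the degenerate boundary: on
a cycle graph every node equals the mean, so there are no hubs and no
bottlenecks. The four classes H-B / H-NB / NH-B / NH-NB partition every
graph.

**Quarters** re-rank the H-B set against its own medians: Q4 strictly
exceeds both the H-B median degree and median betweenness, Q3 only degree,
Q2 only betweenness, Q1 neither; non-H-B nodes get no quarter. With a
single H-B node (or all-identical H-B nodes) nothing strictly exceeds the
median and Q4 is empty — the correct degenerate reading of a strict rule.

`consensus_hb()` intersects the H-B sets of several networks and emits the
full Venn partition for reporting.

## 4. Survival screen

`km_screen()` dichotomizes each candidate gene at its cohort median
(ties to "high" — the historical web tool's tie rule is undocumented; any
rule is defensible and this one is deterministic and stated), then runs a
two-group logrank test (hypergeometric variance with tie correction, via
`survival::survdiff`) and reports the observed/expected hazard ratio
`HR = (O_hi/E_hi)/(O_lo/E_lo)` with the 95% interval
`exp(log HR ± 1.96 √(1/E_hi + 1/E_lo))`. Constant expression is a
degenerate split and is reported per gene rather than aborting the screen.
No multiplicity correction is applied by default — the screen mirrors a
procedure that evaluated each gene individually — but a Benjamini–Hochberg
switch is available. Calibration (type-I error ≈ α on null cohorts),
agreement with a label-permutation oracle, and recovery of a planted log
hazard ratio are asserted by simulation in the tests.

## 5. Enrichment and the pathway interface

`hypergeometric_enrichment()` computes the upper-tail (observed overlap
included) hypergeometric probability per gene set, intersecting each set
with the universe first, and applies Benjamini–Hochberg FDR across the
collection (threshold 0.0001 by default). The universe defaults to the
analyzed network's genes — the natural frame for a network-derived query —
and is configurable.

`pathway_interface()` takes the survival-screen survivors, reports their
Venn membership across the process gene sets, builds one merged network
induced from the interactome over the union of pathway genes and
candidates (interactome edges only — pathway-database relation semantics
are out of scope), and re-runs the H-B/quarter machinery there. Final
pipeline candidates are the survivors that are H-B in this merged network.

## 6. The synthetic-data module

The generators produce every pipeline input with planted truth attached,
under one master seed that fans out to fixed per-generator substreams, so
adding one generator never perturbs another and identical configurations
give byte-identical outputs.

**Expression** (`gen_expression_dataset`): log-normal intensities
(log-scale SD 0.5), with an expressed component shifted
`expression_separation` SDs above the noise component (default **6.0**)
and `frac_expressed` (default **0.05**) of genes expressed, membership
shared across replicates. These two defaults are coupled to the
rank-product calling rule: the pooled-null p-value of a gene sitting at
rank quantile *f* with *r* replicates is
$F(f^r)= f^r\sum_{k<r} \ln^k(1/f^r)/k!$, which at f = 0.05, r = 3 gives
≈ 6×10⁻³ — below the 0.01 calling threshold with margin — whereas at
f ≳ 0.06 it crosses 0.01 no matter how strong the separation. A planted
set larger than ~6% of the genome therefore cannot be *fully* recovered
by this statistic, and separations small enough to mix the components put
the weakest planted genes at noise ranks. The defaults emulate clean
present/absent transcript calls; they are the regime in which full
recovery is the correct expectation, which is what the recovery tests
assert.

**Interactome** (`gen_interactome`): a preferential-attachment backbone
(`attachment_parameter` edges per node, default 2) reproduces the
heavy-tailed degree distribution that hub analysis presumes. A module of
`planted_module_size` (default 10) nodes is densified into a clique and
wired outward with `module_spokes` (default 12) random edges each; two
spoke endpoints per member are designated **anchors**. Anchors are the
device that makes the module's centrality robust under induction: any
downstream gene list that contains the module *and its anchors* yields an
induced network in which every module node keeps pendant neighbours whose
shortest paths to the rest run through it — hence above-average degree
*and* betweenness. Edge confidences are Beta(5, 2), so the 0.400 cutoff
removes a nontrivial minority (~9%) of edges and genuinely exercises the
threshold path; the planted wiring itself (anchor spokes, chemical edges
to module targets) draws from Beta(5, 2) truncated to [0.4, 1], because
planted truth that the stated filter may silently delete would make
recovery ill-defined rather than merely hard.

**Chemical links** (`gen_chemical_links`): each chemical receives
`targets_per_chemical` (default 6) protein targets, 4 from the module and
2 decoys, overlapping between chemicals so the single/both-drug adjacency
partition is populated.

**Disease table** (`gen_disease_table`): planted genes (module + anchors —
disease genes cluster in functional modules) at maximal confidence,
others Beta(2, 2).

**Survival** (`gen_survival_cohort`): standard-normal expression;
exponential event times with baseline hazard log(2)/60 per month (median
survival 60 months, a realistic breast-cancer overall-survival scale);
each planted gene adds `planted_log_hazard` (default 1.0) to the log
hazard of patients above that gene's cohort median; independent censoring
with probability `censoring_rate` (default 0.2) at a uniform fraction of
the event time. Cohort size defaults to 500 patients.

**Morphometry** (`gen_morphometry`): per-class shifts relative to a
control reference (area mean 100, SD 10; shape metrics sized so the
control NII SD is ≈ 0.17): small classes at −4.5 area SD, large at +7
(apoptotic and senescent nuclei differ from normal by far more than the
within-population spread), irregular classes at +4 NII SD split across
the two positively-entering shape terms. Within-class dispersion is 0.8×
the control SD: the control pool mixes a majority normal state with its
own tail morphologies, so a single planted state is modestly tighter.

What the generators do **not** emulate: probe-level microarray artifacts
and normalization effects, literature-mining noise in the disease table,
correlated expression between genes, non-proportional hazards, and
real-database identifier messiness beyond Unicode hyphens. Passing
recovery tests on these generators demonstrates the pipeline's logic and
calibration, not robustness to those real-data pathologies.

## 7. The pipeline and its funnel

`run_pipeline()` executes the stage chain with the thresholds 0.400
(edges), 0.01 (rank product), 1/top-1000 (disease genes), 0.05 (survival),
0.0001 (enrichment FDR), logging each stage's parameters and counts. The
candidate funnel is nested by construction and asserted every run:

> final candidates ⊆ pathway-network H-B ⊆ KM-significant ⊆
> drug-adjacent ∩ consensus H-B core.

Degenerate situations degrade rather than fail: an empty intersection or
an empty candidate pool yields an empty report with warnings (CLI exit
code 2); a chemical that cannot be attached at all aborts with a named
error (`hb_attach_failed`), since a drug screen without drugs is a
configuration mistake, not a result. Intermediate artifacts can be
persisted as TSV after every stage (`out_dir`), making each stage
independently inspectable and re-runnable; two runs with the same
configuration produce byte-identical artifacts.

## 8. Quantitative cell-biology formulas

`population_doubling()` is PD = [log N(t) − log N(t₀)]/log 2 (any log
base; negative when the population shrinks) and `cumulative_pd()` its
running sum over passages, indexed by culture day.

`nii()` is exactly NII = Asp − Arbx + Rr + Rou.
`classify_nuclei()` standardizes area and NII against a control sample
and classifies: size small/normal/large outside `mean ± k_area·SD`, shape
irregular above `mean + k_nii·SD` (one-sided — NII increases with
irregularity by construction of its terms), assembling SR/SI/LR/LIr with
every normal-sized nucleus classed N. The threshold *family* follows the
established nuclear-morphometry workflow; the published procedure
delegates its numeric constants to an external spreadsheet whose values
are not printed, so the multipliers are configuration with defaults
**k = 2** — the conventional ~95% reference band. k = 1 would flag ~32%
of a control-like population as abnormal in area alone, which is
inconsistent with any usable definition of "normal"; k = 2 keeps a
control-like sample ~95% N, which is what the round-trip tests require.

## 9. Problem sizes and numerical choices

The package's own experiments (tests and the acceptance script) run at
desk scale, chosen so the full suite completes in well under a minute:
1000-gene/1000-protein synthetic studies, 500-patient cohorts, 25
random graphs of ≤ 30 nodes against the brute-force betweenness
enumerator, 50×200-gene null matrices at 1000 permutations for
rank-product calibration, 50 null cohorts for survival calibration and 20
end-to-end pipeline replicates. Published applications of this kind of
workflow operate on networks two orders of magnitude larger; nothing in
the implementation is specific to the small scale, but the headline node
and edge counts of any particular published analysis depend on versioned
external resources and are not reproduction targets here.

Numerical conventions collected in one place: midranks on intensity ties;
+1 smoothing in permutation p-values; strict `>` against means and
medians; inclusive `≥` at confidence cutoffs; maximum confidence on
duplicate edges at read time, minimum across networks at intersection;
survival-split ties to "high"; lexicographic tiebreak for equal-confidence
disease genes; all RNG through per-generator substreams of one master
seed.

## 10. Known limitations

- Betweenness is recomputed exactly (Brandes) rather than approximated;
  for networks far beyond ~10⁵ edges a sampling approximation would be
  needed.
- The screen's verdicts inherit the logrank test's proportional-hazards
  lens and the median split's information loss; a Cox model on continuous
  expression is out of scope by design.
- Enrichment reports plain hypergeometric/BH tables; term-grouping and
  pathway-hierarchy handling of the graphical enrichment tools are not
  reproduced.
- The pipeline treats gene and protein identifiers as a single namespace
  (aliases can be resolved through `resolve_aliases()` first); no live
  database clients are included, by design.
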