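---
title: "Comparing and aligning metabolic flux distributions"
author: "fluxalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and aligning metabolic flux distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxalign)
```

## The data model

A **flux map** is a set of central-carbon reactions — KEGG-style elemental
reactions plus `transport`/`unknown` pseudo-reactions — each carrying a
signed stoichiometry, an optional EC class, a compartment label and a net
flux value signed relative to the written equation direction. Flux values
are relative: `normalize_fluxes()` rescales a map by a single factor so the
substrate-uptake fluxes sum to exactly 100 (with several substrates, their
*sum* is 100). A missing measurement is `NA`, never 0: zero means "no net
conversion observed", `NA` means "not estimated", and the two behave
differently everywhere downstream (shared-reaction sets drop `NA` rows;
energetics turn `NA` contributors into N/A ranges).

The on-disk dialect is a five-column table (`id`, `ec`, `equation`, `flux`,
`compartment`) as tab-separated UTF-8 or one-sheet-per-case Excel. The
dialect is this package's own: the community exchanges flux maps through ad
hoc spreadsheet templates that are not formally published, so we define a
lossless, documented format instead and provide converters
(`parse_flux_table()`, `write_flux_table()`, `flux_map_to_json()`). One
consequence of supporting empty equation sides (`"=> g6p"` for feeds): such
strings look like formulas to spreadsheet software, so Excel cells must be
stored as literal text.

We deliberately do **not** unlump reactions. Curated databases break lumped
reactions into KEGG elemental form before deposit; this package validates
structure (every ordinary reaction consumes and produces something) but
treats the decomposition itself as a curation task outside its scope.

## Four similarity measures

Two flux maps are compared on their **shared reaction set**: ids present,
with measured flux, in both maps (case-insensitive), in lexicographic order
so every score is independent of input row order. This shared-set policy is
applied to both the vector and the stoichiometry measure; when the two maps
are the same network the restriction is a no-op.

**Vector similarity** is the angular cosine of the two restricted flux
vectors. It is symmetric, scale-invariant (so un-normalized maps compare
identically), bounded in $[-1, 1]$, and blind to stoichiometry.

**Stoichiometry similarity** first builds each map's *flux matrix*
$F = S\,\mathrm{diag}(v)$ — the stoichiometric matrix with every column
scaled by its reaction's flux — and takes the Frobenius-inner-product cosine
of the two matrices on a common frame (shared reactions × union of
metabolites, zero-filled). Writing the flux-matrix product this way keeps
$F$ an $l \times n$ matrix, which is the only reading under which a
double-indexed Frobenius cosine makes sense; it is algebraically identical
to flattening both matrices and applying the vector cosine, and the test
suite asserts that identity to $10^{-12}$ as an internal consistency oracle.

**Topology-based alignment** treats each map as a weighted directed graph
$G(N, E, W)$. Nodes are reactions; an edge $(i, j)$ exists when a product of
$i$ is a reactant of $j$. The shared-compound coefficient sums
$|s_{ki}| + |s_{kj}|$ over the compounds $k$ flowing from $i$ to $j$; we
compute it as a *net* quantity (forward minus backward sum), which
guarantees the antisymmetry $m_{ji} = -m_{ij}$ that the weighted adjacency
matrix requires — the sign convention in the original description of this
coefficient is internally inconsistent, and antisymmetry is the one property
it states unambiguously, so antisymmetry is what we preserve. $W$ has
$v_i / \lVert v\rVert_2$ on the diagonal and $m_{ij} / \lVert m\rVert_F$ off
it; both blocks therefore have unit norm, which is what pins the scores to
$[-1, 1]$.

Node similarity uses the EC hierarchy: $S_{uv} = 1 / C(h_{uv})$ where
$h_{uv}$ is the longest common prefix of the two EC classes and $C(h)$
counts the **distinct** EC classes under $h$ in the universe of the two maps
being aligned. Counting distinct classes (not reactions) keeps
self-similarity at 1 when isoenzymes repeat a class; using the two compared
maps as the universe (rather than the full EC database) keeps the tool
self-contained — scores are therefore comparable *within* a pair, and mildly
context-dependent across pairs, which we accept and document. Reactions
without an EC class (transport, unknown feeds) match only their identical
pseudo-id, with similarity 1.

The alignment maximizes
$$\lambda \sum_{ij} S_{ij}\,a_{ii} b_{jj}\, x_{ij}
  \;+\; (1-\lambda) \sum_{ijkl} a_{ik} b_{jl}\, y_{ijkl}$$
over one-to-one partial matchings, with $y_{ijkl} \le x_{ij}, x_{kl}$ and
$y$ instantiated only for *edge* quadruples ($i \ne k$, $j \ne l$,
$a_{ik} \ne 0$, $b_{jl} \ne 0$). Excluding the diagonal quadruples is a
deliberate reading: including $i = k, j = l$ would re-count the node terms
and break the self-alignment score of exactly 1. Since both off-diagonal
blocks are antisymmetric, quadruples come in equal-valued pairs, so each
matched pair of node pairs contributes $2\,a_{ik} b_{jl}$.

**λ** trades node against edge score; the default 0.5 is the even
compromise, $\lambda = 1$ is exposed as `enzyme_topology_similarity()` (a
pure linear assignment), and $\lambda = 0$ scores topology alone.

### Two y semantics

Under the constraints as written, a *maximizing* solver simply leaves
$y = 0$ wherever the coefficient $a_{ik} b_{jl}$ is negative. The default
solver is faithful to that relaxation. `strict_y = TRUE` adds the standard
linearization $y \ge x_{ij} + x_{kl} - 1$, forcing negative edge terms into
the objective. `evaluate_alignment()` — which scores a *given* matching
rather than maximizing — defaults to the product semantics
$y = x_{ij} x_{kl}$ for the same reason: when one asks "what does this
particular correspondence score?", dropping its negative terms would be
misleading. This distinction resolves an apparent paradox: a map against its
fully reversed copy scores $-1$ at the structure-preserving matching under
product semantics, while the *maximized* score of the same pair is 0 (the
empty matching), because a maximizer is never forced to accept a negative
alignment.

### The exact solver

No off-the-shelf MILP formulation is needed: the program is a quadratic
assignment maximization, and we solve it exactly by depth-first branch and
bound over injective partial matchings. Rows enter in a static heuristic
order; candidate columns are tried by decreasing incremental gain with index
tie-breaks, so co-optimal matchings resolve deterministically. Pruning
combines (i) an admissible per-row bound — exact positive-part interactions
with matched pairs plus a rearrangement-inequality bound (sorted $|a|$
magnitudes paired with sorted $|b|$ magnitudes) on interactions among
unassigned rows — and (ii) a global Cauchy–Schwarz cap: node part at most
$\lVert\mathrm{diag}\,A\rVert \lVert\mathrm{diag}\,B\rVert = 1$, edge part
at most $\lVert A_{\mathrm{off}}\rVert_F \lVert B_{\mathrm{off}}\rVert_F
\le 1$. A multi-restart greedy (best-pair growth, first pair pinned to every
column in turn) supplies the initial incumbent; for identical maps it finds
the identity matching, which *equals* the cap, so self-alignments terminate
immediately at any $\lambda$. Optimality is certified to an internal
tolerance of $10^{-12}$; the equivalence suites against exhaustive
enumeration and against a Hungarian linear-assignment oracle assert
agreement to $10^{-9}$.

Practical reach: maps of central-carbon size (tens of reactions) align in
well under a second when they are structurally related (which is the
scientific use case); adversarial pairs — e.g. a structured map against a
large random graph at $\lambda = 0.5$ — can exhaust the exponential search,
so `time_limit` aborts with the incumbent (a lower bound) and the cap (an
upper bound) in the error message rather than silently returning a
suboptimal matching.

### Alignment outputs

Per-pair contributions split each edge term evenly between its two pairs and
sum exactly to the score. The report partitions both reaction sets:
matched pairs, *gaps* (unmatched in the first map), *insertions* (unmatched
in the second), and *conserved pathways*, operationalized — since no formal
definition exists — as weakly connected components of two or more nodes in
the matched subgraph (pairs connected in **both** maps). GraphML/SIF export
replaces interactive visualization: both maps' nodes and flow edges plus
`match` edges carrying the contribution, ready for Cytoscape, with a
read-back test asserting attribute round-trip to $10^{-9}$.

## Permutation significance

The P-value of an alignment is the fraction of `n_perm` (default 100,
matching the conventional resolution of 0.01) random-valued variants of the
second map whose alignment score *strictly* exceeds the observed one. The
null keeps topology, stoichiometry and EC labels and resamples only flux
values, i.i.d. uniform on $[0, \max |v|]$ — the minimal reading of "random
sampled values"; it deliberately does *not* enforce mass balance, so the
null asks "does this score beat arbitrary flux numbers on the same
network?" rather than "does it beat plausible metabolisms?". All resampling
flows through a caller-supplied seed and restores the session RNG state.
The calibration property — P approximately uniform when the observed map is
itself drawn from the null, mean within 0.15 of 0.5 over 50 replicates of
100 permutations — is asserted in the test suite on 5-reaction maps, a size
at which 5 000+ exact alignments run in seconds.

## Energetics

`production_range()` recomputes ATP and NADPH production from the flux
values: ATP = substrate-level yield + 2.5 × NADH flux + 1.5 × FADH₂ flux
(the standard P/O ratios), NADPH summed over its producers. Because
isocitrate dehydrogenase and malic enzyme wobble between NAD and NADP, the
report brackets each quantity by the two exclusive-assignment extremes
(all wobble flux to NADH vs all to NADPH) — by construction min ≤ max, and
emptying the wobble set collapses the bracket. The producer table itself is
not canonical anywhere, so the package ships an explicit, fully overridable
default for the central-carbon set (oxidative PPP → NADPH; GAPDH, PDH,
AKGDH, MDH → NADH; SDH → FADH₂; PGK, PYK, SCS → substrate-level ATP;
hexokinase and PFK as ATP investors). Whether reported ATP should be gross
or net of the glycolytic investment is genuinely ambiguous in the
literature, so both conventions are exposed (`gross = FALSE` nets them out
by default). Any contributing reaction with an absent flux turns the
quantities depending on it into N/A — a value, not an error.

## The synthetic generator

`toy_network()` ships two mass-balanced skeletons: a 5-reaction linear
chain (one flux mode — after normalization every flux is 100) and a
22-reaction central-carbon core (glycolysis, oxidative PPP branch, full TCA
cycle, feed and drain; CO₂ external) whose null space has dimension 2, the
glycolytic and pentose-phosphate modes. `sample_steady_state_fluxes()`
draws from the null space of the internal-metabolite stoichiometric matrix
(so $\lVert S v\rVert_\infty < 10^{-9}$ by construction), orients the draw
to positive uptake, rejects draws running irreversible steps backwards, and
normalizes. Null-space sampling is used *because* real curated maps obey
mass balance; the permutation null above deliberately does not.

What the generator does **not** emulate: measurement noise and
identifiability limits of real ¹³C experiments, condition-dependent
reversibility, compartmentation beyond a label, and networks larger than
central carbon. Passing tests therefore demonstrate correctness of the
algorithms on realistic *structure*, not robustness to every artifact of
experimental flux estimates.

`reverse_all()` flips every equation and flux sign (magnitudes preserved):
the weighted adjacency negates, making it the canonical $-1$ fixture.
`perturb_fluxes()` applies multiplicative lognormal noise and renormalizes
— the graded-similarity generator; `random_flux_map()` makes small
arbitrary (deliberately unbalanced) instances for the solver-vs-oracle
suites.

## Numerical choices and problem sizes

* Scores are asserted to $[-1 - 10^{-9}, 1 + 10^{-9}]$; self-alignment to
  $10^{-6}$; solver-vs-oracle equality to $10^{-9}$; Frobenius/flatten
  identity and symmetry to $10^{-12}$; normalization idempotence and mass
  balance residuals to $10^{-9}$.
* Normalization refuses zero total uptake; cosines refuse zero-norm
  vectors/matrices; graph construction refuses incomplete or all-zero flux
  vectors. Empty shared sets are errors for the vector/stoichiometry
  methods and masked (with a warning) in all-vs-all matrices.
* Test and acceptance problem sizes: oracle equivalence on 3–5-node
  instances (where exhaustive enumeration is cheap), identity/reversal on
  the 5-reaction chain and the 22-reaction core, permutation calibration on
  the 5-reaction chain. These sizes were chosen so the whole suite runs in
  about a minute while still exercising every code path at central-carbon
  scale.

## Limitations

* Exact alignment is exponential in the worst case; dissimilar maps beyond
  ~10 nodes may need `time_limit` and judgment. (Structurally related maps
  — the scientific use case — stay fast far beyond that.)
* EC-universe-relative node similarity makes cross-pair score comparisons
  approximate.
* The multi-map interface is all-pairs; there is no simultaneous multi-way
  alignment and no in-house clustering (feed `similarity_matrix()` to
  `stats::hclust()` or similar).
* Excel support is read-only (workbook → TSV); the canonical interchange
  formats are TSV and JSON.
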