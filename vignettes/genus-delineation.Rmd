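---
title: "Methods: identity metrics, the genus gap, and the choices behind them"
author: "genusgap"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `genusgap` implements,
the tunable parameters and their defaults, the numerical and design
choices made where the method description left room, and what the
synthetic-data tests do and do not demonstrate about real data.

## The metrics

### AAI

For proteomes $A$ and $B$, every protein of $A$ is searched against all
of $B$ and vice versa (optimal local alignment, BLOSUM62, affine gaps
with open 11 / extend 1). A pair $(x, y)$ is *reciprocal* when $y$ is
$x$'s best hit and $x$ is $y$'s. Reciprocal pairs are kept when both
directional identities are $\ge$ 40 % and coverage passes at 50 %;
AAI is the arithmetic mean over kept pairs of the per-pair identity
$\tfrac{1}{2}(\mathrm{id}_{xy} + \mathrm{id}_{yx})$.

Three conventions matter and are all configurable:

* **Identity denominator** — matches divided by *all alignment columns,
  gap columns included* (the blast `pident` convention). This makes the
  40 % floor mean the same thing it meant in the original
  tool chain.
* **Coverage direction** — "50 % coverage length" does not say relative
  to what. The default (`coverage_mode = "both"`) requires each
  direction's query coverage to pass — the strictest reading;
  `"either"` and `"shorter"` are available.
* **Per-pair symmetrization** — averaging the two directional
  identities makes AAI exactly symmetric, which the downstream matrix
  contract (symmetry, diagonal 100) relies on.

A pair of proteomes with *no* qualifying pairs yields an explicit
"no qualifying pairs" result (`aai = NA`), never a silent zero: a zero
would otherwise masquerade as an extremely distant comparison.

### POCP

$\mathrm{POCP} = 100\,(C_a + C_b)/(T_a + T_b)$, where $C_x$ counts
proteins of $x$ with at least one hit in the other proteome at
$\ge$ 40 % identity over $\ge$ 50 % of their own length. The published
criterion also caps the e-value at $10^{-5}$; an optimal-alignment
engine has no e-value statistic, so internally a positive-scoring
alignment stands in for it, and the e-value ceiling is applied whenever
hits arrive from an external search tool's 12-column table
(`hits_from_table()`). This is a stated deviation, preserved exactly
when the external adapter is used.

### ANIb

Genome $A$ is cut into consecutive 1020-bp fragments (terminal
remainder kept, flagged); each fragment is aligned to every contig of
$B$ on both strands (+2/−3, gap open 5 / extend 2) and its best
alignment kept. Fragments reaching 30 % identity over 70 % of their
length contribute their identity to $\mathrm{ANI}_{A\to B}$; the
reported `ani_mean` averages the two directions, and both directional
values are always reported because published pairs are asymmetric
("96.14/96.18"-style) without a stated direction order.

## The genus rule and the gap

The delineation rule is two inclusive thresholds on AAI computed at the
40/50 parameters:

* membership: AAI to the genus anchor (type strain of the type
  species) $\ge$ 76 %;
* cohesion: every intra-genus pair $\ge$ 74 %.

Comparisons are inclusive ($\ge$) because the operative wording in
emended genus descriptions is "$\ge$ 76 %" / "$\ge$ 74 %", while the
narrative text says "greater than"; `strict_gt = TRUE` switches to
strict if wanted. Band membership in `band_fraction()` is accordingly
the *open* interval $74 < v < 76$.

`assign_genera()` never resolves conflicts silently: multi-anchor
passes are assigned to the max-AAI anchor but flagged
(`ambiguous_multi_anchor`), strains whose best anchor lies inside the
band are flagged `intermediate`, and intra-genus pairs below cohesion
raise `cohesion_conflict` on both strains. Taxonomic adjudication of
such cases (the historical ones involved hand judgment) belongs to the
user.

### Operationalizing "the two modes"

No numerical definition of the distribution's two modes was ever
published, so `detect_gap()` states one: histogram at 1 % bins; first
mode = highest bin; second mode = highest bin holding $\ge$ 10 % of the
first peak and separated from it by a valley bin at $\le$ 5 % of the
smaller peak; the returned band is the widest maximal run of
minimum-count bins strictly between the modes, required to be
$\ge$ 1 % wide with every bin $\le$ 5 % of the smaller peak. The
prominence (10 %) and valley (5 %) fractions keep stray tail bins of a
unimodal distribution from posing as modes while remaining insensitive
to the absolute sample size; both emerged from probing the detector
with unimodal, uniform and planted bimodal samples across sample sizes
from tens (a 12-strain matrix) to thousands of values.

## Calibration and dating

`fit_quadratic()` is ordinary least squares of AAI on
$(1, \mathrm{ANIb}, \mathrm{ANIb}^2)$; the fitted curve must be
monotone non-decreasing on the observed ANIb range for band inversion
to be meaningful (violations warn). Inversion of the band edges uses
bisection (`uniroot`, tolerance $10^{-6}$) rather than the quadratic
root formula — robust when the curvature term is near zero, where the
closed form loses precision.

`fit_dating()` regresses time on ANI (time is the predicted quantity)
over anchor points. The default anchors are

| label | ANI (%) | time (MYA) |
|---|---|---|
| Permian | 73.25 | 252 |
| Triassic | 80 | 201 |
| present | 100 | 0 |

The Permian ANI is the midpoint of the 72.5–74 % ANIb gap; the
Triassic uses the ~80 % valley. Every plausible anchor triple, fitted
by ordinary least squares, puts the 95 % ANI species boundary near
50 MYA — not at the ~65 MYA sometimes quoted for the K-Pg
coincidence — and no regression specification that reproduces 65 MYA
from these anchors could be reconstructed. The module therefore treats
anchors as fully user-overridable inputs and reports the fit
transparently rather than targeting a particular output. Nothing here
is a causal claim about extinctions; the anchors are interpretive.

## Core-genome supermatrix

The pipeline follows the published cascade with two under-specified
steps made explicit:

1. **Ortholog groups** — proteins are nodes, qualifying reciprocal
   pairs (the same pairings that feed AAI) are edges; a connected
   component is kept iff it has exactly one protein from every strain.
   Components are the simplest reading of "gene pairings were used to
   generate the loci"; a stricter all-pairs-connected criterion is
   available (`clique = TRUE`).
2. **Length filter** — keep a group iff every member is $\ge$ 90 % of
   the group's maximum length (boundary inclusive).
3. **Alignment** — member proteins are aligned with mafft and
   back-translated to codons from their CDS; terminal stop codons are
   stripped first and CDS/protein length consistency is enforced, which
   is the reproducible surrogate for the original "manual refinements
   to align start and stop codons". Groups failing it are rejected with
   a named reason, not repaired.
4. **Divergence filter** — drop a locus iff its pairwise ungapped
   nucleotide identity falls *strictly below* 25 %. The statistic is
   the minimum over row pairs by default ("unusually divergent" most
   plausibly concerns the worst pair); `stat = "mean"` is the
   alternative.
5. **Masking** — concatenate in group order, then delete every column
   containing a gap *or ambiguity code* (ambiguities were not addressed
   in the original description; treating them as gaps is the
   conservative choice) and every invariant column. What remains are
   the core variable sites, with pre-masking partition ranges kept for
   provenance.

Distances use the Jukes–Cantor closed form
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$, with saturated pairs
($p \ge 0.75$, where the formula diverges) capped at 5.0
substitutions/site with a warning. Tree building is plain
neighbor-joining (negative branch lengths clamped to zero) and tree
comparison is the unweighted Robinson–Foulds bipartition count;
maximum-likelihood search, bootstrapping and weighted-RF convergence
diagnostics are deliberately out of scope — the supermatrix exports
(relaxed PHYLIP, FASTA) feed external ML tools.

## The simulator

`simulate_clade()` evolves a random ancestral CDS set along a user
tree. Branch lengths are *per-site amino-acid substitution
probabilities*: each codon, with probability $b$, is replaced by a
codon of a uniformly chosen different amino acid. Two leaves separated
by branches $b_1, b_2, \dots$ therefore match at a site with
probability $\prod_i (1 - b_i)$ (up to rare double-hit collisions), and
`two_leaf_tree(D)` plants a pairwise divergence $D$ by giving each
branch $p = 1 - \sqrt{1 - D}$. Indels act in whole codons and
duplication/loss are per-gene per-branch, all off by default, so CDS
and proteins stay consistent and the ortholog truth is exact. Genomes
are the leaf CDS concatenated with random 50-bp spacers.
`planted_aai_matrix()` draws intra-genus values from
$N(82, 1.5^2)$ and inter-genus from $N(70, 1^2)$, rejection-resampling
anything inside the forbidden (74, 76) band, so gap-detection tests
are deterministic in outcome; the defaults respect the 3-sigma
plantable-gap margin (intra/inter means closer to the band would
violate it and are rejected before sampling).

What the simulator does *not* emulate: GC skew and codon-usage bias,
operon structure, horizontal transfer, rate heterogeneity across sites
and lineages, non-uniform substitution processes, and assembly error
beyond clean contig breaks (`degrade_assembly()` splits without
introducing errors). Passing tests therefore demonstrate the
correctness of the computations and rules on data satisfying their own
assumptions — not that real genomes of a given family will show a gap
at exactly 74–76 %.

## Performance choices

All pairwise DP alignment is delegated to
`Biostrings::pairwiseAlignment`. For proteome searches the package runs
the exhaustive all-vs-all search when $|A|\times|B| \le 2500$; above
that, a shared 3-mer prescreen ranks subjects per query and only the
top `max_targets` (default 8) candidates get exact DP. At 30 %
divergence a true ortholog of length ~100 still shares dozens of
3-mers while unrelated proteins share a couple by chance, so the screen
loses essentially nothing there (the reciprocal-recall test holds
$\ge$ 95 % recall); `max_targets = 0` forces the exhaustive search when
exactness matters more than time. Any external search tool emitting
the 12-column tabular format can replace the internal engine entirely.

Test and acceptance problem sizes — 500 genes for AAI recovery, 4–12
strains for matrices and pipelines, ~6-kb genomes for ANIb — were
chosen as the smallest sizes at which the statistics concentrate well
inside their asserted windows (binomial concentration at 500 genes
gives an AAI standard error ~0.15 points, far inside the ±2-point
window).

## Known limitations

* No e-value model: statistical significance filtering is only
  available through the external-tool adapter.
* ANIb aligns fragments per contig; fragments spanning contig breaks
  of heavily fragmented assemblies lose coverage and are dropped by
  the 70 % criterion (they do not bias retained identities).
* `align_locus()` requires `mafft` on the PATH for non-identical
  members.
* The dating model is a two- or three-point straight line; it has no
  uncertainty quantification and should be read as the transparent
  arithmetic consequence of its anchors.
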