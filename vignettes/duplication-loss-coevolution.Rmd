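---
title: "Inferring and testing correlated gene-family evolution with dupcoev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and testing correlated gene-family evolution with dupcoev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupcoev)
```

## The problem

Gene families expand by gene duplication and contract by gene loss. When two
families participate in the same biological process — for instance enzymes
that write a post-translational modification and enzymes that erase it — one
may ask whether their evolutionary histories are coupled: do branches of the
species tree on which one family expanded tend to be branches on which the
other also expanded, and likewise for contractions?

`dupcoev` implements the full chain of inference needed to ask this question
from gene trees alone:

1. **Rooting** an unrooted maximum-likelihood gene tree by branch-sum
   balance.
2. **Rearrangement** of weakly supported branches so that phylogenetic noise
   is not mistaken for duplication.
3. **Reconciliation** of the (binary) gene tree with a species tree that may
   contain polytomies, by weighted duplication–loss parsimony.
4. **Mapping** of the inferred events onto species-tree branches, per
   family.
5. **Testing** whether the per-branch net gains of one family differ between
   branches on which a second family gained, lost, or did not change.

A birth–death simulator of gene-family histories, with optionally shared
rate episodes between two families, provides ground truth for every stage;
all of the package's empirical claims are checked against it in the test
suite.

## Reconciliation model

Given a rooted binary gene tree, a rooted species tree and a mapping of gene
leaves to species leaves, each gene node is mapped to the last common
ancestor (LCA) of its children's images. An internal node is a
**duplication** when it maps to the same species node as one of its
children, otherwise a **speciation**. Each gene edge whose endpoint images
are separated by $k$ species-tree edges implies $k-1$ **losses** under a
speciation parent and $k$ under a duplication parent; every loss is
attributed to the species node of the off-path sibling subtree in which the
lineage disappeared. The reconciliation cost is

$$C = w_\mathrm{dup}\,n_\mathrm{dup} + w_\mathrm{cond}\,n_\mathrm{cond} +
w_\mathrm{loss}\,n_\mathrm{loss},$$

with default weights $w_\mathrm{dup} = 1.5$, $w_\mathrm{cond} = 0$ and
$w_\mathrm{loss} = 1$ — the standard weighted-parsimony setting for this
kind of analysis. For binary species trees the LCA reconciliation minimises
both the duplication and the loss count simultaneously, hence the weighted
cost for any non-negative weights; the test suite verifies this against a
brute-force enumeration of *all* valid mappings, exhaustively (up to
isomorphism) for every gene tree with up to 6 leaves against every species
tree with up to 4 leaves.

### Species-tree polytomies

Species trees assembled from taxonomies are rarely fully resolved. At a
polytomous species node the duplication status of a gene node can depend on
how the polytomy is resolved. The package follows the resolution semantics:

* a node is a **required duplication** when it is a duplication in *every*
  binary resolution of the polytomy — which holds exactly when the sets of
  polytomy-child subtrees hit by its two gene-child clades intersect;
* it is a **conditional duplication** when it is a duplication in some but
  not all resolutions — hit sets disjoint, but at least one clade spans two
  or more polytomy children;
* otherwise it is a speciation in every resolution.

This equivalence is verified in the tests against explicit enumeration of
all binary resolutions. Conditional duplications carry weight 0 and are
excluded from all downstream event tables. Losses along a path through a
polytomous node are attributed to the polytomous node itself when the
off-path sibling is not unique (a documented choice; any single off-path
sibling would be equally defensible, and the count is unaffected).

Note that on polytomous species trees the reported cost is not comparable
to the cost on a binary resolution: paths through a polytomy are shorter,
and conditional duplications are free. The optimality guarantee is
therefore stated for binary species trees, and the classification contract
for polytomous ones.

### Duplication bounds

Each required duplication is reported with a **lower bound** (the oldest
species node in which the duplicate pair was already present: its LCA
image) and an **upper bound** (the youngest species node in which it was
not: the parent of the image, absent at the species root). Event tables
attribute each duplication to the incoming branch of its lower bound.

## Rooting and rearrangement

`root_balance()` implements the branch-sum variant of midpoint rooting: the
root is placed on the edge, and at the point along it, where the total
branch lengths of the two resulting subtrees (each including its
root-adjacent partial edge) are as equal as possible. This is a
deterministic one-dimensional minimisation per edge with a closed-form
optimum, so no discretisation is involved; a scan oracle in the tests
confirms the argmin.

`collapse_weak_edges()` contracts every internal edge with bootstrap
support strictly below the cutoff (default 90; an edge at exactly 90 is
kept — the cutoff names the weakest acceptable support, and the boundary
choice is configurable). `resolve_min_cost()` then re-resolves each
polytomy at minimum reconciliation cost. Because the LCA image of a
polytomy is the LCA of a fixed leaf set, it is invariant under the
resolution, and so is everything outside the polytomy; each polytomy can
therefore be optimised independently and the concatenation of local optima
is a global optimum over all joint resolutions. Resolution is exact — full
enumeration of the $(2k-3)!!$ local topologies — up to degree 8 (135,135
topologies); beyond that a species-guided greedy join is used and a warning
emitted. `rearrange_tree()` finally keeps the rearranged tree only if its
cost does not exceed the original tree's, so rearrangement can never hurt
parsimony, greedy fallback included.

When the species tree has polytomies the default protocol mirrors the
two-pass procedure used with taxonomy-derived trees: rearrange against a
*randomly* binarised species tree (seeded), then reconcile against the
non-binary one. Random rearrangements introduced by the arbitrary
binarisation map back onto polytomies and can only surface as conditional
duplications, which are discarded.

## The coevolution test

For each family, duplications and losses from all of its reconciliations
are summed per species-tree branch; a branch's **net gain** is duplications
minus losses, and its category is *gain*, *loss* or *no change* by the sign
of the net gain — the simplest rule consistent with calling branches
expansions or contractions. Terminal branches are excluded from testing
(single-species counts say little about ancestral coupling) but kept in the
tables; the species root, which has no incoming branch, is kept as a
flagged row so events mapped to it are not dropped silently.

Internal branches are partitioned by family B's category and family A's net
gains are compared between the *gain* and *loss* groups with the Wilcoxon
rank-sum test — the headline comparison; both remaining pairwise
comparisons are reported as secondary, and the full 3×3 category
co-occurrence table is tested with Fisher's exact test (Freeman–Halton).
Which single comparison should be the headline is genuinely open — the
source analyses print one p-value over three groups — and gain-vs-loss is
the contrast that directly expresses "expansions here, contractions there".
A `min_events` filter (default 0, i.e. off) restricts the comparison to
branches with a minimum level of family-A activity, since weak branches
carry mostly noise.

### Statistical kernels

The Wilcoxon test uses midranks, an exact enumeration of rank assignments
when $n_1 + n_2 \le 12$ without ties, and otherwise a normal approximation
with tie correction and continuity correction. Fisher's test is the exact
hypergeometric two-sided sum for 2×2 tables; larger tables are enumerated
exactly when the grand total is at most 60 and otherwise sampled
(`stats::r2dtable`, at least $10^5$ tables) with the Monte-Carlo standard
error reported. These kernels are implemented in the package because the
switching rules above are part of the analysis contract; `stats::wilcox.test`
and `stats::fisher.test` serve as independent cross-checks in the tests,
and Pearson copy-number correlations use `stats::cor` directly.

## The simulator

`sim_family()` evolves a gene family inside a species tree by an exact
linear birth–death process: one copy enters at the species root, every
lineage duplicates at rate $\lambda$ and dies at rate $\mu$ per unit branch
length (exponential waiting times), and every lineage splits at every
speciation. Along a root-to-leaf path of length $T$ the expected extant
copy number is $e^{(\lambda-\mu)T}$, which the tests verify to within three
Monte-Carlo standard errors.

The defaults — 30-species Yule tree (rate 1.0), $\lambda = 0.3$,
$\mu = 0.2$, episodes multiplying a rate by $\rho = 10$ on 20% of branches,
NNI noise probability 0.1 — are the study conditions used across the test
suite and the acceptance script. **Episodes** model lineage-specific
expansions and contractions: in the default `paired` mode half of the
episode branches elevate the duplication rate (expansions) and a disjoint
half elevate the loss rate (contractions). Both kinds are needed: a
generator that only accelerates duplications never produces contraction
branches, leaving the loss category of the coevolution test empty.
Episodes are placed on internal branches because they represent ancestral
events — the events the coevolution statistic, which is defined on internal
branches, is meant to detect; an episode on a terminal branch is invisible
to it. Under `shared_episodes = TRUE` two families draw the same branch
sets (the correlated regime); otherwise each family draws independently.

The simulator records, per branch, both **true** and **observable** event
counts. A duplication is observable when both daughter lineages leave
extant descendants *and* the species LCAs of the two descendant sets are
ancestrally comparable; it is then attributed to the LCA of all its extant
descendants — the oldest node at which it is reconstructible, i.e. its
lower bound. With this definition, parsimony reconciliation of the
noise-free surviving gene tree recovers the observable per-branch
duplication counts exactly, which the acceptance suite checks over 200
replicates. Totals of observable events never exceed totals of true events;
per individual branch this need not hold, because parsimony necessarily
places an event at its reconstructible position, which can lie below the
branch where it truly occurred.

`add_noise()` perturbs each internal edge by a random nearest-neighbour
interchange with probability `noise_p` and assigns supports from 50–89 to
perturbed edges and 90–100 to clean ones, emulating the signature of
phylogenetic reconstruction error that the rearrangement stage is designed
to absorb. It emulates topology error only — not alignment error, rate
heterogeneity, or biased rooting — so passing tests demonstrate robustness
to topological noise at weakly supported edges, not to every failure mode
of real data.

### What the simulation studies show — and one negative result

At the default study conditions the package's guarantees hold exactly:
rearrangement never increases cost (strict improvement in the large
majority of noisy replicates), and event recovery on noise-free trees is
exact in 100% of replicates. The coevolution test, however, is **underpowered
at these rates**: with expected copy numbers near 1.3 and internal branches
averaging ~0.46 time units, a ×10 episode yields on the order of one event,
the gain and loss groups contain only a handful of branches, and the exact
rank-sum test rejects at $\alpha = 0.05$ in only roughly a fifth to a
third of correlated replicates, depending on the species tree drawn. Under the null the same discreteness makes the test strongly
conservative (empirical size well below 2%). These measured rates are
reported by the acceptance script rather than hidden; detecting coupling
reliably at desk scale requires either larger families (higher $\lambda$,
more copies) or more species than the default conditions provide.

## Sequence-side helpers

Three bespoke pre-processing procedures used when building family profiles
are included:

* `ml_pairwise_distance()` — maximum-likelihood distance between two
  aligned amino-acid sequences under the LG substitution model (published
  exchangeabilities and stationary frequencies, rate matrix normalised to
  one expected substitution per site; spectral decomposition computed once
  and cached). The 1-D likelihood optimisation uses `stats::optimize` to
  tolerance $10^{-6}$, estimates are capped at 10 substitutions/site, and
  pairs with no overlapping non-gap columns yield `Inf` with a warning.
  `phangorn::dist.ml` is the independent cross-check in the tests.
* `subset_select()` — reduces a redundant homolog set to $k$
  representatives by iterating two steps: find the closest pair, then drop
  the member of that pair with the larger total distance to the current
  set. Ties break lexicographically (smallest id pair; on a total-distance
  tie the larger id is dropped) so the result is deterministic and
  independent of input order.
* `filter_columns()` / `filter_hits()` — alignment-column selection by
  non-gap fraction (≥ 0.80) and conservation (≥ $5\times10^{-6}$), and
  domain-hit filtering by score threshold plus required motif or
  per-column residue constraints. The conservation score is the mean
  BLOSUM62-derived pairwise similarity of the column's residues rescaled
  to $[0,1]$ — a near-zero-floored score, which is what makes a threshold
  like $5\times10^{-6}$ meaningful. It is applied per column (not
  windowed), and the score function is pluggable. Column indices are
  returned 1-based, following R convention. The score threshold for hits
  is deliberately a user decision (it is chosen by inspecting the
  length–score distribution; `hit_score_by_length()` summarises it) —
  the package does not guess it.

## Numerical and degenerate-input choices

* Supports live on the child node of their edge; rerooting re-homes them,
  and the two root-adjacent edges share the support of the split they both
  represent.
* Missing supports are treated as weak at the collapsing stage (logged).
* Tied optima (rooting position, resolution cost, subset ties) are broken
  deterministically: first edge in traversal order, first enumerated
  topology, lexicographic ids.
* A family that goes extinct in simulation is a valid outcome and is
  flagged; single-copy and single-leaf gene trees reconcile trivially with
  cost 0.
* Zero-length branches are preserved and distinct from absent lengths in
  newick I/O.
* Exact-test p-values compare table probabilities with a relative
  tolerance of $10^{-7}$ to absorb floating-point ties, the same guard used
  by the reference implementations.

## Problem sizes used by the test suite

Exhaustive reconciliation optimality runs over all species-tree shapes with
≤ 4 leaves and all gene-tree shapes with ≤ 6 leaves up to isomorphism
(~13,000 cases); congruence checks use random species trees up to 50
leaves; rearrangement and event-recovery checks use 200 simulated
30-species families each; power and size of the coevolution test use 200
and 1000 replicates; simulator calibration uses 2000 replicates on an
8-species tree. The simulator caps a family at $5\times10^4$ lineages (configurable);
replicate draws that hit the cap (a rare possibility under stacked
×10 episodes) are discarded and redrawn, so all replicate statistics
are conditional on the family staying below that size. These sizes give Monte-Carlo standard errors small enough
for the stated bounds while keeping a full run of the suite at desk scale.

## Limitations

* Horizontal transfer is not modelled; incongruence is explained by
  duplication and loss only.
* Reconciliation is parsimony-based; probabilistic reconciliation is out
  of scope.
* The coevolution test treats branches as independent observations; it
  does not correct for phylogenetic autocorrelation beyond conditioning on
  the branch partition, and, as measured above, it has limited power on
  small, slowly evolving families.
* The simulator's rate episodes are piecewise-constant per branch; real
  rate variation is continuous and lineage-correlated.
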