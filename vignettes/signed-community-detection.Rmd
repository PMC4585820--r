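---
title: "Community detection in signed networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community detection in signed networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CPMap)
```

# The problem

Many relational datasets — trust/distrust in online platforms,
activation/inhibition in regulatory networks, alliance/rivalry in social
systems — are *signed* graphs: edges carry a positive (affinity) or
negative (antagonism) weight. A community in such a graph is a group with
dense internal positive connectivity, few links to the rest of the
network, and as few internal negative ties as possible. Most community
detectors ignore edge signs; this package provides a complete signed
pipeline: a quality measure (the signed map equation, *SiMap*), a family
of partition generators (the signed Constant Potts Model, *CPM*, optimized
by Louvain with refinement), a scale-selection rule combining the two
(*CPMap*), baselines (signed modularity, the unsigned map equation), the
*NVI* partition metric, and benchmark generators with planted ground
truth.

# The signed map equation (SiMap)

The unsigned map equation scores a partition by the expected number of
bits per step needed to encode a random walk under a two-level codebook:
one codebook addresses modules, and each module has a private codebook for
its member nodes plus an exit word. Good partitions trap the walker, so
within-module codes are short and module switches rare.

Negative ties enter by *reweighting the walk* under the assumptions that
(i) if a node's negative weight toward a foreign module matches or exceeds
its positive weight toward it, the walker should not go there at all, and
(ii) the same holds for the inside of its own module. Concretely, for node
$i$ in module $c_i$:

1. **External cancellation.** Flow from $i$ toward each foreign module
   $c'$ is scaled by $\max\!\big(0,\,1 - w^-_{i,c'} / w^+_{i,c'}\big)$.
   The removed mass $p_{i,\mathrm{back}}$ is redistributed over $i$'s
   internal positive links in proportion to their weights: external
   enemies keep the walker home.
2. **Internal expulsion.** The internal flow (original plus backflow) is
   then scaled by $\max\!\big(0,\,1 - w^-_{i,\mathrm{in}} /
   w^+_{i,\mathrm{in}}\big)$. The mass removed here, the *negative
   teleport* $\tilde p_i$, is spread uniformly over all $N_G$ nodes
   (including $i$): internal enemies push the walker anywhere.

Conservation holds exactly: reweighted outflow plus $\tilde p_i$ is 1 for
every node, and with no negative ties the transition probabilities are the
untouched $w^+_{ij}/s^+_i$. If a node has no internal positive links the
backflow has nowhere to land and joins the teleport — one of the places
where the design was genuinely open; routing it uniformly is the only
choice consistent with "the walker must not re-enter the cancelled
module".

A worked example, frozen as a unit test: a node with positive strength 4
(two internal links, one link each to modules $c_2$ and $c_3$), equal
positive and negative weight toward $c_2$, and one internal negative tie
against two internal positive ones. The $c_2$ flow (1/4) is fully
channeled back inside, the internal mass becomes $1/2 + 1/4 = 3/4$, the
internal negative halves it, and $3/8$ of all flow teleports.

Visit rates use *smart teleportation*: power iteration of the
teleport-augmented chain (teleport rate $\tau$, target weights
proportional to positive strength $s^+_j$) from the uniform distribution,
followed by one extra teleport-free step; module exit probabilities are
computed teleport-free as well. This removes the teleporter's bias from
the reported flows while preserving ergodicity during iteration. The MDL
in bits is then the standard two-level expression over visit rates $p_i$
and exits $q_c$, with $0\log 0 \equiv 0$ and all logs base 2.

Two qualitative consequences, both covered by tests: adding *external*
negative ties can only lower the MDL of the planted partition (fully
cancelling externals reproduces the zero-mixing MDL exactly on
two-community benchmarks), and adding *internal* negative ties raises it
toward the level of a graph with no internal ties at all. The reward is
module-wise: negative ties between modules without positive inter-ties
change nothing.

# Signed CPM and its optimization

SiMap cannot be optimized by local moves (a move changes the reweighting
globally), so partitions are generated by the signed Constant Potts Model
at resolution $\lambda$:

$$H(\lambda) = \alpha \sum_c \big(\omega^+_c - \lambda N_c (N_c - 1)\big)
 - (1 - \alpha) \sum_c \big(\omega^-_c - \lambda^- N_c (N_c - 1)\big),$$

maximized over partitions ($\omega^\pm_c$ are directed internal weight
sums). $\lambda$ is a density threshold: modules denser than $\lambda$ are
rewarded, sparser ones punished, and sliding $\lambda$ from 0 upward zooms
from the whole graph into ever smaller, denser groups. Two parameter
choices matter:

* $\lambda^- = 0$: *any* internal negative density is punished. A positive
  $\lambda^-$ would reward modules whose internal negative density stays
  below it — the same defect that makes signed modularity inflate modules
  as negative ties accumulate (see below).
* $\alpha = 1/2$: one unit of positive weight cancels one unit of negative
  weight; the signed objective then equals exactly half the unsigned CPM
  of the net-weight graph $w^+ - w^-$, which the tests verify on random
  instances.

The internal pair count uses $N_c(N_c-1)$ (no self-pairs), consistent with
directed-sum bookkeeping; the $N_c^2$ convention found in part of the CPM
literature is available behind the `selfPairs` flag of `cpmValue()`.

Optimization is Louvain with refinement, shared by all objectives
(including the baselines, to keep comparisons honest): singleton start,
seeded-random sweeps moving each node to the neighboring module with the
best exact gain (improvement threshold $\varepsilon = 10^{-12}$ against
floating-point cycles; ties to the lowest module id; an empty module is
always a candidate so nodes can escape), aggregation into super-nodes with
positive and negative weights kept separate, and recursion. Refinement
(default 4 rounds, after which gains were negligible) alternates
leaf-level sweeps with re-running Louvain *inside* each module and
proposing the resulting submodules as unit moves, accepted only under
exact global deltas — so the objective never decreases. Set-move deltas
are computed from module aggregates in time proportional to the set's
incident links and are fuzz-tested against from-scratch recomputation to
$10^{-10}$.

# CPMap: selecting the scale

CPMap feeds a grid of resolutions to the CPM optimizer and returns the
partition with minimal SiMap. The search keeps an interval $[a,b]$ with
$N+1$ equally spaced evaluations (memoized): while the minimum is attained
at the right edge — including ties, since a flat stretch means the
structure resolves further right — the interval is extended rightward with
doubled width (capped at `maxLambda`); once an interior minimum appears
the interval is re-centered and shrunk around it until the spacing reaches
$L$. Defaults $N = 4$, $L = 0.005$ start the search on $[0, 0.02]$, inside
the smooth initial drop observed on graphs with clear structure; the MDL
curve is smooth enough that halving $L$ changes the selected map by well
under 1% (tested). $\lambda = 0$ is scored via the all-in-one partition
directly (optimizing at exactly 0 is degenerate on connected graphs), so a
curve that only rises away from 0 yields the all-in-one output: "no
community structure" is a first-class answer.

`negativeTieReport()` runs the scan twice — signed CPM, and CPM+ on the
positive subgraph — and compares the two partition families on the signed
graph: when the signed family reaches a lower MDL, the negative ties are
*informative*; the smallest scale at which CPM+ already places 95% of the
negative weight between modules quantifies how far the "negatives lie
between dense positive regions" pattern extends without using sign
information.

# Baselines and the modularity inconsistency

Signed modularity $Q = \alpha Q^+ - (1-\alpha) Q^-$ (Newman modularity per
subgraph, default $\alpha = \omega^+/(\omega^+ + \omega^-)$) is provided
with the same optimizer. Its null-model term *rewards* same-module node
pairs with high negative strengths and no actual negative tie between
them; as negative weight accumulates anywhere in the graph, this reward
overwhelms the positive-density term and modules inflate regardless of
density. On twin-layer benchmarks coupled only by negative ties the
largest modularity module grows with the coupling until each layer is one
module — immediately so at $\alpha = 1/2$ — while CPMap keeps the correct
layer communities throughout. The tests reproduce both behaviors.

The unsigned map-equation baseline (`optimizeUnsignedMap()`) ignores
negative ties; on undirected unsigned graphs the visit rates have the
closed form $s_i/\omega$, so it runs entirely on incremental deltas within
the shared Louvain machinery, and it is validated against a brute-force
enumeration oracle on all fixtures up to 8 nodes.

# Benchmark generators

`generateLFR()` plants scale-free structure: degrees from a truncated
power law (exponent 2; the minimum degree is solved so the truncated mean
hits the target mean degree, default 20, maximum 50) and community sizes
from exponent 1 on [20, 100] — the standard LFR regimes for the two
distributions. Each node gets $\approx(1-\mu_{out})k_i$ internal and
$\approx\mu_{out}k_i$ external stubs, wired by a configuration model;
conflicting pairs (self-loops, duplicates, internal "external" pairs) are
repaired by partner swaps accepted only when both resulting pairs are
admissible, and irreparable stubs are dropped and reported. Nominal
parameters are therefore approximate by construction, and the generators
report realized (empirical) values — the honest quantity to condition on.

`signifyLFR()` flips per-node quotas of external (internal) positive links
to negative, keeping endpoints, with flips preferentially shared between
two nodes that both still need them so realized fractions track nominal
ones. With $\mu_{out} = 0.6$, $\mu^-_{out} = 0.25$ each node ends with
roughly 40% internal-positive / 25% external-negative / 35%
external-positive links. `generateCoupledLFR()` duplicates one LFR layer
and adds per-node quotas of positive ($\mu_c$) and negative ($\mu^-_c$)
links strictly between twin communities (independent additive budgets —
the one open reading of the coupled design, chosen because it lets the two
phases be swept independently). Reference partitions `single`, `couple`
and `allInOne` are returned; `single` refines `couple` by construction.
The signed LFR's negatives are deliberately *uninformative* (flipping
external positives to negatives only sharpens the positive structure);
informative negatives require the coupled benchmark's third phase, where
positive coupling has merged the twins and negative coupling must be read
to separate them again.

What passing on these benchmarks does **not** show: real signed networks
have degree–sign correlations, reciprocity structure and clustering that
the generators do not emulate, and all generated weights are ±1, so the
weighted code paths are exercised only by randomized unit tests, not by
the benchmark reproductions.

# Numerical choices and limitations

* Power iteration: uniform start, L1 stopping tolerance $10^{-14}$ by
  default (the successive-iterate difference approaches the double-
  precision floor near $10^{-15}$ on graphs of a few thousand nodes, so
  the tighter value risks spurious non-convergence errors), iteration cap
  $10^4$, error with the final residual on failure. Teleport rate $\tau =
  0.15$, the customary map-equation value; results are insensitive to it
  because reported flows are teleport-free.
* Entropies in bits; $0\log 0 \equiv 0$; MDL comparisons in the scale
  selection use a $10^{-9}$-bit tie tolerance.
* Degenerate inputs: nodes with zero positive strength are rejected with a
  pointer to `preprocessSignedGraph()` (whose largest-component step runs
  on the union of positive and negative edges — negative edges are data,
  not absence of relation — and whose zero-positive-node removal runs
  once, followed by one component re-take, not iterated to a fixed point).
  A pair carrying both signs after merging is resolved by net weight.
* Problem sizes in the shipped validation experiments: benchmarks of
  1000 nodes (or two 1000-node layers), 2–10 seeds per condition, chosen
  as the smallest sizes at which the mesoscopic effects under study are
  unambiguous. One quantity moves visibly with size: the mixing level at
  which community structure stops being detectable by description length
  is near $\mu_{out} = 0.65$ at 1000 nodes (at this size the planted
  partition's own MDL already exceeds the single-module MDL there),
  whereas larger graphs sustain detectability to higher mixing.
* SiMap is a selection criterion here, never an optimization target; a
  direct SiMap optimizer (each move re-solves the stationary distribution)
  is out of scope, as are hierarchical (multi-level) codebooks, directed
  flow models, and overlapping communities.
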