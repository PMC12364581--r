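---
title: "Dynamics and combinatorics of mutually repressive gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics and combinatorics of mutually repressive gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(togglen)
```

## The model

A toggle-n network (`Tn`) is a caricature of multi-lineage cell-fate
decision circuits: `n` master transcription factors, each repressing all the
others. `togglen` studies what steady states such circuits can reach, how
robust those states are to perturbation, and what additional mechanisms are
needed to drive the circuit into a *single-positive* state in which exactly
one factor is expressed — the signature of terminal differentiation.

States are vectors $x \in \{-1,+1\}^n$, with $x_i = +1$ meaning gene $i$ is
ON. The low state is $-1$ rather than $0$ so that a silent repressor still
releases its targets. Regulation is a signed adjacency matrix `Adj`, indexed
(regulator, target): `Adj[i, j]` is the weight of the edge from $i$ onto
$j$ ($+$ activation, $-$ inhibition, $0$ none). One *time step* updates a
single node $j$, chosen uniformly at random among the non-clamped nodes,
to the sign of its weighted input

$$x_j \leftarrow \operatorname{sign}\Big(\sum_i x_i\,\mathrm{Adj}_{ij}\Big),$$

holding the current value when the sum is exactly zero. The tie rule is
applied literally and never randomized: integer-weighted circuits genuinely
produce zero sums, and the hold branch is what makes some states
*meta-stable* (self-maintaining under some update orders, yet able to
escape). A state is a fixed point when no single-node update can change it —
an exact test, independent of the random update order.

`find_steady_states()` draws `n_init` initial conditions uniformly (with
replacement; the default 100 000 exceeds $2^n$ for small circuits, matching
the study protocol), relaxes each for at most `max_steps = 1000` single-node
updates, and discards non-converged trajectories. Frequencies are reported
relative to the converged trajectories of each replicate, with the converged
fraction reported separately, and summarized across `n_replicates = 3`
replicates as mean and normal-approximation 95% CI. `F(k)`, the summed
frequency of states with exactly `k` high *core* nodes, is the headline
statistic; `F_A(1)` is the frequency of the state in which only the focal
node `A` is high.

Two implementation details are worth stating. The 1000-step cap counts
single-node updates (the natural unit of the asynchronous scheme, not
sweeps), and the fixed-point test is evaluated every `n` updates to amortize
its cost — correctness is unaffected because the test is exact. A single
root seed drives everything; replicate and trajectory streams are derived
from it deterministically, so runs are bit-reproducible (the engine uses its
own rejection-sampled integer draws rather than library distribution
objects, which keeps streams identical across compilers).

## Network families

* `make_toggle(n, self_regulation)` — all off-diagonal entries $-1$;
  diagonal $0$, $+1$ or $-1$.
* `make_impurity_variants(n, n_imp)` — toggles with `n_imp` inhibitions
  flipped to activation. Because the pure toggle is symmetric under all node
  permutations, variants are reduced to non-isomorphic representatives;
  isomorphism is decided on the unweighted digraph of activating edges
  (VF2, via igraph). When the number of edge combinations is enumerable
  the list is enumerated, filtered, then capped (100 variants for
  $n \le 5$, 50 for $n = 6$); otherwise combinations are sampled uniformly
  without replacement and filtered until the cap. $n > 6$ is refused as
  combinatorially infeasible.
* `make_team_network(sizes)` — teams with intra-team activation and
  inter-team inhibition; size-1 teams reduce exactly to the toggle.
  `sample_unequal_teams()` draws multinomial splits, rejecting draws with an
  empty team or any team of exactly the mean size (the literal rejection
  rule of the study design, enforced by rejection sampling with an explicit
  budget).
* `embed_in_random(network, spec)` — the circuit is merged into a uniform
  random simple digraph (no self-loops; reciprocal edges allowed, as
  nothing in the design forbids them) with exactly
  `size * density` edges of weight $\pm 1$, and **every** ordered
  core–host pair receives an independent weight from $\{-1, 0, +1\}$ with
  equal probabilities. Defaults: sizes 10/15/20, densities 2/4/6,
  100 replicate hosts.

## Interventions

`randomize_edge_weights()` rescales every edge by an independent $U(0,1)$
draw (signs preserved) to model heterogeneous interaction strengths.

`apply_asymmetric_weight(network, A, W)` strengthens the repressions *from*
`A` only while `A` is high: its targets receive $-W$ when $x_A = +1$ and the
unmodified $+1$ contribution when $x_A = -1$. Because the rule is
state-dependent it lives inside the update-rule input assembly, not in the
adjacency; the simulator and the exhaustive enumerator share that one code
path, so Monte-Carlo results can always be checked against exact
enumeration.

`attach_cytokine(network, A, W_C, mode)` adds a signalling node with weight
$+W_C$ onto `A` and, in `activate_and_inhibit` mode, $-W_C$ onto every other
core node. The cytokine is *clamped* at $+1$: it has no incoming edges, so
under the tie-hold rule a $+1$ initialization would behave identically, and
clamping makes the "constitutive signal" semantics explicit while removing
any dependence on initial-condition sampling. Cytokine nodes are excluded
from the update draw and from `F(k)` counting.

`threshold_scan()` walks the integer grid $W \in \{1..10\}$,
$W_C \in \{0..10\}$ and records `F_A(1)` per cell, then extracts the minimal
$W$ (and minimal $W_C$) at which some cell reaches complete differentiation.
Saturation is exact in these dynamics — when a cell differentiates, the
A-only state is the *unique* fixed point — so the completion test uses
$F_A(1) \ge 1 - 10^{-6}$ with the tolerance exposed as an argument.

One caveat this package's exact machinery surfaces: for even-sized toggles
with an activating-only cytokine, exhaustive enumeration shows the A-only
state becomes the unique fixed point already at $W \ge n - 1$, $W_C = 2$, so
the minimal signalling strength over the grid is 2; the parity rule "3 for
odd networks" does hold, and can be traced to tie-held obstruction states
that only exist at even input counts.

## Multi-level dynamics

The 2l-level extension gives each node values
$\{\pm k/l : k = 1..l\}$ (zero excluded; $l = 1$ recovers the Boolean
model — the package uses literally the same engine). The update normalizes
the input by the node's in-degree $d_j$ (the count of its nonzero incoming
weights, self-edges included — the reading under which $l = 1$ reduces
exactly to the Ising rule) and maps $s = \sum_i \mathrm{Adj}_{ij} x_i / d_j$
to the bracket it falls in: $(k-1)/l < s \le k/l$ gives $+k/l$, the mirror
bracket gives $-k/l$, anything beyond $\pm(l-1)/l$ saturates at $\pm 1$, and
$s = 0$ holds. Bracket comparisons are done in integer arithmetic
($|s|\,l = |\sum \mathrm{Adj}_{ij} m_i| / d_j$ with integer level indices
$m_i$), so boundaries are exact for integer-weighted networks. Initial
conditions are uniform over the $2l$ levels independently per node.

For team networks the result carries *team scores* (mean member expression)
and their discretization to $\{0, 1, 2\}$: 2 at a normalized score of
exactly $+1$, 0 at exactly $-1$, 1 strictly between, with the profile
written as the descending symbol string ("22000"). The normalization
reference is the maximum expression level the dynamics actually *sustain*,
read off the steady states carrying at least `min_mass = 0.001` mean
frequency. The reference matters: with five or more teams the dominant
fixed points sit at $\pm 1/2$ — the grid maximum is never sustained — and
those states are fully polarized team patterns, while rare tie-held mixed
states (aggregate mass $\sim 10^{-4}$) do contain extreme values and would
otherwise distort the reference. For a single state,
`discretize_profile()` defaults to the grid maximum 1.

Multi-level simulation of non-team networks is allowed but warned about:
the analyses in this package are designed around team networks.

## Counting compatible update logics

The Ising rule is one choice of update logic. To ask which results depend on
it, the package enumerates *every* Boolean update logic compatible with the
toggle wiring: each node's function must be decreasing (antitone) in each of
its $n-1$ inputs, since all its regulators are repressors. Here states live
in $\{0,1\}$, with 1 corresponding to the high Ising level.

Decreasing functions of $s$ inputs are counted by the Dedekind number
$D(s)$; `enumerate_decreasing_mbfs()` builds them as down-sets of the
Boolean lattice via complemented inputs — truth-table positions are visited
in an order where every subset precedes its supersets, and a position is
free only when all its immediate predecessors are 0 — which touches only
the $D(s)$ valid tables instead of all $2^{2^s}$ candidates ($D(5) = 7581$;
beyond 5 inputs enumeration is refused). Truth tables are stored with the
canonical input of Hamming weight $j$ at index $2^j - 1$.

Because a decreasing function's output distribution depends only on the
number of ones in the input, two vectors suffice: $u_n(j)$ / $v_n(j)$, the
number of decreasing functions of $n-1$ inputs whose output at an input with
$j$ ones is 0 / 1. The number of function tuples for which the canonical
$k$-high state is a fixed point is then the product

$$\phi_k^n = v_n(k-1)^{\,k}\; u_n(k)^{\,n-k},$$

each high node seeing $k-1$ ones and demanding output 1, each low node
seeing $k$ ones and demanding output 0. `brute_force_phi()` re-derives
$\phi^n$ for $n \le 3$ by explicitly testing all $D(n-1)^n$ tuples — an
independent oracle for the product formula. Counts are returned as doubles;
for $n = 6$ the middle entries exceed $2^{53}$, so the exact factored form
(e.g. $5573^6$) travels alongside as an attribute.

## The T-helper case study

The packaged 5-node network of CD4+ T-cell master regulators (TBX21/Th1,
GATA3/Th2, RORC/Th17, FOXP3/Treg, BCL6/TFH) is an *incomplete* toggle-5: 16
of 20 possible repressions are present — the first four regulators mutually
inhibit (12 edges), TBX21 and BCL6 mutually inhibit (2), and BCL6 represses
GATA3 and RORC (2); no reported repression of BCL6 by GATA3/RORC/FOXP3 and
no BCL6→FOXP3 edge. A `self_activation` variant adds self-edges on the four
documented self-activators. Steady states are labelled by hybrid names
("Th1/Th2") joined in canonical lineage order.

Cytokine stimulation attaches one clamped node per exogenous cytokine of
the stimulated lineage (Th1: IFN-γ, IL-12; Th2: IL-4, IL-2; Th17: TGF-β,
IL-6, IL-21; Treg: TGF-β, IL-2), each activating the lineage's regulator
and repressing the others present. The multiplicity matters: a single ±1
signal leaves tie-held opposite states in the 2-node subnetwork, while the
lineage's actual cytokine count drives complete differentiation at unit
weights, as reported. Two literature-derived deviations ship as explicit
per-cytokine overrides (`thelper_cytokine_overrides()`): IFN-γ also
activates FOXP3, and TGF-β activates RORC; the full cytokine–regulator
interaction table is not bundled, and further overrides can be supplied in
the same format.

## What the synthetic conditions do and do not show

All inputs here are generated by the package itself under the study's
stated conditions (uniform initial states, integer weight grids, $U(0,1)$
weight noise, uniform random hosts). Passing tests therefore demonstrate
internal consistency of the model family — Monte-Carlo against exact
enumeration, simulation against combinatorial counts — not fidelity to any
measured biological network: real regulatory circuits have unequal,
context-dependent interaction strengths, autocrine signalling, and
topologies far from complete graphs. The edge weights are qualitative
abstractions, not measurable biological parameters.

Problem sizes are chosen to keep the full verification cheap: test and
acceptance simulations use $10^4$ initial conditions (CI half-widths on
frequencies of order $10^{-2}$), threshold scans one replicate per grid
cell, and the five-team acceptance run uses equal teams of two members.
Exhaustive cross-checks cover all networks up to 12 nodes and multi-level
state spaces up to $4^{10}$.

Known limitations: no synchronous or probabilistic update modes and no
continuous (ODE) dynamics; monotone-function counting covers pure toggles
only ($n \le 6$ by Dedekind growth; sampling-based estimation for larger
$n$ is not implemented); scale-free or hierarchical host topologies are not
generated.
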