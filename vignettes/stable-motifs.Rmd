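---
title: "Stable motifs: attractors and control of logical network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable motifs: attractors and control of logical network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stablemotifs)
```

## The modelling framework and its assumptions

A logical network model consists of binary node states
$\sigma_1,\dots,\sigma_N$ and one Boolean update rule $f_i$ per regulated
node. We use general asynchronous updating: at each discrete step one node,
chosen uniformly at random, is updated,
$\sigma_j(t+1) = f_j(\sigma_{j_1}(t),\dots,\sigma_{j_k}(t))$, while all
others retain their state. This samples every relative timescale of the
underlying processes and makes no kinetic assumptions beyond the
combinatorial logic of activation and inhibition. Input nodes (nodes
referenced by rules but carrying none) represent external conditions; all
analyses require an explicit environment assignment for them
(`bn_environment()`), reflecting sustained external signals. Analysis never
proceeds with unassigned inputs, and a node clamped to contradictory values
is an error rather than a silent resolution.

## Stable motifs as minimal self-sustaining sets

The *expanded network* contains two literal nodes per network node (one per
state; the state-0 literal is the complementary node) and one composite
node per multi-literal prime implicant of each literal. Canonicalization
uses the Blake canonical form — *all* prime implicants, computed by
Quine–McCluskey over the rule's truth table — because completeness of the
composite nodes is what guarantees that no motif is missed; any smaller DNF
could hide a sustaining implicant.

Operationally the package finds stable motifs as the **minimal nonempty
consistent self-sustaining literal sets**: every literal in the set has at
least one prime implicant wholly inside the set, no node appears in both
states, and no proper subset has the same property. Minimality makes the
supporting subgraph strongly connected — in any choice of sustaining
implicants, a source strongly connected component would itself be
self-sustaining, contradicting minimality — so these sets are exactly the
minimal strongly connected partial fixed points, and they coincide with the
minimal nonempty trap subspaces of the dynamics. Rules that are constant
(or become constant once the environment percolates) are resolved before
the search: constants are external conditions, not motifs, and
`is_partial_fixed_point()` applies the same convention. Ties in the search
are broken by lexicographic node order, so output order is deterministic.

## Succession diagram and quasi-attractors

`build_succession_diagram()` reduces the network by each stable motif
(merging the motif states into the accumulated assignment and percolating
their downstream consequences), finds the motifs of each reduced network,
and recurses; nodes with identical accumulated assignments are merged and
expanded once, with memoization keyed on the canonical assignment. A
childless node with no free nodes is a steady state; with free nodes left
it is an oscillatory quasi-attractor whose free nodes are marked `OSC`.
Steady states are captured exactly; complex attractors are reported in
compressed form (fixed part plus `OSC` marks).

Two special cases of oscillatory behaviour require care. First, an
oscillatory leaf may actually host several distinct terminal oscillations;
second, an attractor may exist in which *no* motif ever locks (an unstable
oscillation, as in the two-node XNOR pair, which has the fixed point
$\{A{=}1, B{=}1\}$ and a three-state oscillation that never commits to it).
Reduced networks with at most `oscillation_check = 10` free nodes are
therefore screened exhaustively: the full general-asynchronous
state-transition graph is built, its terminal strongly connected sets
extracted, and any terminal oscillation in which no motif holds throughout
becomes an additional oscillatory quasi-attractor. Ten free nodes keeps the
screen exact for every reduced network the bundled models produce while
remaining cheap ($2^{10}$ states); larger reduced networks are not
screened, which matches the observation that intracellular models are not
known to exhibit motif-avoidant oscillations. `count_sequences()` counts
ordered root-to-leaf motif choices (path count over the merged diagram);
the JSON export records both the path count and the merged node count so
either convention can be audited.

Quasi-attractors receive deterministic labels `A1, A2, ...` ordered by
decreasing number of active nodes (ties by state signature), or phenotype
labels when a marker configuration is supplied. Markers are partial states
(e.g. `Apoptosis: Apoptosis=1`); they must be mutually exclusive, and a
quasi-attractor matching two marker sets signals a configuration error.
Several quasi-attractors may legitimately share a label — phenotypes are
specified by a few master regulators, not by every node — and control then
targets the phenotype (reaching *any* attractor with the target label).

## Control and blocking

For a target attractor the control algorithm (i) collects all motif
sequences leading to it, (ii) shortens each sequence to the motifs after
which every remaining choice still reaches the target, (iii) replaces each
motif by its inclusion-minimal driver subsets — subsets of the motif's
states whose clamping forces the whole motif through percolation, found by
subset enumeration in increasing size (with a warning above 12 motif
nodes, since the enumeration is exponential and published motifs are
small) — and (iv) forms unions over one driver choice per motif, pruning
duplicates and supersets. Shortening removes motifs greedily in sequence
order and repeats the pass until a fixed point, validating every candidate
against the diagram, so the result is deterministic and auditable. The
resulting sets are guaranteed interventions: they drive every initial
state to the target, permanently or transiently applied.

Blocking negates every node state of every motif leading to the unwanted
attractor. Each singleton eliminates the target as an attractor of the
clamped network; how much probability mass it diverts is an empirical
question answered by simulation, not asserted — new attractors similar to
the destroyed one can arise, which is why validation classifies by the
phenotype specification (below). Combination blocking interventions are
possible but only singletons are validated by default, matching how such
interventions are reported.

## Stochastic validation

`estimate_attractor_probabilities()` evolves uniformly random initial
conditions (environment inputs at their assigned values) and reports per
label the fraction reaching it, with binomial standard error
$\sqrt{p(1-p)/n}$. Clamping is implemented by overriding the clamped
node's rule with a constant, so the dynamics remain a Boolean network and
percolation-based matching stays valid; the transient protocol runs one
clamped stage and one free stage. Final states are matched against each
quasi-attractor's fixed part (OSC nodes ignored); a state matching no
attractor — typical under attractor-destroying blocking clamps — falls
back to the phenotype markers, mirroring how blocked-attractor validation
is classified in practice; anything else counts as unresolved, and the
unresolved fraction is reported rather than redistributed. Default budgets
are 50,000 steps per stage and 100,000 initial conditions; the desk-scale
preset ($10^4 \times 10^4$), which the tests and the acceptance script
use, already leaves no unresolved trajectories for the bundled models.
The random number generator is a counter-based 64-bit stream with one
deterministic substream per initial condition, so runs are exactly
reproducible from the seed and independent of scheduling.

## Continuous translation

`build_ode_model()` converts the Boolean model into
$\dot{x}_i = (\tilde f_i(x) - x_i)/\tau_i$ where $\tilde f_i$ is the
multilinear interpolation of $f_i$ over the unit cube with each input
passed through a Hill function $h(x) = x^n/(x^n + \theta^n)$, normalized
by $h(1)$ so that the continuous rules agree with the Boolean rules on all
0/1 vertices — hence every Boolean fixed point is an ODE equilibrium
(residual $< 10^{-12}$ in practice) and $[0,1]^N$ is forward-invariant.
Defaults are $n = 3$, $\theta = 0.5$, $\tau = 1$, the conventional choices
for this translation; `ode_parameter_sweep()` varies $n \in \{2,3,5,10\}$
and can randomize $\tau \in [0.5,2]$, $\theta \in [0.3,0.7]$ per node.
Integration uses a stiff-safe adaptive solver (lsoda, relative tolerance
$10^{-6}$) over a horizon of several hundred timescales; endpoints are
classified by the quasi-attractor whose fixed part they match with every
coordinate on the correct side of 0.5, with a slope criterion (max
$|\dot x| > 10^{-3}$ counts as unresolved) guarding against trajectories
stalled near unstable manifolds — a stated decision, since endpoint
protocols for such cases are not standardized. Near-value clamping (e.g.
0.9 for ON) is supported to probe robustness of interventions that cannot
be pinned exactly in a continuous system.

## Fixtures: provenance and validation

The worked example (`toy_fig1`) is reconstructed by constraint
satisfaction against its published analysis and reproduces all of it: the
four stable motifs, the motifs of every once-reduced network, the four
attractors, the four control sets $\{A{=}1,E{=}1\}$, $\{A{=}1,E{=}0\}$,
$\{A{=}0,E{=}1\}$, $\{A{=}0,E{=}0\}$, and the blocking set
$\{\{A{=}1\},\{E{=}0\},\{D{=}0\}\}$. Its succession diagram here has 9
motif sequences.

The T-LGL leukemia fixture is a reconstruction of the 60-node cytotoxic T
cell signalling model (Zhang et al. 2008; Saadatpour et al. 2011) under
sustained Stimuli, IL15 and PDGF. No verbatim rule listing was available,
so the rules were rebuilt from the published model descriptions and
validated against the published stable-motif analysis; the reconstruction
reproduces the 7 stable motifs, the two attractor phenotypes (apoptosis
vs. T-LGL survival), the full published control repertoires for both
phenotypes, the published blocking sets (plus the negations of the two
P2-associated motifs, which published succession diagrams omit), 100%
effectiveness of every control set in both protocols, and a baseline
apoptosis probability within sampling error of the published 62.1%. Known
residuals: the file has 135 regulatory edges against 142 in the original,
the survival phenotype corresponds to two leaf states differing only in
the P2 module, and permanent TBET=OFF blocking yields ~13–15% apoptosis
against a published 10% — right direction and order, but outside sampling
error, so that comparison is reported as a discrepancy rather than hidden.

The helper T cell fixture is likewise a reconstruction of the 55-node
differentiation model (Naldi et al. 2010) under APC, TGFB and IL2. It
reproduces the published single-node control sets exactly
($C_{Th1} = \{TBET{=}ON\}$, $C_{Th2} = \{GATA3{=}ON\}$), the published
Treg and Th17 combinatorial control structure up to a few extra driver
variants, and baselines Th1 $\approx 48.6\%$, Th2 $\approx 47.5\%$ with
small Th17/Treg basins. Residuals: 14 distinct motifs and 80 motif
sequences against 17 and 697 in the original — the reconstruction is
structurally smaller than the booleanized multilevel source model, and
these two counts are reported as genuine mismatches.

Because both case-study files are validated reconstructions rather than
verbatim transcriptions, agreement on the checks above demonstrates the
package's algorithms on realistic published-scale models; it does not
certify node-for-node identity with the original supplementary listings.

## What the random-network generator does and does not emulate

`random_boolean_network()` draws $k$ distinct regulators per node and a
Bernoulli($p$) truth table, reproducibly from a seed. This exercises the
algorithms across arbitrary logic — the test suite checks exact agreement
of quasi-attractors with exhaustive state-transition-graph analysis on 100
such networks ($N \le 10$) — but random networks lack the long signalling
cascades, canalizing rules and modular organisation of curated models, so
those tests validate correctness of the combinatorics, not biological
realism.

## Problem sizes and numerical choices

The test suite runs the full analyses at these scales: exhaustive
state-space oracles up to $2^{10}$–$2^{14}$ states; stochastic validation
at $10^4$ initial conditions $\times$ $10^4$ steps per stage (standard
errors ~0.5% at $p \approx 0.5$); ODE checks at 6–40 initial vectors with
a horizon of 200–300 time units. The succession diagrams of the bundled
models build in under ten seconds each.

## Limitations

Multi-valued logic, update schemes other than general asynchronous, rules
beyond the 20-input truth-table guard, globally minimum-cardinality
control (the returned sets are minimal under inclusion, not guaranteed
smallest possible), exact reconstruction of complex-attractor orbits at
scale, and bifurcation analysis of the continuous model are out of scope.
Motif-avoidant oscillations are detected exactly only in reduced networks
within the screening bound.
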