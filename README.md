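# stablemotifs

Attractor identification and control of logical (Boolean) models of
intracellular networks, for systems biologists who work with published
signalling and regulatory rule sets and want to know **which attractors a
model has** and **which node interventions drive the cell to — or away
from — a chosen fate**.

## The method

A logical model assigns each node `v_i` a binary state and a Boolean update
rule `f_i`; under general asynchronous updating one uniformly chosen node is
updated per time step. Every trajectory ends in an attractor, and attractors
of intracellular models correspond to cell fates.

A **stable motif** is a set of nodes together with states
`M = {σ_m1, …, σ_ml}` such that (i) the nodes form a minimal strongly
connected component of the *expanded network* — an auxiliary graph with one
literal node per node state plus composite nodes for the conjunctive prime
implicants (Blake canonical form) of each rule — and (ii) the states form a
*partial fixed point*: updating any node in `M` returns its state in `M`
regardless of every node outside `M`. Stable motifs are points of no return:
once a motif's states hold they hold forever.

Finding the motifs, fixing one, percolating its consequences
(`substitute-and-simplify`), and repeating on the reduced network yields the
**succession diagram**, whose leaves are the model's (quasi-)attractors —
exact for steady states, with oscillating nodes marked `OSC` for complex
attractors.

From the succession diagram the package computes:

* **Stable motif control sets** `C_A`: for every motif sequence leading to
  attractor `A`, shorten the sequence to the motifs after which all
  remaining choices still reach `A`, replace each motif by its minimal
  *driver subsets* (node states whose clamping forces the whole motif by
  percolation), and take unions over driver choices, pruning duplicates and
  supersets. Fixing any `C ∈ C_A` — even transiently — drives *every*
  initial state to `A`.
* **Stable motif blocking sets** `B_A`: the negations `σ̄_j` of every node
  state of every motif leading to `A`; each eliminates `A` as an attractor,
  and effectiveness is then measured by simulation.

Interventions are validated by seeded general-asynchronous simulation
(permanent and transient clamping protocols, binomial standard errors
`sqrt(p(1-p)/n)`), and in a continuous setting after automatic translation
to a Hill-type ODE model `dx_i/dt = (f̃_i(x) - x_i)/τ_i`, where `f̃_i` is the
multilinear interpolation of `f_i` with inputs passed through normalized
Hill functions — so every Boolean fixed point is preserved as an ODE
equilibrium.

## Worked example

The bundled five-node model (`toy_fig1`) is the framework's standard worked
example:

```r
library(stablemotifs)
toy <- bn_fixture("toy_fig1")$network
sd  <- build_succession_diagram(toy)
summary(sd)
#> Succession diagram of a 5-node network
#>   root stable motifs: 4
#>    { A = 0 }
#>    { A = 1, B = 1 }
#>    { C = 1, D = 1, E = 0 }
#>    { E = 1 }
#>   diagram nodes (merged): 15
#>   motif sequences: 9
#>   quasi-attractors: 4
#>    A1: {A=1, B=1, C=1, D=0, E=1}
#>    A2: {A=1, B=1, C=1, D=1, E=0}
#>    A3: {A=0, B=0, C=0, D=1, E=1}
#>    A4: {A=0, B=0, C=1, D=1, E=0}

stable_motif_control(sd, "A2")
#> Stable motif control sets for A2:
#>   { A = ON, E = OFF }

stable_motif_blocking(sd, "A3")
#> Stable motif blocking interventions for A3:
#>   {A = ON}, {D = OFF}, {E = OFF}
```

Reading: the network has four attractors; clamping just `A=1, E=0`
(transiently!) steers any initial state into attractor A2, and negating any
motif state leading to A3 (`A=1`, `E=0` or `D=0`) removes A3 from the
attractor repertoire. Simulation confirms the guarantee:

```r
qa <- quasi_attractors(sd)
estimate_attractor_probabilities(toy, qa,
  intervention(c(A = 1, E = 0), "transient"),
  sim_config(n_ic = 2000, steps = 1000, seed = 1))
#> Attractor probabilities (n_ic = 2000):
#>   A1               0.00%  (se 0.000%)
#>   A2             100.00%  (se 0.000%)
#>   A3               0.00%  (se 0.000%)
#>   A4               0.00%  (se 0.000%)
```

The two case studies ship as rule files with preset environments and
phenotype markers: `bn_fixture("tlgl")` (T-LGL leukemia survival
signalling, 60 nodes; attractors: Apoptosis vs T-LGL) and
`bn_fixture("thelper")` (helper T cell differentiation, 55 nodes;
attractors: Th1/Th2/Th17/Treg). For example, apoptosis control of the
leukemia model yields `{S1P=OFF}`, `{PDGFR=OFF}`, `{SPHK1=OFF}` and six
combinatorial `TBET/Ceramide` sets, every one 100% effective in simulation.

A command-line interface is installed at `inst/cli/stablemotifs`:

```sh
inst/cli/stablemotifs control --model toy_fig1 --target A2
inst/cli/stablemotifs validate --model tlgl --intervene S1P=0 --transient
```

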