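---
title: "Lifted quantum walks for idea propagation and group decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifted quantum walks for idea propagation and group decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftwalk)
```

## The model

`liftwalk` simulates the spread of a binary idea through a small network
of agents, and the formation of agreement in a group, with a
discrete-time quantum walk.  Each agent $A_k$ is a qubit: $|0\rangle$
means the agent rejects (or has not heard) the idea, $|1\rangle$ means
the agent has adopted it.  The network state is the tensor product of
the agent qubits, with $A_1$ on the least significant slot, so a basis
state reads $|b_n \cdots b_2 b_1\rangle$ and its 1-based index is the
binary value plus one (`basis_state(3, "101")` is basis state 6).

Influence between agents is intrinsically *asymmetric*: a stubborn agent
may sway an open-minded one far more easily than the reverse.  A single
unitary acting on the network state cannot express this asymmetry, so
the walk *lifts* the state: the walk state is
$|\psi\rangle \otimes |\psi'\rangle$, the network (the *controller*)
tensored with a mirrored copy of itself (the *target*).  The walk
operator is block diagonal,
$$U = \mathrm{diag}(U_1, U_2, \ldots, U_{2^n}),$$
so when the controller occupies basis state $i$ — "this is who currently
holds the idea" — block $U_i$ acts on the mirror.  Each block is a short
ordered script of controlled rotations built from two primitives:

* a **lecture**: an infected agent $A_k$ rotates an uninfected
  neighbour by an infection angle $\theta$, conditioned on $A_k$'s
  mirror qubit being $|1\rangle$
  ($M_1 \otimes R(\theta) + M_0 \otimes I$ up to slot placement);
* a **feedback**: the listener, conditioned on still being $|0\rangle$,
  rotates the speaker back by a counteraction angle $\varphi$
  (typically negative, i.e. disinfecting).

$R(\theta)$ is the plane rotation
$\begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta &
\cos\theta\end{pmatrix}$.  Because a quantum control can be in
superposition, a block applies "if infected ... else ..." to *both*
branches at once, which is what lets coherence build up and, later,
produce interference effects.

Each step of the walk is:

1. **lift** the reduced network state $\sigma$ to $\sigma \otimes \sigma$;
2. **evolve** by $U$;
3. **partial-trace** out the controller copy, giving $\rho_T$;
4. **measure** against a stopping projector $M_s$:
   $p_s = \mathrm{Tr}(M_s \rho_T M_s)$, $p_c = 1 - p_s$;
5. **project** onto the continue subspace and renormalise:
   $\sigma' = M_c \rho_T M_c / p_c$.

The unconditional stop/continue probabilities accumulate as
$P_s(t) = P_c(t-1)\,p_s(t)$, $P_c(t) = P_c(t-1)\,p_c(t)$, and the run
ends at the first $t$ with $\sum_{\tau \le t} P_s(\tau) \ge 1-\epsilon$.
The cumulative stop probability telescopes,
$\sum_{\tau\le t} P_s(\tau) = 1 - \prod_{\tau \le t} p_c(\tau)$, which
guarantees termination whenever $p_c$ stays bounded away from 1; the
test suite asserts this identity to $10^{-9}$ on every run it makes.

For **idea propagation** the stopping state is all-infected
($M_s$ picks the last basis index) and the walk starts from
all-uninfected, with the all-zero block seeding the idea into every
agent unconditionally.  For **group decisions** there are two stopping
states, unanimity on either option ($M_s$ picks the first and last
index), members arrive with opinions
$\alpha_k = c_k|0\rangle + d_k|1\rangle$, and the all-zero and all-one
blocks are the identity (nothing needs seeding).  At the stopping step
the decision probabilities are read from the consensus-projected state,
$P_i = \mathrm{Tr}(M_i\, M_s \rho_T M_s\, M_i)/p_s$.

## Numerical design

The lifted operator has dimension $4^n$, but it is never multiplied
densely during a run: with $U$ block diagonal and the lift a tensor
square, the partial trace collapses to
$$\rho_T = \sum_i \sigma_{ii}\, U_i\, \sigma\, U_i^\dagger,$$
a sum of $2^n$ products of $2^n\times 2^n$ matrices.  This identity is
exact, and the suite checks the block contraction against the dense
$4^n$ route to $10^{-12}$.  A five-agent run costs roughly a millisecond
per step, so the multi-thousand-step line-graph runs finish in seconds.

Two guards keep long runs stable: the projected state is re-Hermitised
and renormalised to unit trace after every projection (thousands of
projections would otherwise accumulate drift), and a step whose continue
probability falls below $10^{-14}$ is treated as absorption into the
stopping states.  Validity thresholds are fixed at $10^{-10}$ for
unitarity and $10^{-9}$ for Hermiticity/trace, with a PSD eigenvalue
floor of $-10^{-9}$ — comfortable margins for double precision at
$n \le 8$ qubits.

## Angles and their units

Angle *settings* — the per-block named angles of the 3-agent factories
and the $\theta_{ij}, \varphi_{ij}$ of the ring generator — are
expressed in **units of $\pi$ radians** (half-turns): a setting of 0.05
rotates by $0.05\pi \approx 0.157$ rad.  This is the convention under
which the bundled scenarios reproduce their reference stopping times
(e.g. 1139 steps for the no-disinfection line graph); pass
`angle_scale = 1` to any factory to interpret settings as plain
radians.  The gate primitives (`rotation_gate()`,
`build_controlled_gate()`) always take radians.  Angles are never
wrapped or normalised; negative settings model disinfection.

Defaults that matter:

* `epsilon = 0.01` — the stopping tolerance: the walk stops once less
  than 1% of the probability mass remains unaccounted for;
* `max_steps = 20000` — a cap that flags truncation instead of looping
  forever (an all-zero-angle walk never stops);
* `angle_scale = pi` — the half-turn convention above.

## The 3-agent factories

`build_line3()` and `build_ring3()` transcribe the eight blocks of the
line- and ring-graph walk operators literally from their defining
matrix products, including their quirks: the application order inside
each block follows the printed right-to-left products even where (as in
the ring block for the controller state $|011\rangle$) a feedback
rotation precedes the lecture it answers, and angle names follow the
historical labels even where (as in block $U_6$, whose `theta_x`
rotates $A_2$) the subscript does not name the rotated agent.  The test
suite rebuilds every block from raw Kronecker products as an
independent oracle.  In the ring block $U_2$ the joint lecture places
its two rotations by tensor position; at the homogeneous angles used in
every bundled ring scenario the alternative reading (swapping the two
listeners' angles) gives the identical operator.

## The n-agent ring generator

For $n > 3$ no closed-form block table exists and the generator must
order the pairwise exchanges itself.  `build_ring_n()` uses this
convention, chosen once and frozen:

* interaction exists only between adjacent agents holding different
  ideas, evaluated once against the controller bit string;
* infected agents act in ascending index order; each jointly lectures
  all of its currently-uninfected neighbours (a joint lecture is
  provably identical to lecturing them one after another), then
  receives feedback from each listener in ascending neighbour order;
* the wrap-around pair $(A_1, A_n)$ participates by default
  (`include_wrap = TRUE`): the ring's adjacency is what distinguishes
  it from a line.  The alternative convention, in which the wrap pair
  generates no interaction, is selectable because it makes the
  generator consistent with a worked interaction listing that omits
  the wrap pair; both variants pass all structural invariants.
* the all-one block is the identity; the all-zero block is the
  unconditional seeding rotation when `initializing = TRUE` and the
  identity otherwise.

These ordering choices are genuinely open — different conventions give
different walks, and only structural properties (unitarity, trace
symmetry under bit reversal, invariance of joint versus sequential
lectures) constrain them.  A notable consequence of the frozen
convention: when infection and counteraction have equal magnitude
($\theta = |\varphi|$), every lecture/feedback gate pair maps, under a
global 0↔1 bit flip, onto the feedback/lecture pair of the
complementary block, so the walk treats the two consensus outcomes
almost symmetrically.  The five-member group decision at
$\theta_{ij} = 0.05$, $\varphi_{ij} = -0.05$ accordingly yields
$P_1 \approx 0.50$ (computed by `scripts/acceptance.R`), with the
first-speaker ordering advantage visible only in the third decimal and
in the transient.  Conventions that break this correspondence (for
example lecturing already-infected neighbours as well) push the split
as far as roughly 0.33–0.67 in either direction; none was adopted,
because each contradicts the stated rule that only differing
neighbours interact.

## Group decisions and interference

`run_decision()` runs the consensus walk and reports $P_0, P_1$ and the
stopping step.  Soft opinions are given per agent as a $(c, d)$ pair;
the default reading (`probabilities_sqrt`) treats the pair as
probabilities and takes square roots for amplitudes, so "80% sure of
option 1" is $(0.2, 0.8) \mapsto \sqrt{0.2}|0\rangle +
\sqrt{0.8}|1\rangle$; `amplitudes_normalized` instead treats the pair
as literal amplitudes and renormalises.

`run_with_midway_measurement()` measures one agent pair projectively at
an intermediate step: the pre-projection state is split into the four
collapse branches with probabilities $u_i$, each branch is
renormalised, continue-projected and evolved to the horizon, where the
consensus-conditional all-ones probability $v_i$ — the stopped-state
construction applied at the horizon step — is read off.  Classical
probability would compose these as $u \cdot v$; the unmeasured walk
instead yields its own baseline, and the difference is quantum
interference.  Under the frozen generator the five-member scenario
(measurement at step 25, horizon 50) shows a baseline–composite gap of
about $-0.0075$: real, deterministic, but modest, because the
near-symmetry described above also damps the coherences the effect
feeds on.  With all angles zero the state never moves, the measurement
finds the initial bits with certainty, and a single branch carries all
the weight.

## What the fixtures do and do not show

`generate_fixture()` draws seeded random scenarios — line-3 or
ring-3/4/5 topology, angle settings uniform in $[-0.1, 0.1]$, a random
product initial state — and the property tests run every structural
invariant over them: unitarity of all blocks and the assembled
operator, preservation of density-operator validity at every step,
$p_s + p_c = 1$, the telescoping identity, and the block-versus-dense
evolution contract.  Passing these shows the machinery is exact for
*any* angle configuration; it says nothing about which convention of
the ring generator corresponds to any particular real discussion
protocol, nor about networks beyond lines and rings, which are out of
scope.

## Known limitations

* Only line and ring topologies; no stars, trees or arbitrary graphs.
* Dense (non-sparse) matrices throughout: practical up to roughly 8
  agents.
* One pair measured once per run; no repeated or adaptive mid-walk
  measurements.
* The $n$-agent ring generator's interaction ordering is a frozen
  convention among several defensible ones (see above); results that
  depend on the ordering — most visibly the consensus split of the
  equal-angle group decision — are convention-dependent in the second
  decimal and beyond.
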