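---
title: "Repulsive-bias replica-exchange docking: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repulsive-bias replica-exchange docking: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpremd)
```

## The problem

Molecular dynamics is in principle an ideal tool for finding where a ligand
binds on a receptor surface: it keeps both partners fully flexible and can
include solvent. In practice, biomolecular surfaces are covered with "sticky"
non-specific patches. An unbiased trajectory started away from the native
site binds to the first such patch it meets and stays there for times that
are easily as long as the whole simulation, so most of the compute budget is
spent watching the ligand sit in the wrong place.

`bpremd` implements a Hamiltonian replica-exchange (H-REMD) answer to this
trapping problem. A set of replicas runs at one temperature under potentials
that differ in exactly one term: a repulsive biasing potential acting on a
single collective variable that measures how close the two partners are.
The reference replica permits contact; higher replicas penalise it
progressively, so the ligand detaches and travels quickly along the surface
there. Metropolis exchanges between neighbouring replicas let any promising
contact geometry found aloft descend into the reference replica, whose
sampling remains canonical under the unmodified force field.

## The collective variable

The bias acts on an inverse-power weighted mean of the receptor-ligand
surface-atom distances,

$$
d_{\mathrm{ave}\text{-}p} \;=\;
\left[\frac{1}{N}\sum_{r,l} d_{rl}^{-p}\right]^{-1/p},
\qquad p = 6 \text{ or } 12,
$$

where the sum runs over surface-atom pairs of the two partners currently
closer than a 10 Å cutoff, and the pair list is rebuilt at every step.
Because of the inverse-power weighting the shortest current distance
dominates; $p = 12$ (the default) sharpens that dominance, so the bias
effectively controls the closest contact while remaining smooth as contacts
form and break. The gradient concentrates on the shortest pair in the same
way — the chain-rule weight of pair $k$ is $(d_{\mathrm{ave}}/d_k)^{p+1}/N$.

Two readings of the printed normalisation are possible because the sum is
restricted to pairs inside the cutoff. The package defaults to dividing by
the *restricted* pair count $N$, which keeps $d_{\mathrm{ave}}$ an actual
distance scale (a single contact at distance $d$ gives exactly $d$) and
matches the 2–10 Å magnitude of the ladder bounds; dividing by the full
group-size product $N_r N_l$ is available as
`normalization = "full"`. Evaluation factors out the minimum distance so the
twelfth powers act on ratios bounded by one and cannot overflow for
distances above 0.05 Å.

## Surface groups, bias windows and the guard

The atom groups are fixed once, from the starting conformation: per-partner
solvent accessibility is computed on each *isolated* partner with a
deterministic sphere-point method (Fibonacci lattice, 960 points, probe
1.5 Å), hydrogens are excluded, and heavy atoms with at least 10 Å² of
accessible area enter the groups. Only the contact-pair list is dynamic.

Each replica $i$ carries a window $(d_{\mathrm{low},i},\,d_{\mathrm{up},i})$
and the piecewise-quadratic bias

$$
H_i(d) = \begin{cases}
k_f\,(d-d_{\mathrm{low},i})^2 & d \le d_{\mathrm{low},i}\\
0 & d_{\mathrm{low},i} < d < d_{\mathrm{up},i}\\
k_f\,(d-d_{\mathrm{up},i})^2 & d \ge d_{\mathrm{up},i},
\end{cases}
$$

with $k_f$ = 2.5 kcal mol⁻¹ Å⁻² by default (working range 2.5–5). All
harmonic terms in the package — bias, restraints, guard — use the
Amber-style convention $E = k\,\Delta^2$ without a factor of one half.
Lower bounds increase strictly along the ladder and consecutive windows
overlap, which is what keeps neighbour exchanges frequent. The three
published atomistic ladders (6, 10 and 12 replicas) ship verbatim as
`ladder_preset()`; the 6-replica ladder's non-monotone upper bounds are
preserved as printed and exempted from the advisory monotonicity warning.

When the partners drift so far apart that no surface pair lies within the
cutoff, the bias has nothing to act on. A dissociation guard then applies a
harmonic restraint $k\,(d_{\min}-10)^2$ to the single closest surface pair
(ties broken to the lowest index pair), so the partners can never fully
dissociate. The trigger condition in the source text can be read two ways —
"every pair beyond 10 Å" versus "$d_{\mathrm{ave}}$ beyond 10 Å" — and the
package uses the empty-pair-list reading by default with the other behind
`guard_mode = "dave"`. Exactly one of bias and guard is nonzero at any
configuration, and the guard energy enters the exchange criterion together
with the bias.

## The engine

The bundled engine is a coarse-grained Langevin integrator for bead models:
Lennard-Jones pair terms between partners and between non-bonded ligand
beads, harmonic bonds, positional restraints (receptor anchoring,
0.5 kcal mol⁻¹ Å⁻²) and pair-distance restraints (internal-geometry
preservation, 2.5 kcal mol⁻¹ Å⁻²). Units are Å, kcal/mol, ps, amu, with
$k_B$ = 0.0019872041 kcal mol⁻¹ K⁻¹.

Integration uses the BAOAB splitting of Langevin dynamics, chosen for its
configurational-sampling accuracy at practical step sizes; with zero
friction it reduces to velocity Verlet and conserves energy, which the test
suite checks. The default collision frequency is 0.1 ps⁻¹ (a deliberately
thin solvent so surface diffusion is fast) and the default temperature
300 K. The default time step is 5 fs (0.005 ps): the calibrated toy systems
use wells up to 12 kcal/mol deep whose curvature puts a 10 fs step at the
edge of stability for 12 amu beads, while 5 fs is comfortably stable. Every
simulation state carries a private RNG stream derived from the master seed,
so runs are bit-reproducible and replica trajectories are independent.

## Replica exchange

Since replicas differ only in their bias term, the Metropolis exponent for
a neighbour swap reduces to

$$
\Delta = \beta\,[E_i(x_j) + E_j(x_i) - E_i(x_i) - E_j(x_j)],
$$

with $E_i$ the bias-plus-guard energy of window $i$; acceptance is
$\min(1, e^{-\Delta})$. Attempts alternate between even (1–2, 3–4, …) and
odd (2–3, 4–5, …) neighbour pairs every `exchange_interval` steps (default
20 engine steps for the toy systems; the attempt frequency is not fixed by
the original protocol). On acceptance, coordinates and velocities move
between replica slots while windows stay attached to their slots, so
"replica 1" is always the reference condition. No velocity rescaling is
needed because all replicas share one temperature. Exchange decisions draw
from their own RNG stream, and `demultiplex()` reconstructs continuous
walker trajectories from the exchange log.

The decisive correctness property is detailed balance: for a harmonic pair
with an analytic stationary density, the long-run separation histogram of
each replica must match the quadrature Boltzmann density of its own
(biased or unbiased) Hamiltonian. The acceptance suite verifies both
replicas to a Kolmogorov–Smirnov distance below 0.03 at $10^5$ samples.

## The synthetic systems, and what they do and do not show

`make_harmonic_pair_system()` is the analytic fixture: a frozen bead plus a
mobile bead confined to one axis under
$U(d)=\tfrac12 k_{\mathrm{base}}(d-x_0)^2$, with a closure returning the
exact normalised density under any window (including the guard region), so
sampling can be compared against quadrature rather than against another
simulation.

`make_sticky_receptor()` is the docking benchmark: receptor beads on a
positionally-restrained spherical shell (radius 6 Å, 32 beads, σ = 2 Å),
one native site and four shallower decoy sites spread maximally over the
shell, and the ligand started antipodal to the native site. The native site
is certified by an exhaustive rigid grid scan (1000 placements) to be the
global minimum of the receptor–ligand interaction; systems failing the
certificate refuse to construct. Depths are native 12 / decoy 4.8 kcal/mol
— the 2.5:1 ratio held fixed, the absolute scale calibrated once so that
unbiased Langevin dynamics at 300 K reliably traps at the antipodal decoy
for the full benchmark budget while the replica ladder still lifts the
ligand off. The default benchmark ligand is a single bead: the success
metric (ligand RMSD below one bead diameter after receptor superposition)
should measure binding-*site* search, and a symmetric bead chain would
confound it with internal pose relabelling — a 3-bead ligand bound
correctly but with end beads swapped scores ≈3.3 Å forever. Multi-bead
bonded ligands are fully supported and are exercised by the force-field and
analysis tests.

The toy ladder (`toy_ladder()`: 2.0/4.0, 3.2/5.2, 4.0/6.0, 4.6/6.7 Å,
$k_f$ = 2.5) was calibrated the same way the atomistic ladders were in the
original protocol — by short test simulations adjusting the windows until
every neighbour pair exchanges at a healthy rate (measured 0.25–0.75 across
seeds). The reference window opens at 2 Å, below the bead contact distance
$2^{1/6}\sigma \approx 2.24$ Å, so bound poses score zero bias.

What passing these tests shows: the collective variable, its gradient, the
thermostat, the exchange machinery and the analysis operators are correct,
and the search acceleration mechanism works end to end on a landscape built
to have the failure mode the method targets. What it does not show: anything
about force-field quality, solvation, or atomistic kinetics — the toy
engine deliberately replaces all of that, and conclusions about real
receptor–ligand systems require the original all-atom machinery.

## The benchmark protocol

`run_benchmark()` compares, per seed, the replica-exchange run (4 replicas ×
6000 steps) against a matched-budget conventional arm: a single replica run
for 24 000 steps under the *reference-replica Hamiltonian* (reference window
plus guard). Giving the conventional arm the same Hamiltonian as the
reference replica — rather than no bias at all — makes the comparison
isolate the exchange machinery itself, and the reference window is penalty-
free for every bound or near-bound configuration anyway; the guard merely
prevents the comparison arm from diffusing away and never returning, which
would make the search problem trivially unwinnable rather than sticky.
Success is first passage of the reference-replica ligand RMSD below one
bead diameter (2 Å). At the default seed set (1–10) the replica-exchange
arm succeeds in 10/10 with a median first passage of ≈3 600 steps versus
3/10 for the matched conventional arm; across 40 seeds measured during
calibration the per-seed success rates are ≈0.8 (replica exchange) versus
≈0.35 (conventional). `scripts/acceptance.R` recomputes the benchmark on a
seed-derived set at run time.

## Analysis conventions

Ligand RMSD is computed after superposing the receptor selection onto the
reference (SVD Kabsch, proper rotation enforced) and never re-fits the
ligand. Near-native fractions use strict `<` thresholds (2 and 4 Å) over
stated frame windows, reported for the first and second half of each run.
Clustering uses the leader algorithm in trajectory order with a 4 Å
pairwise ligand-RMSD radius: deterministic, $O(NK)$, and every member is
certified within the radius of its cluster leader — the published analysis
states only the 4 Å criterion, so the leader choice is a documented package
decision, not a reconstruction of the original procedure. Interaction
energies are the receptor–ligand cross Lennard-Jones terms only, evaluated
with no cutoff.

## Numerical choices and degenerate inputs

* Pair distances below 0.05 Å are a hard error (outside the representable
  range of the factored twelfth powers).
* A configuration crossing the 10 Å cutoff changes the pair list and the
  energy jumps by the entering pair's contribution, of order
  $(d_{\min}/10)^{12} \ll 1$; the discontinuity is accepted, matching the
  per-step reselection of the original scheme.
* Coincident atom centres make sphere-point accessibility undefined and
  error out; degenerate (collinear) superposition selections likewise.
* Guard ties resolve to the lowest (receptor, ligand) index pair.
* The problem sizes used by the test suite and acceptance script — $10^6$
  thermostat steps, $10^5$ detailed-balance samples, 10 benchmark seeds at
  24 000 steps per arm — were chosen as the smallest runs at which the
  statistical tolerances stated in the tests are comfortably resolved.

## Known limitations

* The engine is a bead-model Langevin integrator: no all-atom force fields,
  no implicit/explicit solvent, no constraints, no PME.
* Surface groups are fixed at $t = 0$; systems whose surfaces remodel
  during binding would need re-selection, which is out of scope.
* Replicas run sequentially in-process; the contract permits concurrent
  execution only if bitwise identical for a fixed seed.
* Free-energy estimates from replica populations (e.g. WHAM reweighting)
  are deliberately not implemented.
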