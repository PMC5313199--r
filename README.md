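# bpremd — repulsive-bias replica-exchange docking

`bpremd` finds ligand binding sites by Hamiltonian replica-exchange
molecular dynamics with a repulsive biasing potential. It is aimed at
people studying flexible protein–ligand and protein–protein association
with enhanced-sampling MD, and at anyone who wants a small, fully testable
implementation of the method's machinery: the ambiguity-distance collective
variable, per-replica penalty windows, Metropolis exchanges, and the
bundled coarse-grained Langevin engine and synthetic benchmark systems that
exercise all of it at desk scale.

## The method

Unbiased MD started away from a binding site tends to trap at "sticky"
non-specific surface patches for most of the run. The remedy implemented
here biases each replica on a single collective variable, the 1/d¹²-weighted
mean distance between the surface-atom groups of the two partners,

d_ave-12 = [ (1/N) Σ_{r,l} d_rl⁻¹² ]^(−1/12),

summed over receptor×ligand surface-atom pairs currently closer than 10 Å
(the pair list is rebuilt every step; the shortest distance dominates the
weighted mean). Replica *i* adds a piecewise-quadratic penalty outside its
window (d_low,i , d_up,i):

H_i(d) = k_f (d − d_low,i)²  for d ≤ d_low,i;  0 inside;
         k_f (d − d_up,i)²   for d ≥ d_up,i,      k_f = 2.5–5 kcal mol⁻¹ Å⁻².

The reference replica allows contact without penalty; higher replicas push
the ligand off the surface so it translates and rotates freely, and
Metropolis exchanges (Δ = β[E_i(x_j) + E_j(x_i) − E_i(x_i) − E_j(x_j)],
bias terms only) funnel favourable geometries back into the reference
replica, whose sampling stays canonical. A harmonic guard on the closest
surface pair prevents full dissociation when no pair is inside the cutoff.

Surface groups are heavy atoms with ≥ 10 Å² of sphere-point accessible
area (probe 1.5 Å) on the isolated partners. Analysis follows the field's
conventions: ligand RMSD after receptor superposition (no ligand re-fit),
near-native fractions at strict < 2 / < 4 Å thresholds, leader clustering
at 4 Å pairwise ligand RMSD, interaction-energy–vs–RMSD profiles and first
passage times.

## Worked example

A complete docking run on the bundled sticky-receptor benchmark (32-bead
shell receptor, one certified native site, four sticky decoys, ligand
started on the opposite side of the receptor):

```r
library(bpremd)

cfg <- default_run_config()
cfg$remd$n_steps <- 2000          # 4 replicas x 2000 steps, dt = 5 fs
out <- run_docking(cfg, "demo_run")
out$fractions
#> replica first_half_lt2 first_half_lt4 second_half_lt2 second_half_lt4
#>       1              0           0.00            0.13            0.50
#>       2              0           0.00            0.07            0.38
#>       3              0           0.06            0.12            0.12
#>       4              0           0.07            0.00            0.00
```

The table is the standard near-native-fraction report: rows are replicas
(1 = reference), columns the fraction of frames with ligand RMSD below 2 Å
(4 Å) in each half of the run. Here the reference replica went from no
near-native sampling in the first half to 50% of frames within 4 Å of the
certified native pose in the second half, while the most strongly repelled
replica (4) stays off the surface — exactly the funnelling behaviour the
ladder is designed to produce. Occupancy decreases up the ladder at the
native site. `demo_run/` also contains per-replica XYZ trajectories, the
exchange log, per-frame diagnostics (d_ave-12, bias energy, guard flag,
interaction energy), a cluster table and a JSON manifest that reproduces
the run bitwise.

The per-pair exchange acceptance for the same run:

```r
acceptance_statistics(out$store)
#>   i j attempts accepted ratio
#> 1 1 2       50       36  0.72
#> 2 2 3       50        7  0.14
#> 3 3 4       50       29  0.58
```

(Short-run ratios are noisy; over the calibration runs all pairs sit in
0.25–0.75.)

To compare against conventional dynamics at matched cost — the package's
central benchmark — use `run_benchmark(default_run_config(), seeds = 1:10)`;
at the defaults the replica-exchange arm reaches the native site in 10/10
seeds (median first passage ≈ 3 600 steps) versus 3/10 for the matched
single-replica arm; over wider seed sets the per-seed success rates are
roughly 0.8 versus 0.35.

A thin command-line front end with `dock`, `analyze`, `benchmark` and
`make-toy` subcommands is installed under `inst/cli/bpdock`.

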