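---
title: "Gas transport kinetics from grid Markov state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas transport kinetics from grid Markov state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gasport` analyzes how small gas molecules (dioxygen in the motivating
application, a metalloenzyme with a buried catalytic iron) reach and leave a
buried active site. This vignette is the package's own account of the models
it implements, the parameters that matter, and the choices made where the
design was genuinely open. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The event model

The raw observable is a set of trajectories of gas molecules, expressed
relative to the catalytic metal after rigid-body superposition of the
protein frames (Kabsch fit on user-chosen reference atoms, equal weights; we
deliberately do not guess a fit set — it is an input). We store relative
vectors as *gas minus metal*, so exported state clouds overlay the protein
frame directly; distances are unaffected by the sign choice.

An **access event** starts when a molecule's metal distance drops below
`r_inner` (default 6 Å, a literature-typical approach distance for O₂ at
Fe centers; productive binding geometry at 4–5 Å is deliberately not
modeled) and is traced backward to the last frame beyond `r_outer`
(default 20 Å, the protein-plus-shell radius); egress is the mirror image.
Two choices deserve emphasis:

- **Dwell merging.** Consecutive sub-`r_inner` dwells with no intervening
  `r_outer` crossing are one event. Without this, a molecule rattling at the
  inner cutoff would register dozens of spurious entries. The merge radius is
  the *outer* cutoff because the trace is defined shell-to-shell.
- **Censoring.** A dwell already in progress at the first frame (or still in
  progress at the last) has no defined trace time. Such records are counted
  but flagged `censored` and excluded from mean entry/exit times. Silently
  dropping them would bias event tallies; including them would corrupt the
  means.

Rates are reported three ways — events per μs, mean interval between events
anywhere in the system (`1000 × T_μs / n`), and mean interval per molecule
(`n_mol × T_μs / n`) — because all three appear in the field's bookkeeping
and differ by factors that are easy to confuse.

## Contacts and pathways

A residue is *in contact* when any of its atoms is within 3.5 Å of the gas
site (both sites for a diatomic representation; the synthetic generator uses
a single site, to which the rule degrades gracefully). Contact frequency is
contacts per nanosecond of the traced span; aggregated tables list the top
10 residues per pathway × direction and omit entries below 12 contacts/ns
(the raw per-event profile always retains everything — the floor is a
reporting convention, and we interpret it in table units of contacts/ns,
since published tables of this kind bottom out near 12 in those units while
their footnotes say "12 %").

The **trapped filter** (`In**`/`Out**` variants) removes the specific
(residue, event) pair when a single residue is contacted for more than 75 %
of an event — a molecule parked against one residue for most of an event
says more about that cavity's stickiness than about the transport pathway.
Only the offending pair is removed; the event and its other contacts stay.
Two properties follow by construction and are tested: filtered frequencies
never exceed unfiltered ones, and no new residue can appear.

Pathways are assigned by *contact mass*: the signature set (a named list of
residue ids, from configuration or from the synthetic generator's well
linings) with the largest summed contact frequency along the traced span
wins; ties go to the lower priority rank and are flagged; events touching no
signature are `unassigned`. First-contact assignment was rejected because
pathways in this field are described by their most frequently contacted
residues, not their first ones.

Overlap statistics count pairs of events whose traced spans intersect in
time, split intra-/inter-pathway; the overlap window is the full
outer-to-outer span (the source material does not state its window — this
choice is recorded in outputs).

## The grid MSM

Relative positions are rounded to the nearest point of a cubic grid
(spacing 1 Å, half-edge 20 Å). With **periodic** wrapping (the default,
matching a solvated periodic simulation box) the `+20` plane is identified
with `−20`, giving exactly 40³ = 64,000 states; **clamp** mode pins outside
positions to the nearest face and keeps the boundary plane distinct. Clamp
is the right mode for the synthetic generator, whose box is reflecting, not
periodic: wrapping would alias a molecule at `+19.6` Å onto the opposite
face.

Transition counts are sliding-window pairs `(x_t, x_{t+τ})`, skipping pairs
with a null endpoint (nulls arise from event filtering). States never
visited or without outgoing counts are excluded, iterating until stable.
The MLE is row normalization, `T_ij = c_ij / Σ_k c_ik`; no detailed-balance
constraint is imposed (the unconstrained estimator is what the likelihood
`L(T) = Π [T_ij]^{c_ij}` defines, and event-filtered matrices are genuinely
irreversible). The stationary distribution is the leading left eigenvector
on the largest strongly connected component (exact solve below 2000 states,
power iteration above — sparse LU fill-in on grid-shaped chains costs far
more than repeated matvecs), zeros elsewhere, renormalized.

Validation: implied timescales `t_k = −τ/ln|λ_k(τ)|` across a lag scan
(defaults 0.1–5 ns at the 100 ps MSM stride), and Chapman–Kolmogorov tests
comparing `w'T(τ)^k 1_set` against the same quantity under a model estimated
directly at `kτ`, with credible intervals from per-row Dirichlet posterior
sampling (uniform prior pseudo-count `1/N`; the conjugate mean
`(c+1/N)/(Σc+1)` is tested against closed forms). Bayesian sampling and CK
testing are intended for **milestoning-reduced** models — each frame
relabeled by the most recently visited disjoint core set, nulls inheriting
the last core — because dense posterior draws on tens of thousands of grid
states are pointless.

## Kinetics

Source states are those occupied at event boundary frames (the ~22 Å shell
crossing of each traced event); sink states are all visited states within
6.7 Å of the metal — larger than the 6 Å event cutoff because nearest-point
rounding can move a grid state ±0.5·spacing in radius. Committors solve the
standard discrete linear systems (backward committor via the time-reversed
chain `π_j T_ji / π_i`); intermediate states that can reach neither boundary
set make the system singular and are reported and dropped rather than
silently regularized. The headline MFPT is the linear-system definition
`m_i = τ + Σ_j T_ij m_j`, `m ≡ 0` on the sink, averaged over the source
with stationary weights (or explicit weights); the reciprocal TPT rate
`1/k_AB`, `k = F/(τ Σ π_i q⁻_i)`, is reported alongside as a diagnostic —
the two agree only approximately, by construction, and neither is privileged.
Unreachable sinks yield explicit `Inf`, never a dropped row.

Large systems use multi-source backward BFS for reachability and damped
fixed-point iteration for the substochastic solves (both exact in the limit,
with tolerances recorded in the code); small systems use direct sparse
solves.

## The synthetic generator, and what passing tests mean

The generator emulates the statistical structure of flooded-gas MD:
many non-interacting gas molecules (the motivating simulations also assume
gas–gas interactions are negligible) diffusing by overdamped Euler–Maruyama
(`x ← x − D∇U dt + √(2D dt) ξ`) around a fixed center, with smooth C¹
radial wells (`U = −depth·(1 − 3t² + 2t³)`, `t = r/radius`) standing in for
hydrophobic cavities, reflecting walls, and single-atom pseudo-residues on
well surfaces so contact classification has exact ground truth. Defaults:
`kT = 1`, `D = 1 Å²/ps`, `dt = 0.01 ps`. Smooth ramps rather than square
wells keep `∇U` defined everywhere (stability without rejection sampling);
a guard refuses timesteps whose maximum drift per step exceeds half a well
radius.

It does **not** emulate protein flexibility, explicit solvent, anisotropic
tunnels, or force-field realism. Passing tests therefore demonstrate that
the *analysis machinery* is correct on dynamics with known kinetics — not
that any particular protein conclusion is right.

Oracles built into the generator:

- `shell_mfpt_theory`: the closed-form MFPT between concentric absorbing
  and reflecting spheres, `τ = (b³/3D)(1/a − 1/r₀) − (r₀² − a²)/6D`.
- `brute_force_mfpt`: independent first-passage simulations from a uniform
  source shell. A Brownian-bridge crossing test at the absorbing sphere
  (`P = exp(−d₁d₂/(D dt))` for endpoint distances `d₁, d₂`) removes the
  `O(√dt)` overshoot bias of naive endpoint detection, which would otherwise
  be comparable to the statistical error at practical timesteps.
- `boltzmann_reference`: per-grid-point weights `∝ exp(−U/kT)`. Exact
  agreement with long-run occupancy requires the box wall to fall on grid
  cell *boundaries* (`box_half_edge = half_edge + spacing/2`), otherwise
  edge cells are clipped and carry less volume than the point-weight
  reference assumes; the equilibrium fixtures are built that way.

### Choosing the MFPT comparison lag

One numerical effect dominates MSM-vs-simulation MFPT comparisons and is
worth stating plainly: a chain sampled every τ only *sees* an arrival if the
molecule is still inside the sink at a sample time. If the sink region is
purely diffusive, grazing passages shorter than τ are invisible and the MSM
MFPT is biased high, increasingly so at longer lags — easily by integer
factors for a free sink at multi-picosecond lags. Two consequences are
baked into the package's test systems and defaults:

- The synthetic kinetics fixtures give the catalytic zone a *binding basin*
  (an attractive well with meaningful force at the absorbing radius), which
  is also the physically sensible picture — real active sites hold the gas.
  Arrivals are then resolved at any reasonable lag.
- MFPT comparisons use the smallest validated lag (the ITS of a memoryless
  diffusion are lag-stable from the first lag, so "post-plateau" begins at
  the stride); long lags are for Markovianity checks, not first-passage
  resolution.

With both in place the MSM linear-system MFPT tracks the brute-force oracle
to within ~10 % on the two-well fixture; the residual is sampling plus the
jagged Voronoi surface of the discrete sink set, and is covered by the 15 %
test band.

### Problem sizes used by the test suite

The suite favors a few deep fixtures over many shallow ones: the two-well
kinetics fixture (100 molecules × 20 ns at 1 ps saving, ~2×10⁶ frames, ~10⁴
brute-force passages) and the equilibrium fixture (10⁶ saved frames against
the Boltzmann reference, total-variation target < 0.05) are each built once
per session and shared across tests. Unit fixtures are scripted waypoint
trajectories whose event counts, durations, censoring flags, labels and
overlaps are hand-enumerable.

## Known limitations

- Pathway signatures are supplied, not discovered; there is no geometric
  tunnel detection.
- The Bayesian MSM does not enforce reversibility (deliberately, see above),
  so its credible intervals describe the unconstrained posterior.
- Committors and fluxes on event-filtered matrices describe the filtered
  process; disconnection is surfaced, not repaired.
- The MSD exponent α is a single power-law fit over a configurable window;
  no anomalous-diffusion model beyond that is fitted, and subdiffusive α is
  a caveat on MSM timescales, not a corrected quantity.
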