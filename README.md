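# gasport

Gas molecules reach buried enzyme active sites through transient tunnels and
internal hydrophobic cavities. In flooded-gas molecular dynamics simulations —
many dioxygen molecules diffusing around a protein with a catalytic metal
center — the interesting observable is not any single trajectory but the
statistics of *access and egress events*: excursions of a gas molecule from
the outer solvent shell (≥ 20 Å from the metal) down to the catalytic zone
(< 6 Å), and back. `gasport` turns such trajectories into quantitative
transport kinetics:

- **Event tracing.** Every approach of a gas molecule below the inner cutoff
  `r_inner` is traced backward and forward to the outer shell `r_outer`,
  producing entry/exit records with trace times, minimum approach distances,
  and censoring flags. Sub-`r_outer` excursions never split an event, so
  rattling at the cutoff is not double-counted.
- **Pathway classification.** Residue contacts (any residue atom within
  3.5 Å of the gas) are profiled along each traced segment; events are
  assigned to named pathways by the contact mass on user-defined signature
  residue sets, with a trapped-molecule filter (`In**`/`Out**`) that removes
  residue–event pairs in contact for > 75 % of an event.
- **Grid Markov state models.** Metal-relative gas positions are binned onto
  a 1 Å grid in a 40 Å cube (64,000 states), transition matrices are
  estimated by maximum likelihood from sliding-window counts at a lag τ,

      T_ij(τ) = c_ij / Σ_k c_ik,    L(T) = Π_ij [T_ij(τ)]^c_ij,

  and validated by implied timescales t_k = −τ/ln|λ_k(τ)| and
  Chapman–Kolmogorov tests (with Bayesian posterior sampling of T for
  credible intervals, and a milestoning core-set reduction to make that
  affordable).
- **Transition path theory.** Committors q⁺, q⁻ from the discrete committor
  linear systems, reactive flux f_ij = π_i q⁻_i T_ij q⁺_j, rates, and mean
  first-passage times m_i = τ + Σ_j T_ij m_j (m ≡ 0 on the sink) between
  source states at the ~22 Å shell and sink states within 6.7 Å of the metal.
- **A synthetic gas simulator as ground truth.** An overdamped Brownian
  dynamics engine (Rcpp) with smooth cavity wells, reflecting walls,
  closed-form spherical-shell MFPTs and a brute-force first-passage sampler
  lets every stage of the analysis be checked against known kinetics,
  including subdiffusive MSD exponents (α < 1) induced by trapping.

## Worked example

A two-cavity synthetic system, end to end:

```r
library(gasport)

sys <- synthetic_system(
  box_half_edge = 12, sink_radius = 4,
  wells = list(well_spec(c(6, 0, 0), 2.5, 3, "wA"),
               well_spec(c(0, 0, 0), 3, 3, "site")))
tr  <- simulate_brownian(sys, brownian_params(
  D = 1, n_molecules = 15, n_steps = 3e5, save_stride = 1, seed = 7))

ev <- detect_events(tr, event_thresholds(r_inner = 4, r_outer = 10))
summarize_events(ev, total_time_us = 3e-6, n_molecules = 15)
#> 172 events in 3e-06 us (15 molecules): 5.73e+07 events/us, one every
#> 1.74e-05 ns (2.62e-07 us per molecule)
#>     pathway n_entry n_exit mean_entry_ns mean_exit_ns n_censored
#>  unassigned     172    172   0.009994186   0.01097647          2

g  <- grid_spec(spacing = 1, half_edge = 12, wrap = "clamp")
m  <- estimate_msm(assign_states(tr, g, stride = 2), lag = 2)
m
#> gas_msm (MLE): 11429 active states (11426 in the connected set), lag 2 ps,
#> 22496 counted pairs

ss  <- select_source_sink(assign_states(tr, g, stride = 2), ev,
                          r_sink = 4.5, r_source = 10)
tpt <- compute_tpt_rate(m, ss$source, ss$sink)
tpt
#> gas_tpt: |A|=333, |B|=331, lag 2 ps
#>   MFPT (linear system) = 0.2059 ns
#>   1/k (reactive flux)  = 0.2072 ns
```

Reading the output: the toy run lasts only 3 ns (3 × 10⁻⁶ μs), so the
event *rate* is astronomically large and every event is `unassigned`
(no pathway definitions were supplied); entry traces average ~10 ps from
the 10 Å shell to the 4 Å catalytic zone, and the source-to-sink mean
first-passage time from the model is ~0.21 ns by both estimators — with the
binding basin at the origin, most of that time is spent finding the funnel.

The same chain runs from a single YAML config:

```sh
Rscript inst/scripts/gasport.R all --config run.yaml --out results/
```

which writes the event table, contact tables (raw and `**`-filtered),
overlap/same-path statistics, MSM matrices and state table, implied-timescale
report, kinetics report, MSD table, a state-cloud PDB (stationary
probabilities × 100 in the B-factor column; π > 0.01 orange, > 0.10 blue,
> 0.40 red), and the resolved configuration beside its md5 hash.

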