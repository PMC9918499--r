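# nucdyn

Analysis of nucleosome dynamics from molecular dynamics trajectories, for
structural biologists and simulators studying how histone composition
(e.g. the variant H2A.Z versus canonical H2A) changes DNA accessibility.

The nucleosome wraps ~147 bp of DNA in ~1.65 superhelical turns around a
histone octamer. `nucdyn` quantifies the slow motions that control DNA
accessibility:

* **DNA end unwrapping** — per-frame counts of contiguously displaced
  base pairs from each DNA end (bp center deviating > 7 Å from the
  superposed reference);
* **free-energy profiles** by Boltzmann inversion of the occupancy
  histogram, ΔG⁰ᵢ = −RT ln(fᵢ/f_max), in kcal/mol at 310 K, with
  cross-run standard errors (n = runs × DNA sides), plus 2D free-energy
  surfaces over (DNA radius of gyration, DNA–histone contact count);
* **nucleosome gaping** — separation of the two DNA gyres along the
  superhelix axis, measured between bp windows at SHL −4 and +4;
* **histone core flexibility** — per-atom RMSF about the ensemble mean
  after core Cα superposition, aggregated across copies and runs;
* **tail–DNA interactions** — strict heavy-atom contact counts (< 4.5 Å),
  minimum distances, Savitzky–Golay smoothing, and correlation of raw
  series (e.g. tail contacts versus unwrapping);
* **histone variant sequence analytics** — percent identity, formal tail
  charges, and C-terminal tail-swap bookkeeping for H2A/H2A.Z, with
  canonical human sequences packaged.

Everything is verifiable at desk scale through a built-in synthetic
generator: pseudo-atom nucleosomes whose unwrapping follows a zipper model
with per-bp detachment energy ε (stationary law P(i) ∝ e^(−iε/RT), so the
free-energy module must recover ε as the profile slope), a mean-reverting
gaping mode, per-element core jitter and two-state tail binding
anti-correlated with unwrapping — all with exact, recorded ground truth.

Trajectory I/O: PDB/GRO structures, DCD and multi-model PDB trajectories
(bio3d backend; a DCD writer is included).

## Worked example

Simulate a 5 000-frame zipper trajectory (ε = 0.5 kcal/mol), superpose it
on the histone core, and recover the unwrapping energetics and gaping
mode:

```r
library(nucdyn)

params <- synthetic_params(epsilon = 0.5, n_frames = 5000, seed = 1)
sim <- simulate_trajectory(params)

ens  <- superpose(sim$ensemble, sim$system)
uw   <- unwrap_series(ens, sim$system, threshold = 7)
prof <- free_energy_1d(c(uw$entry, uw$exit), temperature = 310)
prof
#> free-energy profile over 12 unwrapped-bp states at 310 K
#>    i   delta_g    n
#> 1  0 0.0000000 5462
#> 2  1 0.4974208 2436
#> 3  2 0.9996418 1078
#> 4  3 1.4766195  497
#> 5  4 1.8925655  253
#> 6  5 2.3269156  125
#> ...

profile_slope(prof)
#> [1] 0.4654549

gp <- gaping_series(ens, sim$system)
hist_mode(gp$distance)
#> [1] 27

cs <- tail_dna_contact_series(ens, sim$system, "A", "C", "outer")
series_correlation(uw$total, cs$contacts)
#> [1] -0.3220952
```

The profile is linear in the unwrapped count with slope ≈ ε (0.47 from
5 000 frames; ±10% at 50 000), ΔG = 0 at the modal state, the gaping
distance distribution peaks at the programmed 27 Å, and tail–DNA contacts
anti-correlate with unwrapping as programmed. `run_report()` runs the
whole pipeline over multiple trajectories and writes per-run TSV tables,
pooled profiles with n = run×side standard errors, and a JSON summary.

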