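---
title: "Quantifying nucleosome dynamics: unwrapping, gaping, flexibility and tail contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdyn)
```

## Scope and model

The nucleosome wraps about 147 bp of DNA in roughly 1.65 left-handed
superhelical turns around a histone octamer (two copies each of H2A, H2B,
H3, H4). Several slow motions dominate its conformational dynamics and are
the observables this package quantifies from molecular dynamics (MD)
trajectories:

* **DNA end unwrapping** — terminal stretches of nucleosomal DNA detach
  from the octamer surface ("breathing" for ~5–10 bp, larger unwrapping
  beyond). We count, per frame and per DNA end, the contiguous run of core
  base pairs whose centers have moved more than a threshold (default 7 Å)
  from their position in the superposed reference structure.
* **Gaping** — the two DNA gyres separate along the superhelix axis,
  perpendicular to the nucleosome plane. We measure the distance between
  the centroids of two bp windows at superhelical locations (SHL) −4 and
  +4.
* **Histone plasticity** — per-atom RMSF of core Cα atoms about the
  ensemble mean after superposition.
* **Tail–DNA interactions** — heavy-atom contact counts (< 4.5 Å,
  strictly) and minimum distances between histone tails and DNA regions.

Free energies are obtained by Boltzmann inversion of occupancy
histograms,

$$\Delta G_i^0 = -RT \ln\left(\frac{f_i}{f_{\max}}\right),$$

with $f_i$ the frequency of frames showing $i$ unwrapped base pairs,
$f_{\max}$ the modal frequency, $R = 1.987204\times10^{-3}$
kcal mol$^{-1}$ K$^{-1}$ and $T = 310$ K by default. The same inversion
applied to a 2D histogram of (DNA radius of gyration, total DNA–histone
contact count) yields a free-energy surface. Empty states are undefined
(NA), never $+\infty$: the inversion has no information there.

## Coordinate conventions

Base pairs are indexed from the dyad: 0 at the dyad, −73…+73 for the 147
bp core, ±74…±93 for two 20 bp linkers (a 1-based sequential mapping is
provided for file I/O). The continuous SHL coordinate is `bp / 10.3`,
using the canonical ~10.3 bp/turn nucleosomal twist; integer SHL $n$
corresponds to the bp window $\mathrm{round}(10.3\,n) \pm 2$. DNA regions
partition the duplex into *inner* ($|i| < 37$), *outer*
($37 \le |i| \le 73$) and *linker* ($|i| \ge 74$); the inner/outer
boundary sits near SHL ±3.5 and is configurable, since different studies
draw it differently. Region labels and ad-hoc bp windows are independent
mechanisms: analyses that need a window (e.g. the ±41…±75 end segment for
tail–DNA distances) take it as an explicit argument.

Frames are superposed on histone-core Cα atoms against the reference
structure before any displacement-based analysis; the default fit
selection excludes the L1/L2 loops (configurable), and the fit minimizes
the selection RMSD by a least-squares rigid-body transform. Superposition
is idempotent and commutes with equilibration trimming; both properties
are tested. The first 200 ns of each trajectory are discarded by default
(`trim_equilibration`); the input object is left untouched so
time-evolution plots can still use the full run.

## The synthetic trajectory generator

Every analysis stage is validated against pseudo-atom nucleosome
trajectories with known ground truth (`synthetic_params`,
`generate_reference`, `simulate_trajectory`). One bead represents each bp
(the bp "center" is then the bead itself; on all-atom systems it is the
C1′–C1′ midpoint), Cα-like beads represent annotated core helix/loop
elements, and bead strings represent the H2A-family tails. Geometry
defaults (superhelix radius 41.9 Å, pitch 25.9 Å/turn, 1.65 turns) are
generator choices giving a realistic overall shape; analyses never assume
them.

The stochastic processes are chosen so their stationary behavior is known
in closed form:

* **Zipper unwrapping.** Each DNA end performs single-bp Metropolis moves
  on the lattice energy $E(i) = i\,\varepsilon$, so the stationary law is
  the truncated geometric $P(i) \propto e^{-i\varepsilon/RT}$. Boltzmann
  inversion of simulated occupancies must therefore return a linear
  profile of slope $\varepsilon$ — the recovery test for the free-energy
  module (0.5 kcal/mol recovered within ±10% at 50 000 frames). Released
  bp leave the superhelix radially by 12 Å, comfortably beyond the 7 Å
  detection threshold.
* **Gaping.** A mean-reverting AR(1) process (default mean 27 Å,
  stationary sd 1.5 Å, relaxation 50 frames) drives a rigid axial
  displacement of the two half-turn regions $|i| \ge 31$, leaving the
  dyad fixed. The per-bp axial shift is bounded (default 5 Å) so gaping
  can never masquerade as unwrapping; rare truncated excursions are
  recorded at their realized distance, keeping ground truth exact.
* **Core plasticity.** Per-element Gaussian jitter, loops (L1/L2) twice
  as mobile as helices by default — RMSF analyses must recover
  $\sigma\sqrt{3}$ for isotropic jitter and the loop/helix ordering.
* **Tail binding.** Tails toggle between a bound conformation (each bead
  within 3.5 Å of its anchor DNA bead, guaranteeing a contact floor) and
  an unbound one 25 Å out into solvent, with bound probability
  $\max(0.05,\, 0.9 - 0.08\,i)$ decreasing in the total unwrapped count
  $i$. Measured contact series are therefore anti-correlated with
  unwrapping, and the strength of the anti-correlation grows with the
  coupling parameter.

Isotropic Gaussian noise (default 0.5 Å) is added only after ground truth
is recorded, and an arbitrary rigid transform per frame (optional,
default on) exercises the superposition machinery. A fixed seed fixes the
entire stream, making every ensemble and ground-truth table bit
reproducible.

What the generator does *not* emulate: force-field physics, solvent and
ions, sequence-dependent DNA elasticity, realistic kinetics (frames are
abstract time), or correlated multi-mode couplings beyond those
programmed. Passing the recovery tests demonstrates that the analysis
operators measure what they claim on data where truth is known — not
that any particular biological system behaves this way.

## Numerical choices

* Contacts use a strict `<` at the cutoff (many tools use ≤; the strict
  convention is asserted at 4.49 vs 4.50 Å). The cell-list kernel is
  exactly equivalent to the all-pairs definition and is tested against a
  brute-force oracle on 1 000 random instances.
* Savitzky–Golay smoothing (default 10 ns window, order 1 — 101 points at
  100 ps sampling) handles edges by shrinking the window symmetrically,
  so output length equals input length and polynomials up to the filter
  order are reproduced exactly. Correlations are always computed on raw
  series; smoothing is presentation-only.
* Unwrap counting is end-anchored: counting stops at the first
  non-displaced bp, so isolated interior displacements (e.g. a perturbed
  dyad) contribute nothing. Each side is capped at 73 bp (end to dyad).
  Linker bp are ignored.
* The 2D projection plane is fixed from the reference structure. Because
  a 1.65-turn helix has no exact reflection symmetry, the smallest
  principal axis of the bp-center cloud is a biased estimate of the
  superhelix axis; the axis is therefore refined by a cylinder fit
  (minimal spread of radial distances about a least-squares circle), and
  the in-plane origin is the fitted circle center, so radial excursions
  read directly as unwrapping.
* RMSF uses the population mean-square deviation (divide by $n$) about
  the time-averaged structure; some tools divide by $n-1$, a ~0.5%
  difference at 100 frames that the cross-checks account for.
* Free-energy profiles are pooled following the per-run-and-side
  convention: one profile per run and DNA end, then per-state means and
  standard errors $s/\sqrt{n}$ across the profiles (n = 6 for three runs
  × two sides). No histogram smoothing or reweighting is applied.
* Histogram modes of distance distributions use 0.5 Å bins with centers
  aligned on multiples of the bin width.
* Sequence identity defaults to a Needleman–Wunsch global alignment with
  BLOSUM62 and affine gaps (open 10, extend 0.5 — the standard needle
  defaults), identity = identical columns / alignment length. A plain
  match/mismatch matrix is available but scatters gaps on diverged pairs
  and underestimates identity relative to common practice; on the
  packaged human H2A vs H2A.Z.1 sequences the BLOSUM62 alignment
  reproduces the published gap structure and ≈60% identity (58.6 by
  columns, 60.9 by shorter-sequence length). Formal tail charges count
  K/R as +1, D/E as −1 and His as neutral at pH 7 (protonated His would
  shift tail charges by integer amounts; the neutral convention is the
  usual one for coarse tail comparisons).
* Two conventions for the H2A/H2A.Z C-tail boundaries circulate
  (120–130/122–128 and 121–130/123–128); both are shipped as named
  presets and neither is silently preferred.

## File formats and sizes

Structures: PDB (via bio3d) and GRO (fixed-column, nm → Å). Trajectories:
DCD (read via bio3d; written by the package's own CHARMM-format writer,
round-trip validated against bio3d's reader) and multi-model PDB. There
is currently no R reader for XTC/TRR, so those formats are out of scope;
convert with standard tools first. Fixtures for tests are generated
programmatically at run time; the only shipped data file is the two-entry
FASTA of canonical human H2A/H2A.Z.1 sequences.

Validation problem sizes were chosen to keep the full suite fast on a
single CPU while leaving comfortable statistical margins: 10 000-frame
fixtures for label recovery, 50 000 observable-only frames for the
zipper-energy recovery, 10 000 frames for the gaping mode, and a
2.4-million-frame observable-only run for the rare-event barrier
comparison.

## A worked example

```{r example, eval = FALSE}
library(nucdyn)

params <- synthetic_params(epsilon = 0.5, n_frames = 5000, seed = 1)
sim <- simulate_trajectory(params)

ens <- superpose(sim$ensemble, sim$system)
uw  <- unwrap_series(ens, sim$system, threshold = 7)
gp  <- gaping_series(ens, sim$system)

prof <- free_energy_1d(c(uw$entry, uw$exit), temperature = 310)
profile_slope(prof)        # ~ 0.5 kcal/mol per bp
hist_mode(gp$distance)     # ~ 27 Angstrom

cs <- tail_dna_contact_series(ens, sim$system, "A", "C", "outer")
series_correlation(uw$total, cs$contacts)   # negative: anti-correlated

run_report(sim$system, list(ens), analysis_config(trim_ns = 0),
           out_dir = "report")
```

## Known limitations

* No periodic-boundary re-imaging: frames are assumed whole; minimum-image
  conventions are not applied in distance computations.
* No solvent/ion handling, no trajectory concatenation beyond ordered
  multi-file input, and no binding-energy estimates.
* The unwrapped-bp definition compares each bp against its own reference
  position (the literal displacement definition); an alternative
  histone-surface-distance definition is not implemented.
* RMSF superposes on the whole octamer core by default; per-chain
  superposition is available through the `selection` argument of
  `superpose`.
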