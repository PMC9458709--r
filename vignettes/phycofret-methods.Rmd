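---
title: "Models and methods behind phycofret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phycofret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycofret)
```

# Scope and model

`phycofret` connects the geometry of an allophycocyanin-type (αβ)₃ trimer to
its photophysics in three linked layers:

1. **Geometry.** Six bilin chromophores sit in three *monomeric* and three
   *interface* binding pockets. The observables that matter are the
   per-frame distances between the three designated monomer–interface
   chromophore pairs, the K6–D100 salt bridge on the α-subunit, K6 rotamer
   occupancies, and chromophore–pocket contact frequencies.
2. **Förster EET.** In the weak-coupling regime the pairwise transfer rate
   is $k_{DA} = (\kappa^2/\tau_D)\,(R_0/R_{DA})^6$. The package treats
   $R_0$, $\tau_D$ and $\kappa^2$ as inputs and converts distances (or
   distance series) into rates and times. Exciton (strong-coupling) physics
   is out of scope: no Hamiltonian diagonalisation, no computation of $R_0$
   from spectral overlap.
3. **Time-resolved emission.** TCSPC decays are modelled as
   $F(t) = \sum_i A_i e^{-t/\tau_i}$ convolved with a Gaussian instrument
   response function (IRF) plus a constant background, and fitted by
   iterative reconvolution; transient-absorption (TA) traces use the same
   machinery on real-valued ΔT with stimulated emission taken positive.

The assumptions are the standard ones for this system: transfer is
incoherent and pairwise (Förster), the IRF is adequately described by a
Gaussian of known FWHM, and decays are sums of a few discrete exponentials
rather than lifetime distributions.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Pocket-contact cutoff (`classify_pockets`) | 4.5 | Å | common heavy-atom contact convention for residue–ligand enclosure |
| Contact-frequency cutoff (`contact_frequency`) | 4.0 | Å | common heavy-atom contact criterion for per-residue frequencies |
| Salt-bridge criterion (`salt_bridge_series`) | 4.0 | Å N–O | standard lysine–carboxylate bound criterion |
| Equilibration window | final 30% of frames | — | mirrors analysing the last equilibrated stretch of a production run; overridable as an explicit frame range |
| Histogram bin width (`distance_histogram`) | 0.25 | Å | resolves a ~0.5 Å-wide distance distribution without starving bins |
| Förster radius `R0` | 68.0 | Å | literature value for the allophycocyanin pair |
| Donor lifetime `tauD_ns` | 1.5 | ns | literature donor lifetime |
| `kappa2` | 1.0 | — | "sandwich" mutual dipole configuration; the trimer geometry gives no evidence of a change toward "in line", so a static κ² is the default and per-frame κ² from trajectory dipoles is available but off |
| Transition dipole | NA→ND atom pair | — | axis between the terminal pyrrole nitrogens of the conjugated system; configurable because deposited bilins differ in atom naming |
| Rotamer bins | g+ (0°,120°], t (120°,180°]∪(−180°,−120°], g− (−120°,0°] | deg | standard terciles; a χ₁ ≈ 75° rotamer is then unambiguously g+ |

Angles are reported in degrees in (−180°, 180°]; coordinates in Å; times in
ps internally, with donor lifetimes accepted in ns at the interface.

Open points the source data leaves unspecified are exposed rather than
guessed: which atoms define a "chromophore" for contact analysis (the
conjugated-atom set is configurable), whether distance distributions are
raw counts or normalised (both supported), which distance statistic enters
the Förster equation (`median`, `mean`, or per-frame — exposed explicitly),
and which mean-lifetime convention is meant by a published ⟨τ⟩ (both
amplitude- and intensity-weighted means are always reported; published
values reconcile with the intensity-weighted form).

# The synthetic generators

`build_toy_trimer` constructs a C3-symmetric pseudo-trimer: six minimal
protein chains (A+B, C+D, E+F forming three αβ monomers), six pseudo-bilins
of four collinear heavy atoms 1.4 Å apart (giving every downstream
operation a defined conjugated-atom set, centre and dipole axis), and a
planar all-*anti* lysine–aspartate pair per α chain at the formed
salt-bridge distance (2.8 Å N–O). Monomer-pocket bilins touch only their
own monomer's residues; interface bilins touch residues of two adjacent
monomers; the ring radius is chosen so each designated pair sits at 24.5 Å.

`simulate_trajectory` emulates the two study conditions. *apo*: all three
pair distances at 24.5 Å, salt bridge intact. *co2*: one designated pair
contracted to 22.0 Å (both members moved half the shift, keeping the ring
centre fixed) and that monomer's K6 NZ displaced to 8 Å from the D100
carboxylate. Chromophores fluctuate as independent isotropic Gaussians per
frame (default σ = 0.4 Å per coordinate, matching a ~0.5 Å-wide distance
distribution); an optional AR(1) parameter adds temporal correlation but is
off by default, because the distance-distribution statistics consumed
downstream do not depend on it. Protein atoms are held fixed.

What the generator deliberately does **not** emulate: force-field dynamics,
solvent, correlated protein motions, anharmonicity, or rotamer kinetics.
Passing tests therefore demonstrate that the *analysis chain* is correct
and unbiased on data with the assumed statistical structure — not that real
MD trajectories have that structure.

`simulate_decay` scales the IRF-convolved model so the channel sum equals
the requested total counts and draws Poisson counts per channel;
`simulate_transient` adds Gaussian noise scaled to the peak. All generators
are pure functions of their spec, seed included; sub-seeds for pipeline
stages are derived deterministically from one master seed.

# Numerical choices

**Closed-form convolution.** The exponential ⊗ Gaussian convolution is
evaluated analytically (exponentially-modified Gaussian) in log space,
using `pnorm(..., log.p = TRUE)` for the erfc factor, so the model is
stable from the rising edge to channels 10⁵-fold below the peak. With
FWHM = 0 it reduces exactly to the switched-on multi-exponential.

**Fitting.** Lifetimes are fitted as log(τ) and amplitudes as log(A)
(positivity by construction); the background is free. Levenberg–Marquardt
(minpack.lm) runs from five deterministic starts — a geometric lifetime
ladder spanning the window, scaled by ×0.1…×10 — and the best converged
start by deviance wins (ties resolve to the first, i.e. the least extreme
grid). A fit in which the integrated component signal is under 2% of the
data is flagged `degenerate` rather than reported as a lifetime.

**Weighting.** Poisson fits begin with per-channel variance max(count, 1)
and then make two reweighting passes with variance max(fitted, 1).
Weighting by observed counts alone over-weights channels that fluctuate low
and shortens recovered lifetimes by several percent once a sizeable
fraction of channels is sparsely populated; model-based reweighting removes
that bias (recovery errors drop below ~1.5% on 10⁶-count bi-exponential
decays) while keeping zero-count channels in the fit.

**Unresolved components.** A fitted lifetime longer than **twice the
acquisition window** is reported as an unresolved lower bound. The
threshold must sit above 1: a 2.9 ps stimulated-emission component is
legitimately fittable on a 2.5 ps pump–probe window (the curvature within
the window determines it), whereas a 50 ps component on the same window
only admits a lower bound.

**Superposition.** Kabsch (SVD) with the proper-rotation correction; for
ring assemblies whose chain count is divisible by 3, the three cyclic
monomer mappings are searched and the lowest-RMSD mapping returned, with
per-chain author-numbering offsets estimated from the modal Cα residue
difference. Fewer than three paired atoms is an error, and reflections are
never applied.

**Degenerate inputs.** Single-frame trajectories run end to end but skip
histograms and emit a warning into the run manifest; empty selections,
empty windows, non-positive distances, zero separation vectors, non-unit
dipoles and all-zero amplitudes raise immediate errors naming the offending
quantity.

# Study problem sizes

The packaged analyses and tests use: 2 000-frame trajectories (σ = 0.4 Å)
for distance/salt-bridge statistics, where the standard error of a pair
median is ≈ 0.016 Å; TCSPC recovery on 4 096 channels × 1 ps (≈10 slow
lifetimes of window) at 10⁶ counts for the sub-ns bi-exponential
conditions, and 4 096 × 5 ps for the nanosecond predominant-lifetime
condition; TA recovery on 500 points × 5 fs (2.5 ps window) with a 200 fs
IRF and 1% noise. The nanosecond decay's minor component is fixed at
500 ps / 3.2% amplitude — a plausible minor component for a recombinant
trimer — since only the predominant component is specified by the published
fit.

# Known limitations

- Pocket classification assumes monomers are pairs of chains; the default
  pairing (consecutive chains in sorted order) matches typical trimer
  depositions but heterogeneous assemblies need an explicit `monomers`
  argument.
- The chain-mapping search covers cyclic ring rotations only, not
  reflections or arbitrary permutations.
- κ² from trajectory dipoles treats the transition dipole as a fixed atom
  pair within the conjugated system; vibronic reorientation within a frame
  is invisible.
- The reconvolution fitter assumes a Gaussian IRF when given a FWHM;
  measured-IRF histograms are accepted but interpolated linearly.
- No global/target analysis across wavelengths, no maximum-entropy lifetime
  distributions, and no absolute quantum yields (only ratios of supplied
  QYs with quadrature error propagation).
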