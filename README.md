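# phycofret

Structure-to-photophysics analysis for phycobiliprotein trimers.

Cyanobacteria harvest light with the phycobilisome, whose core is built from
allophycocyanin (αβ)₃ trimers carrying six bilin chromophores — three in
*monomeric* binding pockets (enclosed by one αβ monomer) and three in
*interface* pockets (enclosed by residues of adjacent monomers). Electronic
energy transfer (EET) between a monomer-pocket chromophore and the interface
chromophore of the adjacent monomer is fast (ps) and exquisitely sensitive
to their separation: in the weak-coupling Förster regime the transfer rate
is

    k_DA = (κ² / τ_D) · (R₀ / R_DA)⁶

with Förster radius R₀, donor lifetime τ_D, donor–acceptor distance R_DA and
orientation factor κ² = (d̂_D·d̂_A − 3(d̂_D·R̂)(d̂_A·R̂))² ∈ [0, 4]. A CO₂ adduct
(carbamate) on the allophycocyanin α-subunit lysine K6 breaks a K6–D100 salt
bridge and pulls one chromophore pair from ~24.5 Å to ~22 Å, roughly
doubling the EET rate. `phycofret` implements the full inference chain that
connects trimer geometry to that photophysical readout, for people who
analyse phycobiliprotein MD trajectories and time-resolved spectroscopy:

- **Structures and trajectories** (`read_structure`, `read_trajectory`,
  `write_structure`, `write_trajectory`): PDB I/O (via bio3d) with author
  residue numbering preserved, plus a plain-text XYZ-per-frame trajectory
  dialect; chromophore identification and monomer/interface pocket
  classification (`chromophore_sites`, `classify_pockets`); Kabsch
  superposition with a cyclic chain-mapping search for ring assemblies
  (`superpose`).
- **Trajectory observables** (`rmsd_series`, `chi_dihedrals`,
  `contact_frequency`, `salt_bridge_series`, `pair_distances`,
  `distance_histogram`): RMSD series, lysine χ₁–χ₄ rotamer occupancies,
  heavy-atom contact frequencies, K6–D100 salt-bridge tracking, and
  inter-chromophore distance distributions for the three designated
  monomer–interface pairs.
- **Förster photophysics** (`forster_params`, `forster_rate`,
  `kappa_squared`, `eet_from_trajectory`): EET rates/times from distances or
  distance series.
- **Time-resolved emission fitting** (`fit_decay`, `fit_transient`,
  `model_decay`, `mean_lifetimes`, `qy_ratio`): iterative-reconvolution
  fitting of TCSPC decays (multi-exponential ⊗ Gaussian IRF, Poisson
  weighting with model-based reweighting, deterministic multistart) and of
  fs–ps transient-absorption traces, returning a classed model object with
  `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate` methods;
  amplitude- and intensity-weighted mean lifetimes.
- **Synthetic generators** (`build_toy_trimer`, `simulate_trajectory`,
  `simulate_decay`, `simulate_transient`): seeded, fully reproducible
  stand-ins for MD trajectories and spectroscopy data — a C3-symmetric
  pseudo-trimer with apo/CO₂-bound two-state geometry, TCSPC histograms
  with Poisson counting noise, and IRF-convolved transients.
- **Pipeline** (`pipeline_config`, `run_pipeline`, `read_pipeline_config`):
  one call from trajectories to a JSON/CSV report comparing apo vs
  CO₂-bound EET times, with a run manifest that makes every stochastic
  output reproducible. A command-line wrapper lives in `inst/cli/phycofret.R`.

## Worked example

```r
library(phycofret)

# Förster EET times at the allophycocyanin parameters
p <- forster_params(R0 = 68.0, tauD_ns = 1.5, kappa2 = 1.0)
forster_rate(p, 24.5)
#> EET: R_DA = 24.5 A -> rate 0.305 /ps, time 3.3 ps
forster_rate(p, 22.0)
#> EET: R_DA = 22.0 A -> rate 0.581 /ps, time 1.7 ps

# Apo vs CO2-bound synthetic trajectories, end to end
cfg <- pipeline_config(states = list(
  apo = trajectory_spec("apo", n_frames = 2000, seed = 101),
  co2 = trajectory_spec("co2", n_frames = 2000, seed = 202)), seed = 1)
run_pipeline(cfg)
#> phycofret run manifest (package 0.1.0 , seed 1 )
#>   apo: 2000 frames; pair EET times 3.3/3.3/3.3 ps; salt bridge bound 1.00
#>   co2: 2000 frames; pair EET times 1.7/3.3/3.3 ps; salt bridge bound 0.00

# TCSPC reconvolution: refit a simulated bi-exponential decay
spec <- decay_spec(components = list(c(0.82, 164), c(0.18, 410)),
                   irf_fwhm = 200, n_channels = 4096, channel_width = 1,
                   total_counts = 1e6, seed = 7)
d <- simulate_decay(spec)
fit_decay(d$time_ps, d$counts, n_components = 2, irf_fwhm = 200,
          irf_center = attr(d, "irf_center"))
#> TCSPC reconvolution fit: 2 components, reduced chi^2 = 0.847
#>   tau1 = 165 ps (82.7%)
#>   tau2 = 414 ps (17.3%)
#>   <tau> amplitude-weighted 208.3 ps, intensity-weighted 250.8 ps
```

The first block is the core physics: with κ² = 1 and τ_D = 1.5 ns, moving a
chromophore pair from 24.5 Å to 22.0 Å roughly halves the EET time
(3.3 ps → 1.7 ps). The pipeline shows the same contrast emerging from
simulated two-state trajectories — only the designated pair speeds up, and
the K6–D100 salt bridge goes from fully bound to fully broken. The TCSPC fit
recovers the generating lifetimes (164/410 ps at 82/18% amplitude) and its
intensity-weighted mean (≈251 ps) matches the convention used for published
⟨τ⟩ values.

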