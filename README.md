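# smforce

Single-molecule FRET force-sensor analysis for quantifying the piconewton
forces that T-cell receptors (TCRs) exert on their pMHC ligands within the
immunological synapse.

Peptide-based molecular force sensors (MFS) anchored in a supported lipid
bilayer carry a FRET dye pair across an entropic-spring element: collapsed
sensors show high FRET efficiency, and mechanical load stretches the spring,
separates the dyes and lowers the efficiency. `smforce` turns tables of
single-molecule FRET trajectories into force statistics:

- **Calibration.** The spring obeys a linear force–extension law
  *F(r) = (r − b·n − c)/(a·n)* and the dyes the Förster relation
  *E(r) = (1 + (r/R₀)⁶)⁻¹*; composing the closed-form inverses gives the
  readout map *F(E)*. Defaults: a = 0.0122 nm/pN, b = 0.044 nm, c = 2.4 nm,
  n = 29 residues, R₀ = 5.1 nm. Efficiency uncertainty is propagated to
  force by shifting each grid efficiency down by ΔE and re-inverting.
- **High-force fraction.** A threshold q_f is the f = 0.05 empirical
  quantile of cell-free efficiencies; the corrected fraction of
  force-bearing sensors is n_low/n_total − f, with a bootstrap that
  resamples whole tracks (observations within a track are correlated).
- **Force PDF.** Average shifted histograms (range −0.5..1.5, 40 shifts,
  Sturges bins) of cell and cell-free efficiencies; the cell-free PDF is
  width/height-scaled about E = 0.87 by least squares on the low-force
  window (E > 0.75), subtracted, clipped at zero, and mapped to a force
  density through the calibration Jacobian; quartiles summarize it.
- **Mobility.** Tracks are immobilized (TCR-bound proxy on fluid bilayers)
  when the smallest-enclosing-circle radius divided by √duration falls
  below 0.35 μm·s⁻⁰·⁵ (tracks with < 5 observations are discarded).
- **Hypothesis tests.** One-sided KS-type permutation tests (statistic
  D⁺ = max CDF difference, 9999 resamples, exact enumeration when
  feasible) that permute intact tracks.
- **Bond lifetime.** Apparent lifetimes fitted per recording interval Δt
  are combined via τ_app(Δt) = 1/(k_off + k_b/Δt) to separate unbinding
  (k_off = 1/τ_bond) from per-frame photobleaching (k_b).

A synthetic trajectory generator reproduces the statistical structure of
the experiment (zero-force efficiency noise N(0.865, 0.164), Brownian
D = 0.7 μm²/s vs. immobilized motion, geometric track lengths, competing
unbinding/bleaching), so the full pipeline is testable without microscope
data.

## Worked example

```r
library(smforce)

calib <- sensor_calibration()
force_from_efficiency(0.5, calib)        # 4.025 pN
propagate_uncertainty(calib, delta_E = 0.005, F_max = 9)  # 0.1331 pN

cfg <- default_config(seed = 42L)
cfg$scenario$phi_force    <- 0.2   # 20% of tracks under load
cfg$scenario$force_pN     <- 5
cfg$scenario$phi_immobile <- 0.4
cfg$scenario$n_tracks     <- 600
cfg$no_cell_scenario$n_tracks <- 600
cfg$filters$neighbor_radius <- 0   # synthetic fields are sparse
res <- run_pipeline(cfg, "smforce_out")
```

prints nothing but returns (and writes to `smforce_out/results.json`):

```
q_f = 0.5965
high-force fraction = 0.1846  (bootstrap median 0.1837, IQR 0.1692–0.1992)
force quartiles: Q1 3.73, median 4.92, Q3 6.29 pN  (s_width 0.979, s_height 0.784)
bound fraction = 0.430; KS D+ = 0.198, p = 1e-04 (***)
tau_bond = 9.84 s (se 0.34), k_bleach = 0.209 per frame
```

Reading: of 4161 filtered observations, 18.5% lie below the cell-free
threshold beyond the 5% false-positive allowance — close to the simulated
20% of force-bearing tracks. The reconstructed force density peaks at the
injected 5 pN (median 4.92 pN), and the fitted height scale 0.78 is the
force-free share of the cell sample. 43% of classifiable tracks are
immobilized (truth: 40%). The efficiency distribution of synaptic sensors
is significantly shifted below the cell-free one, and the lifetime fit
recovers the simulated 10 s bond lifetime and 0.2/frame bleaching hazard
(−ln 0.8 ≈ 0.223) from apparent lifetimes of 1.5–8 s.

A thin CLI over the same functions lives in
`inst/scripts/smforce-pipeline.R` (subcommands `init-config`, `simulate`,
`run-all`, `qc`).

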