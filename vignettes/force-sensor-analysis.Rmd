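---
title: "Quantifying TCR-imposed forces from single-molecule FRET sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TCR-imposed forces from single-molecule FRET sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smforce)
```

# The measurement

A molecular force sensor (MFS) is a short spider-silk-derived peptide that
behaves as an entropic spring, flanked by a FRET donor/acceptor pair and
mounted between a supported lipid bilayer (SLB) anchor and a TCR ligand
(pMHC or an antibody fragment). Without load the spring is collapsed and
FRET efficiency is high; a pulling T-cell receptor extends the spring,
separates the dyes and lowers the efficiency. Single-molecule TIRF
microscopy yields trajectories of localized sensors with per-observation
donor/acceptor intensities. `smforce` implements the downstream analysis:
from trajectory tables to calibrated force statistics, per-condition
comparisons and bond lifetimes.

# Sensor calibration

Two relations connect the observables:

* the linear entropic-spring law \(F(r) = (r - b\,n - c) / (a\,n)\) with
  compliance slope \(a = 0.0122\) nm/pN, per-residue offset
  \(b = 0.044\) nm, spring constant \(c = 2.4\) nm and \(n = 29\)
  residues — giving a zero-force dye separation \(r_0 = b\,n + c =
  3.676\) nm;
* the Förster relation \(E(r) = (1 + (r/R_0)^6)^{-1}\) with
  \(R_0 = 5.1\) nm.

Both are strictly monotone, so the readout map \(F(E)\) is obtained in
closed form, \(r(E) = R_0 (1/E - 1)^{1/6}\), rather than numerically (an
independent numeric root-finder serves as test oracle). Efficiencies above
the zero-force efficiency \(E_0 = E(r_0) \approx 0.877\) yield negative
forces; these are returned unclamped — the clipping happens once, in the
density-subtraction stage, where negative *densities* (not values) are set
to zero.

```{r calibration}
calib <- sensor_calibration()
calib
force_from_efficiency(0.5, calib)
```

Measurement uncertainty propagates through the same map: each of 100
forces on [0, 9] pN is mapped to its efficiency, shifted down by
\(\Delta E\), and re-inverted. The error grows with force (the Förster
curve flattens), so the maximum sits at the top of the grid:

```{r uncertainty}
propagate_uncertainty(calib, delta_E = 0.005, F_max = 9, n_grid = 100)
```

With \(\Delta E = 0.005\) — the standard error of the zero-force mean
efficiency — the force uncertainty stays below 0.15 pN up to 9 pN.

The width-scaling anchor used later (0.87) is deliberately kept as a
separate configuration constant from \(E_0 = 0.877\): the subtraction
procedure defines its own zero-force reference, and conflating the two
would silently couple the calibration to the density fit.

# What the synthetic generator emulates — and what it does not

Every stage is exercised on synthetic data with the experiment's
statistical structure:

* zero-force efficiencies are drawn from \(N(\mu_0 = 0.865,
  \sigma_0 = 0.164)\), the no-cell distribution of the real measurement;
  force-bearing sensors draw from \(N(E(F), \sigma_0)\) — the noise is
  Gaussian and force-independent because the analysis only rescales the
  width of the no-force peak;
* mobile sensors diffuse freely with \(D = 0.7\ \mu m^2/s\); immobilized
  sensors sit still up to 0.02 µm localization jitter (a typical
  single-molecule localization precision); force-bearing sensors are
  always immobilized, since force requires anchoring;
* track lengths are geometric (mean 8 observations, minimum 1) — a
  stand-in for the unpublished photobleaching-limited length law, flagged
  as such;
* intensities are a binomial donor/acceptor split of a log-normal total
  (2000 counts, 20% relative noise) consistent with the drawn efficiency —
  realistic shot-noise-like structure without claiming a camera model;
* binding events end at the earlier of exponential unbinding
  (\(\tau_{bond}\)) and geometric per-frame photobleaching, recorded at
  several frame intervals;
* frame interval 0.1 s; a 20 × 20 µm field of view.

A single scenario seed deterministically derives all stream seeds, and
generation leaves the caller's RNG untouched.

Not emulated: raw images and localization error structure beyond isotropic
jitter, camera noise, spectral cross-talk beyond the correction factors,
anomalous or confined diffusion, track linking errors, and temporal drift.
Passing tests therefore demonstrate the *statistical estimators* are
correct under the model the analysis assumes — not that the upstream image
processing of a real experiment is.

# High-force fraction

From cell-free data recorded under identical SLB conditions, the threshold
\(q_f\) is the empirical \(f = 0.05\) quantile (linear interpolation
between order statistics — the common default; exposed in the
configuration). In cell data, the corrected high-force fraction is
\(n_{low}/n_{total} - f\). It is left unclamped when negative: the
correction formula is unbiased and clamping would bias averages of
replicate estimates. Uncertainty comes from a bootstrap that resamples
whole tracks with replacement (1000 resamples), because observations
within a track are correlated; summaries follow the box-and-whiskers
convention (quartiles, whiskers at the most extreme points within
1.5 IQR).

On mixtures where a fraction \(\varphi\) of observations sits fully below
the threshold, the expectation is \(0.95\,\varphi\) (the force-free
remainder contributes its false positives, which the \(-f\) correction
removes) — verified at \(\varphi \in \{0.05, 0.1, 0.2\}\).

# Force-PDF reconstruction

Average shifted histograms (ASH) estimate both efficiency PDFs on the
range −0.5..1.5 with 40 shifts; the bin count follows Sturges's rule,
\(1 + \lceil \log_2 n \rceil\), computed from the *cell* sample size and
applied to both histograms so the two PDFs share one grid (the procedure
subtracts them pointwise; independent grids would require an extra
interpolation for no benefit). The cell-free PDF is then scaled — x about
the anchor 0.87 by \(s_{width}\), y by \(s_{height}\) — and fitted to the
cell PDF by unweighted least squares restricted to the low-force window
\(E > 0.75\) (start (1, 1), bounds (0, 5]; L-BFGS-B). Subtracting,
clipping negative densities to zero and applying the change of variables
\(p_F(F) = p_E(E(F))\,|dE/dF|\) with the analytic Jacobian yields the
force PDF; grid points mapping to negative force are dropped before
trapezoidal renormalization, and quartiles are read off the inverse CDF by
linear interpolation.

If the clipped residual carries less than `mass_floor` (default 0.001) of
probability mass, the result is an explicit "no detectable force" rather
than meaningless quartiles — the self-subtraction case.

Two regimes bound the method's accuracy. At moderate forces (the 5 pN
validation case) the residual efficiency distribution lies comfortably
inside (0, 1) and the recovered median is within a few hundredths of a
piconewton. At high forces (9 pN, \(E(F) \approx 0.144\)) an appreciable
tail of the noisy efficiencies falls below 0 where no force is defined;
that mass is necessarily discarded, which skews the reconstructed median
downward. This is a property of the efficiency-space subtraction approach
itself, not of the implementation.

# Mobility classification

The smallest enclosing circle of each track is computed with a
deterministic incremental Welzl-style construction (no random shuffling,
so results are reproducible; a brute-force oracle over all 2- and 3-point
support circles verifies it to 1e-9 in the tests). Under free diffusion
the squared radius grows linearly with time, so the *reduced radius*
\(r_{circle}/\sqrt{T}\) is diffusion-scale-free; tracks below
0.35 µm·s⁻⁰·⁵ are immobilized. Duration \(T\) is taken from timestamps
(last minus first), not frame counts — the threshold's unit is per
\(\sqrt{s}\), and timestamps remain correct when frames are missing.
Tracks with fewer than 5 observations are labeled `too_short` and excluded
from fraction denominators; a zero-duration track with enough observations
is immobilized by convention (it cannot have moved) and logged.

# Track-preserving permutation tests

Because within-track observations are correlated, classical two-sample
tests are invalid on pooled observations. The test statistic is
\(D^+ = \max_x (\hat F_A(x) - \hat F_B(x))\) — a one-sided KS statistic,
with "A stochastically smaller" (engaged sensors have reduced efficiency)
as the default alternative — and the null distribution is built by
reassigning whole tracks between groups, preserving group track counts
(9999 resamples by default). Ties are handled by evaluating the CDF
difference at the last position of each tie group of the pooled sorted
values. When \(\binom{n_A+n_B}{n_A} \le 20000\) the permutation
distribution is enumerated exactly; otherwise the add-one estimator
\(p = (1 + \#\{D^+_{perm} \ge D^+_{obs}\}) / (1 + n_{perm})\) is used, so
Monte-Carlo p-values are never zero. With all tracks of length 1 the test
reduces to a plain permutation KS test, which the suite checks against a
direct enumeration oracle.

# Bond lifetime with photobleaching correction

At a single recording interval the observed event durations confound
unbinding with photobleaching. Unbinding accrues with elapsed time,
bleaching with the number of exposures, so recording at several intervals
\(\Delta t\) separates them through

\[\tau_{app}(\Delta t) = \frac{1}{k_{off} + k_b/\Delta t},\]

fitted by weighted least squares (weights \(1/SE^2\)) with
\(k_{off} = 1/\tau_{bond}\) and \(k_b\) the per-frame bleaching hazard.
This competing-exponential-rates form is the package's declared model: a
constant per-frame bleaching probability \(p\) corresponds to the hazard
\(k_b = -\ln(1-p)\), which the fit recovers.

Per-interval apparent lifetimes are maximum-likelihood fits of durations
left-truncated at one frame. Two likelihoods are provided: the geometric
likelihood on frame counts and the left-truncated exponential (MLE: sample
mean minus the truncation point). The default `auto` rule uses the
geometric form when events span fewer than 10 frames *on average*.
Durations are intrinsically frame-discrete, and the two estimators differ
by \(\Delta t\,q/(1-q)\) versus \(\Delta t / (-\ln q)\) in the per-frame
survival \(q\); when typical spans are short that discrepancy biases the
global fit noticeably, while for long spans the forms coincide — hence a
criterion based on the typical, not the maximal, span. If all events last
exactly one frame the lifetime is not identifiable and the fit aborts with
advice to record faster. A flat \(\tau_{app}(\Delta t)\) curve (fitted
\(k_b\) within 2 SE of 0) is flagged non-identifiable and falls back to
the pooled apparent lifetime instead of failing.

Recovery on the synthetic grid \(\tau_{bond} \in \{5, 10, 20\}\) s ×
\(p_{bleach} \in \{0.1, 0.2, 0.3\}\) at 1000 events per interval
(intervals 0.5–8 s) is within 10% per cell.

# Preprocessing contracts

`compute_fret()` implements the community-standard ALEX-style corrections
(donor bleed-through, direct acceptor excitation, detection factor γ,
excitation factor β), defaulting to identity/zero so the efficiency
reduces to the proximity ratio; the factors are configuration-settable
because their values are instrument-specific. `filter_tracks()` removes
same-frame neighbors closer than a configurable radius (default 0.8 µm,
about twice a typical PSF sigma at 160 nm pixels — unstated upstream,
hence exposed), applies efficiency/stoichiometry windows (defaults
[−0.5, 1.5] and [0.3, 0.7], configuration stand-ins), and drops tracks
below the minimum length; every rule logs its removal count.
`single_emitter_filter()` counts downward mean-shift changepoints on the
summed intensity by binary segmentation with a robust noise estimate
(MAD of first differences / √2) and penalty \(6\hat\sigma^2\log n\):
single-step bleaching is kept, two or more downward steps (multiple
emitters) are removed, and tracks too short to segment pass with a log
entry. Binary segmentation was chosen because the goal — counting clear
bleach steps — does not need an exact changepoint solver, only a
deterministic, conservative counter.

# Pipeline, configuration and QC gates

`run_pipeline()` chains simulate → preprocess → force → mobility → test →
lifetime, writing each stage's output (TSV tables, JSON results) so any
stage can be resumed from intermediates; identical configuration and seed
give byte-identical results. All tunables live in one YAML-serializable
configuration (`default_config()`), pre-filled with the standard values
(f = 0.05, ASH −0.5..1.5 / 40 shifts, fit window 0.75, anchor 0.87,
0.35 µm·s⁻⁰·⁵, minimum length 5, 1000 bootstrap / 9999 permutation
resamples), and the configuration is embedded verbatim in the result
bundle. `qc_evaluate()` applies the evaluation-criteria discipline of a
pooled force database as numeric gates — no high-force excess in no-cell
data, a responding positive control, expected mobility on fluid bilayers —
each with an explicit verdict, and `not_evaluable` (flagging the run) when
a metric is missing.

# Problem sizes used in the test suite

The suite validates statistical properties at sizes chosen to make the
Monte-Carlo error a small fraction of the tested effect: 40,000–50,000
observations for threshold/fraction recovery, 20,000 per sample for the
force-PDF median, 500 simulations for null calibrations, 1000 random point
sets for the enclosing-circle oracle, 400 simulations × 199 resamples for
the permutation-test type-I error, and 1000 events per interval for
lifetime recovery. These are desk-scale stand-ins: the corresponding
experimental datasets are larger, and the acceptance checks quantify
estimator correctness, not biological effect sizes.

# Known limitations

* The force PDF inherits the high-force truncation bias described above
  and cannot resolve multiple discrete force levels (no deconvolution).
* The mobility classifier is binary; confined or transiently binding
  tracks are forced into one class (no HMM segmentation, no MSD fitting).
* FRET correction factors default to identity; quantitative use on real
  data requires instrument-calibrated factors.
* The geometric track-length law and log-normal intensity model are
  plausible stand-ins, not fitted to published data.
* The lifetime model assumes memoryless unbinding (single exponential);
  catch/slip-bond load dependence and temperature effects are out of
  scope.
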