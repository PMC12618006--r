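---
title: "Methods: models, estimators, and the synthetic-data generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and the synthetic-data generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltfret)
```

## Scope

voltfret quantifies how plasma-membrane potential modulates ERK kinase
activity in single cells. Its inputs are two-channel (CFP/YFP) FRET
biosensor time-lapse recordings acquired under high-K⁺ perfusion or
voltage-clamp protocols, donor photon-decay histograms from FLIM-FRET
recordings of lipid-probe clustering, and cytokinesis event tables from
bright-field time-lapse movies. Because such recordings are rarely shared
raw, the package ships a first-class synthetic-data generator that emulates
the variability structure of these experiments; every analysis stage is
validated against it by parameter recovery.

## Membrane-potential model

Perfusion experiments manipulate the membrane potential through the
extracellular K⁺ concentration. `nernst_potential()` maps a concentration to
the K⁺ equilibrium potential,

$$E_K = \frac{RT}{F}\,\ln\frac{[\mathrm{K}^+]_o}{[\mathrm{K}^+]_i},$$

about 59.16 mV per tenfold concentration change at 298.15 K. Defaults are
deliberate simplifications, each configurable:

* **Temperature 298.15 K.** Imaging-stage temperatures are rarely reported;
  the slope changes by ~4% between room and body temperature, which is
  irrelevant for rank and correlation statements.
* **Intracellular K⁺ 145 mM**, matching a standard KCl pipette solution.
* **No GHK correction.** A Goldman–Hodgkin–Katz treatment would need
  conductance ratios that are not measured in this workflow. The Nernst
  value is therefore always labelled *predicted*; clamp phases bypass it and
  report the commanded voltage verbatim.

Protocols (`perfusion_protocol()`) are ordered, contiguous phases with roles
`baseline`, `stimulus`, `repolarized`, `egf`. All windows in the package are
half-open `[start, end)`: a frame acquired exactly at a solution switch
belongs to the incoming phase. This single convention governs phase lookup,
reference windows, histogram bins, and mitosis bins, so boundary frames are
never double-counted.

## Ratio quantification and the % ERK statistic

Per frame, the pooled mean over all background ROIs is subtracted from every
pixel; per cell, corrected pixel intensities are averaged per channel. A
cell whose corrected CFP is non-positive anywhere is dropped with a recorded
reason rather than producing an undefined ratio.

Two normalizations make single cells comparable:

1. **Dish reference.** The raw YFP/CFP ratio varies between dishes with
   probe expression and optical gain. Each cell's ratio is divided by its
   own mean ratio over a reference window, by default the final 2 minutes of
   the baseline phase (the 8–10 min convention for a 10-min baseline). The
   normalized ratio then has mean 1 over that window by construction.
2. **EGF ceiling.** Saturating EGF at the end of each recording provides a
   per-cell estimate of maximal reporter response. The per-cell statistic is

   $$\%\,\mathrm{ERK} = 100 \cdot
     \frac{\max_{\text{stimulus}} R - \bar R_{\text{baseline}}}
          {\max_{\text{EGF}} R - \bar R_{\text{baseline}}},$$

   with $R$ the normalized ratio. The baseline-subtracted form is the
   default because it is the only form under which "no response" reads as
   0%; the plain ratio of maxima (`subtract_baseline = FALSE`) is provided
   because both conventions circulate, and since the normalized baseline is
   ≈ 1 the two differ only by that subtraction. The stimulus search window
   is the stimulus phase itself, optionally extended by `stim_lag_min` for
   perfusion rigs with slow solution exchange (default 0).

EGF content is stored verbatim as value + unit, never converted between
molar and mass units: published protocols state it both ways and a silent
conversion would presume the intended one.

**Exclusion rule.** Dead and unhealthy cells are identified by their failure
to respond to EGF. The package makes the rule explicit: a cell is excluded
when its EGF response (`egf_max − baseline`) is below `k_sigma` (default 3)
times the SD of its normalized baseline ratio. Because the response is a
*maximum* over EGF-phase frames, a 3σ threshold admits a minority of true
non-responders (multiple-comparison leakage of order
`n_frames · P(Z > 3)`); the tests quantify this. An empty included set is
reported prominently, not silently.

**Exact invariances.** Per-channel gain rescaling and global additive
offsets (applied to cells and background ROIs alike) cancel algebraically,
and the pipeline preserves them to floating-point exactness; both are
enforced by tests, bitwise for power-of-two gains and integer offsets.

## Clamp recordings and phase extrema

For voltage-clamp protocols the same machinery applies with the depolarized
phase as the stimulus. `phase_extrema()` reports the four per-cell
summaries used for step protocols: baseline mean, depolarized-phase
maximum, repolarized-phase minimum, EGF-phase maximum. Summary panels for
perfusion-style figures use mean ± SEM and clamp-style trace panels mean ±
SD; each report CSV carries its `error_type` explicitly.

## FLIM lifetime estimation

Donor lifetimes are estimated from binned arrival-time histograms by
maximum likelihood under a mono-exponential decay truncated to the fit
window $[A, B)$: bin probabilities
$p_j \propto e^{-a_j/\tau} - e^{-b_j/\tau}$, multinomial log-likelihood
maximised by `stats::optimize()` with tolerance $10^{-10}$, guarded against
boundary convergence. In the fine-bin limit this is equivalent to solving
the truncated-mean equation $\bar t = \tau - T/(e^{T/\tau}-1)$. Choices:

* **Mono-exponential, not multi-exponential or phasor.** The workflow
  reports one mean lifetime per cell per timepoint; a mixture fit would be
  under-determined at those photon counts. When the true decay is a
  mixture, the apparent τ lies strictly between the component lifetimes and
  any added short-lifetime component can only lower it — which is exactly
  the FRET readout direction.
* **Tail fit, no IRF.** The default window starts 0.5 ns after time zero,
  past typical instrument-response peaks; with no IRF data shipped,
  deconvolution would be guesswork. Bin width 0.05 ns, window 25 ns by
  default.
* **Guards.** Fewer than 1000 photons in the window (configurable) is an
  error, as is a boundary solution.

On exact expected counts the estimator returns τ to better than $10^{-6}$
relative error; at $10^6$ photons its bias is below 0.5% across 1–4 ns.

`normalize_lifetime()` divides by the mean lifetime over the first 10
minutes, mirroring the ratio normalization. `detect_fret_shift()` compares
donor-only and donor-plus-acceptor populations with a Welch test and flags
groups too small for a dispersion estimate. In the packaged two-group
simulation the printed per-group `±0.014`/`±0.013` ns figures are treated
as per-cell dispersions: at group sizes 25 and 16 only that reading is
compatible with a clearly significant Welch comparison of a 0.030 ns shift,
so it is the regime the simulation reproduces.

## Mitosis analysis

Cytokinesis events are instantaneous times (10-min frame resolution); no
tracking or lineage. Counts are binned at 1.5 h (half-open bins, totals
conserved for every bin width), time courses are normalized by the matched
control's first-bin count, and condition effects are summarised by
accumulating counts over the first 6 h and dividing by the same
experiment's control accumulation. Ratios are tested against 1 with a
one-sample t-test; pairs of treated arms within the same experiments (e.g.
a depolarizing condition with and without MEK inhibition) use a paired
t-test. A zero first-bin control is an explicit error instructing pooling
or exclusion, not a silent `Inf`. The control is keyed by `experiment_id`;
whether a control is a paired dish or a phase of the same dish is the
caller's bookkeeping.

## Statistical summaries

`correlate_erk()` computes the Pearson correlation of *single-cell* %ERK
values against log₁₀[K⁺] or clamped voltage — pooled cells, not condition
means, matching how per-cell n are reported in this kind of experiment.
Log base is presentation only (R is invariant to affine predictor maps).
The 95% band is the standard linear-regression confidence band. Degenerate
inputs (under 3 points, zero variance on either axis) are flagged, not
errors. `group_compare()` wraps the test family the workflows need;
rank-sum p-values use exact enumeration (via `wilcox.test`'s exact path)
up to 50 observations per group without ties, and the
continuity-corrected normal approximation above — the two agree within
0.01 at the boundary. No multiple-testing correction is applied, matching
the pairwise reporting style of the workflows; reports state this.

## The synthetic-data generator

`simulate_population()` emulates, per recording:

* **Kinetics.** Activity $a(t) \in [0,1]$ relaxes first-order toward a
  target with τ_on = 5 min rising and τ_off = 1 min falling — slow ERK
  activation (10–20 min to plateau), fast shut-off on repolarization
  (~1 min). The voltage transfer is logistic,
  $a_{ss}(V) = 1/(1+e^{-(V-v_{1/2})/k})$ with defaults $v_{1/2} = -25$ mV,
  $k = 8$ mV, chosen so that −40 mV is sub-threshold and 0 mV
  near-saturating. After EGF onset the target is `egf_saturation` (0.95)
  regardless of voltage. The fast upstream channel (Ras /
  phosphatidylserine, `fast_tau_min` = 1 min) drives the simulated
  lifetime time course, which completes most of its drop within 2 min.
* **Channels.** CFP ∝ $1 - \delta a$, YFP ∝ $1 + \delta a$ with contrast
  δ = 0.4 (~2× ratio dynamic range at full activation, a typical
  intramolecular-sensor figure), times per-dish lognormal channel gains
  (SD 0.2), a per-cell lognormal expression level, a *shared* exponential
  photobleaching decay — shared so the ratio is bleach-invariant by
  construction, which is the ratiometric rationale — and multiplicative
  lognormal per-frame noise (CV 1% by default): simple, positive-valued,
  and sufficient for recovery testing.
* **Population structure.** Resting potentials uniform on [−36, −15] mV;
  a non-responder fraction (default 0.1) of cells that ignore stimulus and
  EGF alike, exercising the exclusion rule; per-cell response dispersion.
* **Design-targeted mode.** For recovery studies the generator accepts a
  designed mean %ERK per condition. Per-cell true values are drawn from a
  Beta law on [0, attainable maximum] with mean exactly the design value
  and SD `100 * cell_response_sd` points (default 10). The Beta shape is
  deliberate: near-saturating conditions pile up against the ceiling and
  weak conditions grow a no-response tail, the two qualitative features of
  real single-cell %ERK distributions. Each drawn value is then mapped to
  a stimulus-phase activity target by inverting the *full noise-free
  measurement map* (kinetics, ratio nonlinearity, framewise maxima,
  reference normalization) on a 401-point grid, so the truth table is
  exact by construction rather than approximate.
* **Mitosis.** A homogeneous Poisson process per condition; condition
  effects are rate multipliers.
* **Rendering.** `render_image_stack()` paints cells as uniform ellipses
  on a constant offset with optional Poisson pixel noise, with exact label
  masks and corner background ROIs, so extract-then-quantify round-trips
  the trace-level quantities (exactly, in the noise-free limit).

What the generator does **not** emulate: optical PSFs, split-view
misregistration, cell movement or division during FRET recordings,
bleach-rate differences between channels, correlated (non-lognormal) noise,
or resting-potential dynamics. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated noise model,
not robustness to registration or segmentation artefacts — segmentation is
explicitly out of scope (ROIs are inputs).

In voltage-driven mode, perfusion phases shift each cell's potential by
the Nernst *difference* relative to the baseline solution rather than
clamping it to $E_K$: resting cells are not pure K⁺ electrodes, and the
difference model preserves the logarithmic dose–response while respecting
heterogeneous resting potentials.

## Numerical conventions and degenerate inputs

* Windows and bins: half-open everywhere; an event exactly at a mitosis
  recording's end joins the final bin (the one closed edge, so no event is
  unbinnable).
* Lifetime fit: `optimize` on (bin width/20, 50·window) ns, tol 1e-10;
  boundary solutions raise with diagnostics.
* Activity integration: exact exponential relaxation per frame interval
  with the target held at its left-endpoint value, so frame values at
  phase switches reflect the outgoing phase — consistent with half-open
  phase membership.
* Degenerate statistics (zero variance, groups of one) are flagged in the
  returned tables rather than raised, except where a result would be
  meaningless to continue with (paired tests on unequal lengths, empty
  histograms).

## Problem sizes used by the packaged checks

The recovery studies run 4 conditions × 50 cells at 1% frame noise, 100
replicate seeds for correlation-sign stability, 200 replicates for the
two-group lifetime and the 13-experiment mitosis designs, and 1000 null
datasets for the Kruskal–Wallis size check. These sizes give Monte-Carlo
standard errors several-fold smaller than the tolerances they are checked
against while keeping the default test run fast.

## Known limitations

* The %ERK statistic presumes the EGF response approximates each cell's
  reporter ceiling; submaximal EGF responses inflate %ERK.
* The lifetime estimator's absolute values are comparable across cells and
  timepoints, but not necessarily to vendor software that fits
  multi-exponential models or deconvolves an IRF.
* No mixed-effects treatment of dish/experiment structure; dish effects
  are removed by normalization, not modelled.
* The simulator's designed %ERK ceiling (~99%) reflects the finite EGF
  phase; requesting designs above it truncates.
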