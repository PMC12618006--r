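# voltfret

Single-cell quantification of voltage-dependent ERK activity from FRET and
FLIM imaging.

Plasma-membrane potential modulates ERK signalling and, through it, cell
proliferation. Measuring that link requires turning noisy two-channel
(CFP/YFP) biosensor movies — acquired while the membrane potential is pushed
around by high-K⁺ perfusion or a voltage clamp — into per-cell statistics
that are comparable across dishes and cells. voltfret implements that
quantification pipeline for experimentalists and image analysts:

* **FRET ratio quantification** — background subtraction from pooled
  background ROIs, per-cell YFP/CFP ratios, dish-reference normalization,
  and the per-cell **% ERK activity** statistic

  ```
  % ERK = 100 · (max_stim R − R̄_baseline) / (max_EGF R − R̄_baseline)
  ```

  where `R` is the normalized YFP/CFP ratio and the saturating EGF response
  at the end of each recording serves as the per-cell ceiling; plus the
  explicit k·σ exclusion rule for cells that fail to respond to EGF, and
  phase-wise extrema for clamp protocols.
* **Membrane-potential model** — the Nernst map from extracellular K⁺ to
  predicted potential, `E = (RT/F)·ln([K⁺]o/[K⁺]i)` (59.16 mV/decade at
  298.15 K), and protocol objects describing perfusion/clamp timelines.
* **FLIM quantification** — donor-lifetime estimation from photon-decay
  histograms by binned truncated-exponential maximum likelihood, lifetime
  normalization, and Welch comparison of donor-only vs donor+acceptor
  populations (FRET shortens the donor lifetime).
* **Mitosis analysis** — binning of cytokinesis events, normalization to
  matched controls, accumulated-count ratios and their contrasts.
* **Statistics and reporting** — per-cell Pearson correlation of % ERK with
  log₁₀[K⁺] or clamped voltage, the group-comparison family
  (Kruskal–Wallis, exact rank-sum, t-tests), and CSV+figure report bundles.
* **Synthetic data** — a seeded generator emulating dish gain variation,
  cell-to-cell variability and non-responders, asymmetric activation
  kinetics, saturating EGF responses, photon-decay histograms, Poisson
  mitosis events, and rendered image stacks with exact masks, so the whole
  pipeline is testable by parameter recovery.

See `vignettes/voltfret-methods.Rmd` for the models, defaults, and design
decisions.

## Worked example

Simulate four perfusion conditions (5/15/30/145 mM K⁺, 50 cells each,
designed mean activities 5/25/55/95%), quantify them, and correlate the
recovered per-cell % ERK with log₁₀[K⁺]:

```r
library(voltfret)
library(dplyr)

design <- population_design(n_dishes = 5, cells_per_dish = 10, noise_cv = 0.01,
                            nonresponder_fraction = 0, seed = 1)
ts <- simulate_conditions(c(5, 15, 30, 145), design, kinetic_params(),
                          target_percent = c(5, 25, 55, 95))
q <- quantify_traceset(ts)

q$responses |> filter(included) |> group_by(k_out) |>
  summarise(n = n(), mean_percent_erk = mean(percent_erk), sd = sd(percent_erk))
#> # A tibble: 4 × 4
#>   k_out     n mean_percent_erk    sd
#>   <dbl> <int>            <dbl> <dbl>
#> 1     5    50             5.01 10.5
#> 2    15    50            25.7   9.00
#> 3    30    50            53.9   9.62
#> 4   145    50            93.7   8.65

corr <- correlate_erk(q$responses, "log10_k")
sprintf("Pearson R = %.2f, n = %d", corr$r, corr$n)
#> [1] "Pearson R = 0.96, n = 200"

nernst_potential(145, 14.5)   # mV per tenfold K+ change at 298.15 K
#> [1] 59.15935
```

The condition means recover the designed activities to within a few
percentage points despite per-frame noise, dish gains, and photobleaching —
the normalizations remove exactly those nuisances — and % ERK rises
monotonically with the Nernst-predicted potential.

The same machinery runs end to end from a config file, including the
report bundle:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "voltfret"),
             out_dir = "results/demo")
```

A thin CLI over the same functions is shipped at
`inst/cli/voltfret.R` (subcommands `run`, `simulate`, `quantify`, `flim`,
`mitosis`, `stats`).

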