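---
title: "Electron-flux accounting in denitrifying microbial fuel cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-flux accounting in denitrifying microbial fuel cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcflux)
```

## The accounting model

A batch-fed microbial fuel cell (MFC) whose anode biofilm both respires
on the electrode and denitrifies hosts a competition for one resource:
the electrons of the organic substrate. `mfcflux` treats each batch
cycle as a closed Faradaic ledger. Substrate oxidation liberates a
total charge $C_t$, measured from the chemical-oxygen-demand (COD) drop
between the first and last sample:

$$C_t = \frac{\Delta \mathrm{COD}\,[\mathrm{g}]}{32\ \mathrm{g\,mol^{-1}}}
        \times 4 \times F,$$

because one mole of O2-equivalent accepts four moles of electrons.
Acetate bookkeeping is equivalent: complete oxidation releases 8 e⁻ per
acetate, and one gram of sodium acetate (82.0 g mol⁻¹) carries
$1000 \times 2 \times 32 / 82 = 780.5$ mg COD. The ledger then splits
into

- $C_{an} = \int V(t)/R_{ext}\,dt$ — charge through the external
  circuit (anode respiration), integrated by the trapezoidal rule on
  the logged voltage (default logging every 5 min);
- $C_{de}$ — electrons consumed reducing nitrate to N2 at 5 e⁻ per N
  (14.0 g mol⁻¹);
- $C_{ot} = C_t - C_{an} - C_{de}$ — the residual: biomass synthesis
  and overpotential losses.

Coulombic efficiency is $CE = 100\,C_{an}/C_t$ and the
denitrification-corrected efficiency $CCE = 100\,C_{an}/(C_t-C_{de})$.
Because $C_{ot}$ is defined as a residual, conservation
$C_{an}+C_{de}+C_{ot}=C_t$ holds to machine precision by construction;
a *negative* residual is reported, never clamped, because it can only
mean the measured sinks exceed the measured source — an inconsistency
the analyst should see.

### Assumptions

- Nitrate is reduced fully to N2. Residual nitrite can optionally be
  credited back (nitrate stalled at nitrite used only 2 of 5
  electrons); the correction is off by default because nitrite at cycle
  end is typically below detection. A nonzero final ammonium triggers a
  warning, since dissimilatory reduction to ammonium (8 e⁻ per N) would
  invalidate the 5 e⁻ accounting.
- $C_t$ uses the endpoint COD difference, not the intra-cycle time
  course; intermediate COD samples are accepted but not required.
- Electron equivalents, molar masses and the Faraday constant live in a
  single `stoich_constants()` object, overridable from a JSON/YAML
  config. Molar masses default to 82.0 and 14.0 so the derived
  780.5 mg COD g⁻¹ conversion matches its conventional printed value;
  higher-precision masses move derived ratios only in the third
  decimal.

### The stoichiometric reference point

The critical COD/N ratio — the stoichiometric minimum COD per unit
nitrate-N for complete heterotrophic denitrification with biomass
synthesis — comes from the conventional biomass-inclusive reaction

$$7.03\,\mathrm{CH_3COO^-} + 8.58\,\mathrm{NO_3^-} \rightarrow
  0.58\,\mathrm{C_5H_7O_2N} + 11.16\,\mathrm{CO_2} + 8.58\,\mathrm{OH^-}
  + 7.74\,\mathrm{H_2O} + 4\,\mathrm{N_2},$$

evaluated as (7.03 × 82.0 × 0.7805) / (8.58 × 14.0) = 3.75 g COD per
g N. The printed coefficients balance in C, N and O but **not** in H
(21.09 vs 28.12) or charge (−15.61 vs −8.58); `check_element_balance()`
reports these discrepancies rather than silently re-balancing, and the
ratio uses the coefficients exactly as conventionally given — that is a
deliberate design choice, since the ratio is defined by the C:N
stoichiometry, which is internally consistent.

```{r}
critical_cod_n_ratio(denitrifier_stoichiometry())
check_element_balance(denitrifier_stoichiometry())
```

## Kinetics

Nitrate decline in these reactors is well described by first-order
kinetics, $C(t) = C_0 e^{-kt}$. The default fit is log-linear least
squares on $\ln C$ — robust, initial-guess-free, and exact on clean
exponential data. Samples at or below a detection floor (default
0.1 mg L⁻¹, reflecting typical UV-spectrophotometric limits) are
excluded, because the logarithm of a near-zero reading is dominated by
analytical noise. A nonlinear least-squares variant (`stats::nls`,
seeded by the log-linear pass) is available for series where near-zero
values carry real information. Volumetric removal rates are
endpoint averages, reported in both mg N L⁻¹ h⁻¹ and
kg N m⁻³ d⁻¹ (× 0.024); the endpoint-average convention was chosen as
the headline statistic because it is the one a mass balance over the
cycle actually constrains.

## Electrochemistry

**Polarization.** A resistance sweep gives (R, V) points; per point
I = V/R, current density I/A and power density VI/A, normalized to the
cathode area (default 7 cm²). The maximum power density is taken over
the *measured* points with no interpolation, matching discrete sweep
practice; if the maximum lands on a sweep boundary the result is
flagged. Internal resistance is the negated least-squares slope of V
against I, and for a linear cell the maximum-power-transfer theorem
places the MPD point at $R_{ext} = R_{int}$ — a property the test suite
checks across a random (OCV, $R_{int}$) grid.

**Cyclic voltammetry.** At a 1 mV s⁻¹ scan over −0.6..0.2 V the raw
current derivative is noise-dominated, so each sweep segment is
smoothed with a Savitzky–Golay moving polynomial (order 2, default
window 11 samples) before centered finite differencing. Redox peaks are
local extrema with topographic prominence of at least a configurable
fraction (default 5%) of the segment's current scale, taken as the
larger of the smoothed current's range and its maximum magnitude — the
magnitude term keeps a flat capacitive trace with instrument noise from
producing spurious detections. Inflection structure (extrema of dI/dE)
resolves redox centres that merge into a single broad current wave.
Batch staging for CV sampling uses threshold conventions — first rise
above 10% of the voltage maximum, the maximum, the midpoint of the
≥95% plateau, first drop below 50%, and the 20 mV cycle-end rule —
which are not standardized anywhere; they were chosen to segment the
canonical five-stage description reproducibly and are exposed as
arguments.

## The synthetic-data generator

`simulate_batch_cycle()` emulates the operating regime the analysis
targets: 15 mL anolyte, 1 kΩ external resistance, 780.5 mg L⁻¹ COD
feed, nitrate-N between 0 and 200 mg L⁻¹, 5-min voltage logging, and a
voltage plateau (default 0.45 V) that collapses when the electron donor
runs out. Its mechanics encode the donor-limitation hypothesis: anode
respiration and denitrification draw *concurrently* on one COD pool, so
added nitrate shortens the cycle without lowering the plateau. Nitrate
declines first-order until donor depletion; after depletion the voltage
decays exponentially with a 0.5 h time constant (any positive constant
satisfies the 20 mV cycle-end rule; 0.5 h gives a decay tail of
realistic length). The COD trajectory is constructed so that electrons
consumed equal $C_{an}+C_{de}+C_{ot}$ with $C_{ot}$ exactly the
configured `others_fraction` of the total *before* noise, and the cycle
is timed to leave ~0.5% of the COD budget as residual so the endpoint
stays positive under noise — a realistic residual COD. Measurement
noise is multiplicative log-normal with unit mean (default CV 2%),
drawn independently per channel; every generator is a deterministic
function of (config, seed).

What the generator does **not** emulate: biofilm growth dynamics, pH
and buffering, mass-transfer limits, nitrite transients, electrode
capacitance, drift, or sampling gaps. Passing round-trip tests
therefore demonstrates that the *accounting* is self-consistent and
noise-robust, not that real reactors obey the generator's mechanics;
on real data the residual term absorbs every unmodelled sink.

```{r}
sim <- simulate_batch_cycle(sim_config(initial_no3n_mg_l = 50), seed = 42)
bal <- electron_balance(sim$cycle)
bal
c(truth = sim$truth$ce_pct, recovered = bal$ce_pct)
```

## Numerical choices and degenerate inputs

- Trapezoidal integration throughout (exact for the piecewise-linear
  signals the logger produces).
- Cycle splitting in multi-cycle files uses the 20 mV threshold with a
  3-sample debounce, so a single noisy dip does not end a cycle.
- $CE$ is undefined when no COD was consumed; requesting it with
  nonzero circuit charge is an error, not a silent `Inf`. $CCE$ with
  $C_{de} \ge C_t$ is `NA` with an explicit flag.
- Element-balance tolerance defaults to 0.05 formula units, matching
  coefficients printed to two decimals.
- First-order fits require ≥ 3 samples and at least two above the
  detection floor; an all-zero series is a degeneracy error. A constant
  series fits $k = 0$ with $R^2 = 1$ by convention (the zero-rate model
  is exact).
- Net COD/N is offered in two accountings — `"residual"`
  ($C_t - C_{an}$, i.e. everything not recovered as current, per unit
  N) and `"dissimilatory"` ($C_{de}$ per unit N, the constant
  40/14 = 2.86) — because published "net" ratios rarely state which
  convention they use; the residual mode is the default since it is the
  quantity an operator can influence.

## Problem sizes used in validation

The test suite validates parameter recovery on 100-seed ensembles of
simulated cycles (≈700 samples each at 5-min logging), 100 simulated
kinetic series with $k \in [0.05, 0.5]$ h⁻¹, and 20–25-point random
grids for the electrochemical properties; these sizes give stable
medians while keeping the full suite under a few seconds.

## Known limitations

- Endpoint-based $C_t$ ignores COD produced or consumed by processes
  invisible to the endpoint difference (e.g. cryptic internal cycling).
- The 5 e⁻ nitrate accounting is only as good as the assumption that N2
  is the terminal product; the package warns on ammonium but cannot see
  N2O.
- Internal resistance from the V–I slope assumes ohmic behaviour over
  the sweep; activation and concentration overpotentials curve the
  polarization line at its ends and will bias the estimate if the sweep
  spans them.
- Peak detection reports potentials at the sampling resolution; with a
  1 mV step, sub-millivolt peak localization is not attempted.
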