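# mfcflux

Electron-flux accounting for microbial fuel cells (MFCs) that remove
nitrate while generating electricity.

## The problem

In a batch-fed MFC whose anode community both respires on the electrode
and denitrifies, the electrons liberated by substrate (acetate)
oxidation split three ways: into the external circuit, into nitrate
reduction, and into biomass synthesis plus losses. Quantifying that
split is how one decides whether nitrate *inhibits* electricity
generation or merely *competes* for the same electron donor. `mfcflux`
implements the full accounting pipeline for researchers running such
reactors: Faradaic electron balances per batch cycle, coulombic
efficiency statistics, COD/N stoichiometry, nitrate-removal kinetics,
and polarization / cyclic-voltammetry analysis — plus a deterministic
batch-cycle simulator so the whole pipeline is testable end to end
without instrument data.

## The model

Per batch cycle, with Faraday constant F:

- **Total electrons** `C_t` from the COD drop:
  `C_t = ΔCOD(g) / 32 × 4 × F` (1 mol O2 ≡ 4 mol e⁻; acetate
  equivalently gives 8 e⁻ per mole, and 1 g sodium acetate ≡ 780.5 mg
  COD).
- **Anode respiration** `C_an = ∫ V(t)/R_ext dt` (trapezoidal rule).
- **Anodic denitrification** `C_de = ΔNO3-N(g) / 14 × 5 × F`
  (nitrate → N2, 5 e⁻ per N; optional correction for residual
  nitrite).
- **Others** `C_ot = C_t − C_an − C_de` (biomass synthesis and
  overpotential losses), reported even when negative.

From these: coulombic efficiency `CE = 100 C_an / C_t`, the
denitrification-corrected efficiency `CCE = 100 C_an / (C_t − C_de)`,
electron fractions, and net COD/N ratios. The critical COD/N ratio for
heterotrophic denitrification follows from the biomass-inclusive
stoichiometry `7.03 CH3COO⁻ + 8.58 NO3⁻ → 0.58 C5H7O2N + …`, giving
**3.75 g COD per g N**. Nitrate decline is fitted as first-order,
`C(t) = C0 e^(−kt)`; polarization sweeps yield the maximum power
density and internal resistance; voltammograms get Savitzky–Golay
smoothing, first-derivative inflection analysis, and prominence-based
redox-peak detection.

## Worked example

```r
library(mfcflux)

# a batch cycle: 780.5 mg/L COD, 50 mg/L nitrate-N, 2% instrument noise
cfg <- sim_config(initial_no3n_mg_l = 50, k_no3_h = 0.3, noise_cv = 0.02)
sim <- simulate_batch_cycle(cfg, seed = 42)

electron_balance(sim$cycle)
#> Electron balance (Coulombs):
#>   c_t  total (COD)        140.8
#>   c_an anode respiration  100.5
#>   c_de denitrification    26.16
#>   c_ot others (residual)  14.12
#>   CE  71.4 %   CCE  87.7 %

d <- sim$cycle$data
fit_first_order(d$time_h, d$no3n_mg_l)
#> First-order removal fit (log-linear):
#>   k  = 0.3001 1/h   (half-life 2.31 h)
#>   c0 = 50.09 mg/L   R2 = 0.9999

volumetric_removal_rate(50.09, 1 - exp(-0.3001 * 6), 6)
#>  mg_n_l_h kg_n_m3_d
#> 6.9691908 0.1672606
```

Reading the output: of the ~141 C liberated by COD oxidation, 71.4%
reached the circuit (CE); excluding the 26 C that legitimately went to
denitrification raises the corrected efficiency to 87.7% (CCE). The
fitted rate constant recovers the configured 0.3 h⁻¹, and over the
first 6 h the reactor removed nitrogen at 0.167 kg N m⁻³ d⁻¹. The
simulator also returns the ground-truth partition (`sim$truth`), which
the recovered balance matches within noise.

Polarization and CV:

```r
pc <- simulate_polarization(ocv_v = 0.7, r_int_ohm = 200)
polarization_analysis(pc)       # MPD 0.875 W/m2 at 2.5 A/m2, R_int = 200

cv <- simulate_cv(data.frame(center_v = c(-0.21, -0.185),
                             height_a = c(2e-4, 1.5e-4),
                             width_v = 0.03,
                             kind = c("anodic", "cathodic")))
detect_redox_peaks(cv)          # recovers both peak potentials
```

A thin command-line wrapper ships in `exec/mfcflux`
(`mfcflux simulate|balance|kinetics|polarization|cv|report`), driving
the same functions over the CSV dialect documented in
`?read_cycle_csv`.

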