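# rdapso

Estimation of the diffusion coefficient of dispersing insects from
mark-release-recapture (MRR) field data.

In an MRR experiment, marked insects (classically *Aedes aegypti*
mosquitoes) are released from a single point and recaptured over the
following days at traps or collection houses grouped into concentric
annular zones.  Recapture rates are a few percent and capture sites are
rarely spread evenly, which makes the dispersal coefficient `D` (m²/day)
— the key input to reaction–diffusion models of vector spread — hard to
estimate well from such data.

The package provides four estimators that all consume the same inputs, the
temporal recapture ratios `τ_i` (fraction of recaptures on collection day
`i`) and spatial ratios `σ_j` (fraction of recaptures in zone `j`):

* **MDT-based**: inverts `⟨r⟩_t = √(πDt)` through the τ-weighted mean
  distance traveled, `D = (1/π) (MDT / Σ_i τ_i √t_i)²`.
* **Time-corrected (TC)**: least-squares match of `σ_j` against the
  τ-weighted annulus probabilities
  `Σ_i τ_i [exp(−r_{j−1}²/4Dt_i) − exp(−r_j²/4Dt_i)]`.
* **Area-and-time-corrected (ATC)**: the TC fit after the Lillie
  trap-density correction `N_j^c = N_j (nT_tot/nT_j)(A_j/A_tot)`.
* **RDA-PSO**: an agent-based forward model — `N` walkers taking `S` fixed
  steps of length `k·h` per day among capture sites with a collection disk
  (radius `q·h`), attracting annulus (width `p·h`) and Bernoulli efficiency
  `s_e` — inverted by a grid search plus particle swarm optimization that
  minimizes the discrepancy `E = ½(‖σ−σᵒ‖ + ‖τ−τᵒ‖)` and converts the
  recovered step multiplier through `D = (S/4)(k·h)²`.  The trap parameters
  are not individually identifiable, but `k` (hence `D`) is.

## Worked example

The village-center release of a published MRR study recaptured 105 females
over six days (day counts 48, 14, 10, 16, 9, 8) in six 15 m zones (zone
counts 85, 13, 3, 4, 0, 0), with a reported mean distance traveled of
15 m:

```r
library(rdapso)
tau   <- c(48, 14, 10, 16, 9, 8) / 105
sigma <- c(85, 13, 3, 4, 0, 0) / 105

estimate_D_mdt(tau, 1:6, mdt_emp = 15)
#> [1] 32.09944

fit_tc(sigma, tau, 1:6, seq(0, 90, by = 15))
#> Time-corrected diffusion fit: D = 12.81 m^2/day (SSE 0.003543)

k_to_D(36.87)   # mean step multiplier from replicated RDA-PSO runs
#> [1] 40.78191
```

The MDT estimator reads the data as a diffusion displacement of 32.1
m²/day; the time-corrected fit, which ignores the uneven house placement,
gives 12.8; the RDA-PSO estimate (40.8, from the mean recovered `k` of
replicated inverse runs) needs no area correction because the simulated
capture sites occupy the same zones as the real ones.

A full synthetic round trip with known truth:

```r
spec <- scenario_spec(k = 35, seed = 101)       # D_true = 36.75 m²/day
scn  <- run_scenario(spec)
obs  <- sim_ratios(scn$sim)
cfg  <- pso_config(bounds = list(k = c(15, 55), q = c(5, 30),
                                 p = c(0, 15), s_e = c(0.001, 1)),
                   sim_N = 2000, sim_reps = 2)
res  <- run_replicates(obs, scn$layout, walk_config(k = 1, n_days = 6),
                       c(15, 55), c(5, 30), config = cfg,
                       n_runs = 10, seed = 7)
res
#> RDA-PSO estimate from 10 runs (8 kept, rule mean+1.0sd):
#>   k = 34.97 +/- 0.5763 (Shapiro-Wilk p = 0.151)
#>   D = 36.7 m^2/day, 95% CI [35.86, 37.54]
```

The filtered mean recovers the generating coefficient to a fraction of a
percent.  A command-line front end (`inst/cli/rdapso`) exposes the same
workflow as `simulate`, `estimate-mdt`, `fit-tc`, `fit-atc`, `rda-pso` and
`scenario` subcommands.

See the vignette (`vignettes/estimating-dispersal.Rmd`) for the model
details, parameter conventions and numerical choices.

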