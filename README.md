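# hsp90cycle

Analysis toolkit for the energetic and kinetic coupling between local ATP
hydrolysis and global conformational dynamics in the Hsp90 molecular
chaperone — and, more generally, for any enzyme whose catalytic barrier is
tuned by a conformational switch.

Hsp90 is a homodimeric, ATP-dependent chaperone whose N-terminal domain
(NTD) hydrolyses ATP while the dimer cycles between open and closed
conformations. A conserved NTD ion pair (Arg-32/Glu-33 in yeast numbering)
acts as an electrostatic switch: while the salt bridge is closed it lowers
the proton affinity of the catalytic glutamate and keeps the hydrolysis
barrier high; when it opens, the barrier drops by several kcal mol⁻¹ and the
chemistry becomes fast. The package implements the complete quantitative
chain used to analyse this mechanism:

* **Umbrella sampling / WHAM** (`umbrella_window()`, `wham_solve()`,
  `bootstrap_profile()`, `barrier_height()`): reconstructs free-energy
  profiles g(R) along the hydrolysis reaction coordinate
  R = r₄ − r₃ + r₂ − r₁ from harmonically biased windows, with Monte Carlo
  bootstrap error bars.
* **Eyring kinetics** (`rate_from_barrier()`, `barrier_from_rate()`):
  k = κ(k_BT/h)·exp(−ΔG\*/RT) and its inverse, with CODATA constants.
* **Ion-pair dynamics** (`sidechain_distance_trace()`, `classify_ionpair()`,
  `dwell_times()`, `count_ion_pairs()`, `fit_inverse_distance()`,
  `coulomb_pka_shift()`): distance traces from multi-model PDB trajectories,
  open/closed classification at the 5 Å threshold, salt-bridge counting,
  the coulombic ΔG‡(d) = a + b/d barrier-tuning model, and a point-charge
  estimate of the glutamate pKa shift.
* **Chaperone-cycle kinetics** (`build_default_model()`, `steady_state()`,
  `simulate_ssa()`, `required_closing_reduction()`): a five-state
  open → closed₁ → active → closed₂(ATP) → closed₂(ADP·Pi) → open Markov
  cycle, solved both deterministically and by exact Gillespie simulation,
  including decoupling-mutant perturbations (faster catalysis, slower
  closing, futile open-state hydrolysis).
* **Biophysical fits** (`fit_monoexponential()`, `fit_adp_trace()`,
  `fit_michaelis_menten()`, `fit_anisotropy_competition()`, `csp()`,
  `het_noe()`, `guinier_fit()`, `pr_from_coordinates()`): the standard
  analysis equations for FRET transients, NADH-coupled ADP-release assays,
  ATPase Michaelis–Menten curves, fluorescence-anisotropy competition
  titrations, NMR chemical-shift perturbation and heteronuclear NOE, and
  SAXS Guinier / P(r) analysis.
* **Synthetic data** (`gen_*()`): seeded generators for every input —
  Boltzmann-distributed umbrella samples, telegraph ion-pair traces,
  FRET/absorbance/titration/peak-list/scattering data — each carrying its
  ground truth as an attribute so that every analysis stage has an
  automated recovery test.

## Worked example

```r
library(hsp90cycle)

# barrier -> rate for the closed and open ion-pair conformations
k_closed <- rate_from_barrier(25, temperature = 310)
k_open   <- rate_from_barrier(18, temperature = 310)
coulomb_pka_shift(5.5)                        # pKa shift on ion-pair opening

# chaperone cycle: how much slower closing buffers 100x faster catalysis
model <- build_default_model()
steady_state(model)$turnover
required_closing_reduction(model, f_cat = 100)

# umbrella sampling round trip on the double-well benchmark
dw <- default_double_well(10)
wins <- gen_umbrella_dataset(dw, centers = seq(-2.9, 2.6, by = 0.2),
                             force_constant = 100, n_per_window = 1000,
                             seed = 7)
prof <- bootstrap_profile(wins, n_trials = 10, seed = 1)
barrier_height(prof, reactant_range = c(-2.6, -1.2),
               ts_range = c(-0.8, 0.6))
```

This prints:

```
closed ion pair:  k = 1.5e-05 s^-1 (hours)
open ion pair:    k = 1.3 s^-1 (seconds)
pKa shift at 5.5 A, eps = 4: 10.6 units
baseline turnover: 0.496 min^-1
f_close for f_cat = 100: 1.99
recovered barrier: 10.06 kcal/mol (truth 10)
```

Reading: with the salt bridge closed (25 kcal mol⁻¹ barrier) a single
hydrolysis event takes hours; with the fully open/shielded configuration
(18 kcal mol⁻¹) it takes about a second, bracketing the measured
0.1–1 min⁻¹ turnover. The point-charge model attributes ~10 pKa units of
glutamate activation to the ion-pair opening. In the cycle model, a 100-fold
faster catalytic step needs only a ~2-fold slower closing pathway to leave
the observable ADP-release rate unchanged — the decoupling-mutant argument.
The WHAM layer recovers a known 10 kcal mol⁻¹ double-well barrier from
biased samples to within the bin resolution.

A thin command-line wrapper is included (`inst/cli/hsp90cycle`), e.g.
`hsp90cycle rates --barrier 18 --temp 310`.

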