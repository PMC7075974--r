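---
title: "Models and methods: energetic and kinetic coupling in the Hsp90 cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: energetic and kinetic coupling in the Hsp90 cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsp90cycle)
```

# Scope

`hsp90cycle` implements the quantitative chain that connects a local
electrostatic switch in the Hsp90 N-terminal domain — the Arg-32/Glu-33 ion
pair — to the observable kinetics of the chaperone cycle: free-energy
profiles along the ATP-hydrolysis coordinate, transition-state-theory rates,
ion-pair trajectory statistics, a stochastic model of the conformational
cycle, and the curve-fitting equations used for the accompanying
biophysical assays. This vignette documents the models, their assumptions,
the tunable parameters, and the numerical choices; it is the package's own
account of its methods.

# Reaction coordinate and free-energy reconstruction

## Model

ATP hydrolysis is followed along a one-dimensional collective coordinate

$$R = r_4 - r_3 + r_2 - r_1 \quad [\mathrm{\AA}],$$

combining the proton-transfer forming/breaking distances ($r_1$, $r_2$) and
the phosphate bond forming/breaking distances ($r_3$, $r_4$). Reactants sit
near $R = -2.9$ Å, products near $R = 2.6$ Å; that interval is also the
default binning range (0.1 Å bins).

Biased sampling windows carry a harmonic restraint
$U_i(R) = \tfrac{1}{2} k_i (R - R_{0,i})^2$. Force-constant reporting
conventions differ between simulation codes (some fold the ½ into the
constant), so the convention is an explicit per-window field
(`bias_convention = "half_k"` or `"full_k"`), declared in the window file
header rather than guessed. The default is `half_k`; typical stiffnesses
are 100 or 500 kcal mol⁻¹ Å⁻².

`wham_solve()` iterates the standard WHAM self-consistency equations on the
binned histograms in log space (log-sum-exp throughout, so stiff windows at
500 kcal mol⁻¹ Å⁻² do not underflow). Convergence is declared when the
largest change in any window free-energy constant $-k_BT \ln f_i$ drops
below `tol` = 1e-5 kcal mol⁻¹; the default `max_iter` is 1e5 and hitting it
raises an error carrying the last residual rather than returning a
half-converged profile. The profile is anchored to min = 0 over populated
bins; empty bins are `NA` and excluded from anchoring and from
`barrier_height()` searches. Ties in the barrier search break towards the
lowest $R$.

Windows must be connectable through shared populated bins; otherwise the
relative offsets of the disconnected groups are unidentifiable and
`wham_solve()` refuses with a disconnected-windows error instead of
silently pinning an arbitrary offset.

## Error bars

`bootstrap_profile()` resamples each window's observations with replacement
(default ten Monte Carlo trials, the conventional choice for umbrella error
bars), re-solves, re-anchors every trial profile, and reports the per-bin
standard deviation. Failed trials are reported via an attribute, never
silently dropped; at least two must succeed.

No statistical-inefficiency correction is applied to the samples. The
intended inputs are short (tens of ps) stiffly restrained QM/MM trajectories
whose effective sample sizes are not well estimated by block methods at
that length; treating samples as independent slightly underestimates the
bootstrap errors. The per-bin `counts` slot is exposed so a correlation
correction can be layered on externally.

## Synthetic benchmark

`gen_umbrella_dataset()` draws samples from
$p(R) \propto e^{-(G(R)+U(R))/k_BT}$ by inverse-CDF sampling on a 4000-point
grid. The default benchmark, `default_double_well(10)`, is a quartic
double well with minima near $R = -1.9$ and $1.6$ Å and a 10 kcal mol⁻¹
saddle — chosen to span the full coordinate range at a barrier comparable
to the chemistry being emulated. The recovery tests use 28 windows spaced
0.2 Å apart at k = 100 kcal mol⁻¹ Å⁻², 1000 samples each: at 310 K this
gives a per-window spread of ≈ 0.08 Å, enough histogram overlap for a
connected solve while keeping the whole round trip near a second of
compute. The suite requires ≤ 0.2 kcal mol⁻¹ RMS deviation from the
analytic truth over populated bins; the residual error at these settings is
dominated by bin discretisation, not sampling.

What the generator does *not* emulate: correlated samples (every draw is
independent), anharmonic restraint artefacts, and pull-off/relaxation
transients at window boundaries. Passing the recovery test therefore
validates the estimator, not the adequacy of any particular simulation
protocol.

# Transition-state kinetics

`rate_from_barrier()` implements $k = \kappa (k_B T/h) e^{-\Delta G^*/RT}$
with the reflection coefficient $\kappa = 1$ by default, and
`barrier_from_rate()` its algebraic inverse (round trip exact to 1e-10
relative over 0–40 kcal mol⁻¹, tested). All physical constants come from a
single CODATA-2018 table (`phys_constants`), with the thermochemical
calorie (4184 J) exact; the gas constant in kcal units is derived, not
typed separately, so the Eyring layer and the WHAM Boltzmann factors cannot
drift apart. At 310 K: 18 kcal mol⁻¹ ↦ ≈ 1.3 s⁻¹, 25 kcal mol⁻¹ ↦
≈ 1.5e-5 s⁻¹. `timescale_label()` maps $1/k$ onto seconds (< 60 s),
minutes (< 1 h), hours (< 1 d), days. Tunnelling and variational
corrections are out of scope.

# Ion-pair dynamics

Distances are measured between named side-chain atoms (for the
Arg-32/Glu-33 pair: the guanidinium Cζ and the carboxylate Cδ).
`classify_ionpair()` applies a hard threshold, default 5 Å, with a frame
exactly at the threshold counted as closed; no hysteresis or minimum-dwell
debouncing is applied because the underlying convention is a plain
distance split. Consequently, observation noise near the threshold
fragments dwells — see below.

`dwell_times()` converts state runs into durations using the uniform frame
spacing (explicit per-frame durations must be supplied otherwise). The
first and last runs are censored (their entry/exit was not observed) and
excluded from the dwell means.

`count_ion_pairs()` counts a residue pair once if any opposite-charge
heavy-atom pair (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2, Asp OD1/OD2,
Glu OE1/OE2, C-terminal carboxylate) across the two groups lies within the
cutoff, default 4.0 Å — the common salt-bridge convention. Residues
without charged atoms trigger a warning and are skipped.

The electrostatic tuning model, `fit_inverse_distance()`, is ordinary
least squares of the barrier against $1/d$: the intercept $a$ is the fully
screened barrier, the slope $b$ the effective coulombic coupling.
`coulomb_pka_shift()` is the matching point-charge estimate
$\Delta pK_a = C |q_1 q_2| / (\varepsilon d \ln 10\, RT)$ with
$C = 332.06$ kcal Å mol⁻¹ e⁻² and a protein-interior dielectric
$\varepsilon = 4$ by default; at contact distance (5.5 Å) it gives
≈ 10.6 units. This is deliberately the crudest defensible model — a full
Poisson–Boltzmann treatment with explicit titration sampling is out of
scope — and should be read as an order-of-magnitude statement.

## Telegraph generator and test conditions

`gen_two_state_trace()` simulates the two-state continuous-time Markov
(telegraph) process exactly (exponential dwells), samples it on the frame
grid, and adds Gaussian observation noise around the state means. Defaults:
closed 4.0 Å, open 8.0 Å, noise SD 0.4 Å, switching rates 0.02 ns⁻¹
(mean dwell 50 ns), frame spacing 0.5 ns. The true state sequence is kept
in the `truth` attribute.

Occupancy tests run at the default 0.4 Å noise: misclassification at the
5 Å threshold is ≈ 0.6% per frame and shifts occupancies negligibly. The
dwell-law tests instead use a 0.05 Å observation noise: with 0.4 Å noise
the ≈ 0.6% per-frame threshold crossings fragment long dwells and bias the
observed mean downward by tens of percent — a property of hard-threshold
classification on noisy data, not of the dwell estimator. Testing the
exponential dwell law at low noise isolates the estimator; the residual
discretisation bias (≈ dt/2) is accounted for in the tolerance. Users
analysing noisy experimental traces should be aware of the same
fragmentation effect (an optional minimum-dwell filter is a reasonable
extension; it is off by default because the underlying convention defines
none).

# The chaperone-cycle model

## States, rates and calibration

The cycle (`build_default_model()`) is the five-state unidirectional chain

open → closed₁(ATP, inactive) → active → closed₂(ATP, active) →
closed₂(ADP·Pi) → open,

with ATP binding lumped into the first closing step (assays run at
saturating nucleotide) and no reverse reactions. The three conformational
steps are all tagged `closing`, catalysis (closed₂-ATP → closed₂-ADP·Pi)
is tagged `catalysis`, product release `release`.

The elementary rates of the real cycle are not individually measured;
the defaults are a calibration chosen once against two constraints:
(i) the steady-state turnover matches the measured wild-type ADP-release
scale, and (ii) the closing pathway and the catalytic step contribute
comparably to the cycle time, which is the regime in which conformational
buffering of a faster catalytic step is possible at all. Closing steps at
3 min⁻¹ each, catalysis 1 min⁻¹ and release 60 min⁻¹ give

$$\text{turnover} = \left(3\cdot\tfrac{1}{3} + 1 + \tfrac{1}{60}\right)^{-1}
\approx 0.496\ \text{min}^{-1}.$$

All rates are overridable through `cycle_model()`.

## Steady state, SSA and the decoupling argument

`steady_state()` solves the stationary linear master equation (one balance
row replaced by normalisation); self-loop (decoupled) reactions do not
enter the generator matrix but their flux $k_{dec}\pi_{open}$ is reported
separately. `simulate_ssa()` is the exact direct-method Gillespie
algorithm over independent enzymes, bit-reproducible per seed, with
time-weighted occupancies and a between-enzyme SEM on the turnover.

`build_variant()` encodes the decoupling perturbation: catalysis × f_cat,
every closing rate ÷ f_close, and an optional futile open → open
hydrolysis branch. `required_closing_reduction()` bisects
f_close ∈ [1, 100] for the value at which the perturbed turnover equals
baseline. On a unidirectional cycle this has a closed form — the cycle
time freed by faster catalysis must be re-absorbed by slower closing,

$$f_{close} = \frac{t_{close} + t_{cat}(1 - 1/f_{cat})}{t_{close}},$$

which the bisection result matches to 1e-6 relative in the tests. With the
default calibration, f_cat = 100 requires f_close ≈ 1.99 and f_cat = 10
requires ≈ 1.9: a large catalytic acceleration is buffered by a mere
two-fold slower closing, which is why an activated-chemistry mutant can
show an unchanged ADP-release rate.

Not modelled: client and co-chaperone binding, nucleotide exchange as a
separate step, reverse conformational transitions, and protomer asymmetry
(sequential hydrolysis across the two subunits); the model is a
single-enzyme Markov chain.

# Biophysical fitting equations

All nonlinear fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) with
deterministic data-driven starting values; there is no stochastic
multi-start. Non-convergence returns a flagged result carrying the
optimiser message rather than throwing, so batch pipelines can triage.

* **Mono-exponential** (`fit_monoexponential()`):
  $y = A_1 e^{-x/t_1} + y_0$, $k_{App} = 1/t_1$ with
  $se(k) = se(t_1)/t_1^2$. The published rendering of this equation
  typesets the exponential as a power of $A_1$; it is read here as the
  standard exponential decay, which is the only dimensionally coherent
  interpretation and matches its companion definition $k_{App} = 1/t_1$.
  Starting values: plateau from the trailing 10% of points, $t_1$ from a
  log-linear pre-fit. A converged optimum with $t_1 \le 0$ is rejected.
* **ADP release** (`fit_adp_trace()`, `adp_release_rate()`): OLS slope over
  a declared window, background slope (post-inhibitor segment) subtracted,
  then $k = -m/(\varepsilon_{NADH} c_{Hsp90} \ell)$. Defaults
  $\varepsilon_{NADH} = 6220$ M⁻¹ cm⁻¹ at 340 nm and $\ell = 1$ cm are
  standard assay values, both configurable.
* **Michaelis–Menten** (`fit_michaelis_menten()`): $v = V_{max}x/(K_M+x)$;
  ATP titrations typically span 0.1–5 mM.
* **Anisotropy competition** (`fit_anisotropy_competition()`). The
  published form of this fitting equation mixes anisotropy and
  concentration units and cannot be implemented as printed. The package
  uses a coherent trace-probe competition model built on the standard
  single-site quadratic (ligand-depletion) isotherm: the unlabelled
  titrant occupies the receptor according to
  $[HL] = \tfrac{1}{2}\big(s - \sqrt{s^2 - 4 c_H c_L}\big)$ with
  $s = c_H + c_L + K_D$, and the trace labelled probe (assumed to share
  the binding site and affinity, and to deplete neither species) reports
  the remaining free receptor through its bound fraction
  $[H]_{free}/([H]_{free} + K_D)$, mapped linearly onto anisotropy between
  $F_{PL}$ (no competitor, receptor in excess) and $F_P$ (probe fully
  displaced). This reproduces the expected limits ($r \to F_{PL}$ as
  $c_L \to 0$ with $c_H \gg K_D$; $r \to F_P$ at large $c_L$). Because the
  printed equation is not implementable, coefficient-level agreement with
  any published fit is not a meaningful target; the recovery tests use the
  package's own generator as truth.
* **CSP** (`csp()`):
  $\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}$
  with $\alpha = 0.1689$ (ratio of the ¹H and ¹⁵N shift ranges). Residues
  are matched by number; unmatched residues are reported, not fatal —
  unassignable residues are a normal feature of exchange-broadened
  spectra.
* **Heteronuclear NOE** (`het_noe()`): $I_{sat}/I_{ref}$ with baseplane
  noise propagated as
  $|r|\sqrt{(\sigma/I_{sat})^2 + (\sigma/I_{ref})^2}$.
* **Guinier** (`guinier_fit()`): weighted linear fit of $\ln I$ vs $q^2$
  over the largest low-q prefix with $q R_g \le 1.3$, iterated to
  self-consistency because the admissible range depends on the fitted
  $R_g$ itself; a non-negative slope (aggregation) is an error, not a
  number.
* **P(r)** (`pr_from_coordinates()`): pairwise-distance histogram with
  uniform weights, $D_{max}$, and
  $R_g^2 = \sum_{i<j} r_{ij}^2 / N^2$ computed from the *unbinned*
  distances. The self-pair normalisation ($N^2$, not the unordered pair
  count) is what makes the two-point case exact ($R_g = d/2$) and
  converges to $\langle r^2\rangle/2$ for dense clouds; computing the
  moment from bin centres would add an avoidable
  $O(\text{bin width})$ bias. The consistency of the Guinier and P(r)
  radii is tested on a uniform sphere cloud whose scattering is generated
  with the exact Debye sum (`gen_scattering_from_coords()`).

# Synthetic-data design

Every generator is deterministic given its seed; a top-level seed fans out
through fixed per-generator offsets
(`seed_substream = (1021·seed + offset) mod 2³¹−1`), so adding a generator
never shifts the streams of existing ones, and truth parameters ride along
as an attribute of every output. Default truth values are set at the
scales of the measured system (wild-type release 0.50 min⁻¹, mutant
0.55 min⁻¹, a 10-fold re-opening ratio, NOE 0.58, radii of gyration 53.1 Å
and 62.3 Å for the compact and open dimer) so the recovery tests exercise
the analyses at realistic signal-to-noise.

The generators emulate the *statistical structure* the analyses assume
(exponential dwells, Gaussian noise, exact model curves). They do not
emulate instrument drift, photobleaching, correlated noise, buffer
mismatch in scattering, or peak overlap in spectra. A passing recovery
test therefore certifies the estimator under its own assumptions; it does
not certify those assumptions for any particular instrument.

# Problem sizes and determinism

The test suite and the acceptance script are sized to run comfortably on a
single CPU: the WHAM benchmark uses 28 × 1000 samples, the stochastic
cycle check 200 enzymes × 500 min (≈ 2.5e5 events), the ADP-release
recovery 2 × 100 replicate traces of 101 points, and the FRET ratio two
200-point traces. All stochastic tests fix seeds; agreement criteria are
stated in SEM or standard-error units computed from the data, not as bare
percentages, except where an identity is exact by construction.

# Known limitations

* WHAM assumes uncorrelated samples (see above); no MBAR generalisation
  and no 2-D coordinates.
* The cycle model's elementary rates are a documented calibration, not
  measurements; conclusions that depend on the *ratio* regime (closing vs
  catalysis times) should be re-checked against user-supplied rates.
* The pKa model is a point charge in a uniform dielectric.
* The PDB reader handles text ATOM/MODEL records (via bio3d) only; binary
  trajectory formats are out of scope.
* Hard-threshold state classification fragments dwells at realistic noise
  levels; dwell-time statistics from noisy traces are biased low unless
  filtered.
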