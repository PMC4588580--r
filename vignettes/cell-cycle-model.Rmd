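---
title: "A 25-species cell cycle oscillator and its signaling events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 25-species cell cycle oscillator and its signaling events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclephase)
```

## The model

`cyclephase` simulates a deterministic ODE model of the metazoan cell cycle
built around the three essential cyclin/Cdk modules: CycE/Cdk2 (CDKE) driving
G1/S, CycA/Cdk1 (CDKA) driving S, and CycB/Cdk1 (CDKB) driving G2/M. Around
this core sit the positive and negative E2F transcription factors (E2F1, and
E2F2 acting in complex with the Cdk inhibitor Dacapo as DapE2F2), the
Rb–E2F1 restriction-point switch, the Cdk inhibitors Dacapo (Dap, targeting
CDKE) and Roughex (Rux, targeting CDKA), the Cdk1-activating phosphatase
String (Stgi/Stga) and inhibitory kinase Wee, the Polo-like kinase Plx, and
the proteolysis machinery: the SCF ligase Skp2 and the anaphase-promoting
complex with its Fzy and Fzr adaptors (APCFzy, APCFzr). Twenty-five species
are tracked; the free Cdk1 and Cdk2 pools are explicit state variables whose
equations consist solely of binding/unbinding/destruction bookkeeping, so
each total is conserved exactly (to machine precision, which the tests
check). Phosphorylated Rb is carried as the conserved remainder of a fixed
Rb total.

Kinetics follow three conventions:

* **Two-state proteins.** Active/inactive forms (Stgi/Stga, CDKBi/CDKBa) are
  discrete states connected by switch-like conversions; multisite
  phosphorylation is not modeled.
* **Hill-gated modification.** The modification of a protein depends
  nonlinearly on its modifiers and linearly on itself: every regulated flux
  has the form `rate * Hill(modifier) * substrate`, with activating gates
  `x^n/(a^n + x^n)` and repressive gates `r^n/(r^n + x^n)`. The Hill
  exponent is 6 throughout, except the Rb auto-dephosphorylation return
  flux, whose exponent is a separate configurable value defaulting to 1
  (the model states only that this process is the exception; a
  Michaelis-type return is the mildest choice).
* **Mass action.** Complex formation and dissociation are bilinear/linear
  (`k * A * B`, `kk * C`).

Concentrations are dimensionless on a 0–1 display scale and time is in model
units; no mapping to hours is implied. Parameters fall into eight groups —
synthesis `s`, decay `d`, ubiquitination `u`, (de)phosphorylation `p`,
binding `k`, unbinding `kk`, and the half-maximal activation `a` and
repression `r` coefficients of the Hill gates.

The equations are not hard-coded: the configuration file
(`inst/extdata/default_model.yaml`) lists species, the 47 numbered
interaction links, and the flux list mechanically expanded from them, so a
reader holding a different term list can enter it verbatim and the engine
will integrate it. Fluxes not attributable to a numbered link (basal
synthesis, decay, the Rb return flux) carry a `note:` field flagging them as
reconstruction choices.

## Growth factor and the restriction point

The growth factor GF enters only CycE synthesis, multiplicatively:
`dCycE/dt` contains `s_CycEb * GF` (basal) plus
`s_CycE * GF * Ha(E2F1, a_E2F1CycE)`. With GF high, basal CycE slowly forms
CDKE against the Dacapo sink; once CDKE crosses `a_CDKERb` it inactivates Rb,
freeing E2F1 from RbE2F1, and E2F1 self-activation ignites the G1/S switch.
Because free E2F1 is held down by Rb sequestration and DapE2F2 repression
until that ignition, graded GF inputs convert into all-or-none E2F1
responses: below GF ≈ 0.1–0.2 the model rests, above ≈ 0.5 it cycles, and in
an intermediate band the attractor depends on history (the tests locate a
band near GF ≈ 0.3–0.4 where a resting start and a post-ignition start
settle into different E2F1 states).

## Signaling events, phases and classification

An event `Source_Verb_Target` (Verb ∈ Act/Rep/Ubi) is *active* exactly while
the source concentration exceeds the half-maximal coefficient of the Hill
gate through which it acts; 38 events are defined on links 3–47. Crossing
times are located by linear interpolation between accepted integrator steps,
with event starts at the upward crossing and stops at the downward one;
activations shorter than 0.1% of the cycle period are discarded as
interpolation chatter near tangencies.

Phase boundaries follow the event-edge convention: G1 starts at the stop of
`CDKBa_Ubi_E2F1`; S at the stop of `DapE2F2_Rep_CycA` together with the
start of `E2F1_Act_CycA` (implemented as the later of the two); G2 at the
start of `Stga_Rep_CDKBi`; M at the start of `APCFzy_Ubi_CDKBi` /
`APCFzy_Ubi_CDKBa` (the earlier). Only the two aggregates G1S (G1 start to
G2 start) and G2M (G2 start to the next G1 start) are reported, and their
fractions sum to 1 by construction.

Runs are classified 0/1/2: no sustained oscillation; oscillation with some
event absent, persistent, or multiple per cycle; all events exactly once per
cycle. Numerical choices the classification needs that have no single
canonical value:

* transient discard: the first 3 cycles (or the first 25% of the horizon
  when cycles cannot be delimited);
* oscillation criterion for class 0: peak-to-trough CDKBa amplitude below
  0.05 on the 0–1 scale, or fewer than two complete cycles;
* cycles for event counting are delimited by upward mid-range crossings of
  CDKBa, which keeps classification defined even when phase-marker events
  are themselves aberrant;
* "persistent" means active across one entire cycle (not necessarily the
  whole run); the per-event detail table reports which failure mode
  occurred.

## The integrator

The solver is an adaptive second-order Runge–Kutta (explicit midpoint)
method with step-doubling error estimation: each step is computed once at
`h` and twice at `h/2`, and accepted only if every component satisfies the
mixed criterion `|err_i| <= relerr * |y_i| + abserr` with
`relerr = abserr = 1e-5` by default. Rejected steps halve `h`; after two
consecutive acceptances `h` doubles, up to `h_max`. `h_max` defaults to 0.05
time units — under 0.5% of the default cycle period — so threshold crossings
are well resolved by the linear dense output. Because `h` moves on a
power-of-two grid, the terminal error decreases in notches rather than
continuously; the convergence test therefore compares errors across
eight-fold tolerance cuts. The stepper is deterministic, reports
accepted/rejected step counts, aborts with a stiffness error if persistent
rejection pushes `h` below `h_min`, and names the offending component when a
derivative becomes non-finite. On the full model it agrees with a
`deSolve::lsoda` reference at tolerance 1e-9 to within 1e-3 per species over
a full period (tested).

## Calibration of the default parameter set

The shipped parameter values were calibrated, in the order the model's own
logic suggests, to produce (i) oscillating concentrations, (ii) all 38
events periodic, and (iii) a G1-dominant phase split: the G1/S aggregate is
8.10 and G2/M 3.05 model-time units (72.7%/27.3% of an 11.15-unit period),
with every half-maximal coefficient placed inside the swing of the species
it watches so that each event occurs once per cycle. Conventional anchors:
the synthesis rates of the constitutive regulators Dap, Rux and Wee are 1.0
so that published perturbations expressed as absolute values (1.05, 1.8,
0.0) keep their meaning; `a_CDKAE2F1 = 0.14` as stated for the default
condition. The G1 clock is a titration race — basal CycE influx against the
Dacapo sink, with E2F2 accumulation gradually diverting Dacapo into DapE2F2
— which makes G1 length strongly and asymmetrically sensitive to `s_Dap`, as
the compensation experiment requires. The G2/M clock is the String/Wee
two-state switch plus the Plx–APCFzy relay.

Two behaviours of the published system were not reproduced at this
calibration and are left as documented differences rather than tuned
targets: lowering active-String decay to 0.3 lengthens M-phase activity but
does not lock the model into arrest, and halving `a_CDKAE2F1` truncates the
E2F1 pulse (shortening G2/M sharply) without abolishing the cycle. Both
arrests appear to require sitting closer to the oscillation boundary than
this calibration does; moving there degrades the default phase split and the
robustness of the event pattern, and we chose the split as the primary
anchor. The corresponding acceptance tests state the published outcomes and
fail informatively.

## Experiments

* `phaseCompensation()` — phase lengths/fractions under named perturbations.
* `arrestEscapeGrid()` — the 11-row arrest/escape grid; a single
  perturbation is Arrested/Not arrested by class 0 vs oscillating; a second
  perturbation on an arrested base is Escaped/Not escaped by whether cycling
  resumes.
* `robustnessScan()` — every one of the 38 event-governing `a_`/`r_`
  parameters increased and decreased by a fraction (default 66.6%,
  implemented as `p*(1±0.666)`; a `mode = "ratio"` flag gives `×(1+f)` and
  `÷(1+f)` instead, in case the multiplicative reading is wanted); failures
  are class-0 runs.
* `rescueExperiment()` — classification before/after adding a rescuing
  perturbation to a broken base.
* `bifurcationSweep()` — brute-force one-parameter sweep reporting class,
  period and amplitude per grid value (replacing continuation-based
  analysis, which is out of scope).
* `simulateSchedule()` — mid-run parameter switching with state carried
  across segments, for continuation-style experiments; the default
  experiment drivers apply perturbations at t = 0 of a fresh run.
* `rankEvents()` / `omnibusTest()` — the 0/0=1 … 2/2=6 unordered-pair rank
  map (mean rank across scans when several are given, the unstated
  aggregation choice), the event partition into critical/intermediate/robust,
  and a one-way F test over rank scores followed by Tamhane's T2
  (pairwise Welch t with Šidák correction). Rank scores are ordinal, so the
  F test is an omnibus screen and is flagged as such in its output.

Problem sizes: experiment drivers integrate to t = 250 (≈ 22 cycles,
≈ 18 analyzed after transient discard); a full three-scan campaign is
3 × 76 runs and completes in about two minutes on one CPU.

## Fixtures: what they emulate and what they do not

`makeFixture()` builds the deterministic test inputs: a sine trajectory
whose closed-form threshold crossings ride along as metadata (the oracle for
event capture), a square-wave event trace with exact edges (the oracle for
order and phase arithmetic), and a three-species Hill-repression ring that
sustains a limit cycle (a minimal positive control for oscillation
detection). A five-species shared-kinase fixture in the test helpers checks
the competition property — loading the kinase pool with one cyclin lowers
the other complex. These fixtures exercise the machinery, not the biology:
passing them shows the event/phase/classification pipeline is correct on
inputs with known answers, and says nothing about how faithfully the default
parameterization matches any real cell. Conversely, the model itself is
deterministic and noise-free: robustness here means parameter-perturbation
robustness, not stochastic robustness.

## Known limitations

* The exact published right-hand sides and rate values are not available in
  the main text; the shipped flux list is a mechanical reconstruction from
  the 47-link interaction table under the stated conventions, and the
  parameter set is this package's own calibration. Quantities that depend
  sharply on the original values (the arrest grid's absolute thresholds,
  scan failure counts) differ; the calibrated model is noticeably more
  perturbation-robust than the published one (5 base-scan failures rather
  than 14).
* Association/dissociation links are not captured as events, matching the
  published convention; only Hill-gated links define events.
* No stochasticity, no compartments, no multisite phosphorylation, no
  continuation-based bifurcation analysis.
* SBML export is not provided; the YAML configuration is the interchange
  format.

## A worked run

```{r, eval = FALSE}
model <- defaultModel()
run <- analyzeRun(model, solverSettings(t_end = 250))
run
#> Run class: 2 (all events periodic)
#> Period: 11.15
#> Mean phase lengths over 18 cycles: G1S = 8.099, G2M = 3.048 (72.66% / 27.34%)

head(run$phases[, c("cycle", "g1s", "g2m", "total")])
eventOrder(run$events, run$phases$g1_start[3], run$phases$g1_start[4])
```
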