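---
title: "Modelling the menstrual cycle and minimising contraceptive doses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the menstrual cycle and minimising contraceptive doses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ovucycle)
```

## The model

`ovucycle` implements a 13-state delay differential equation model of the
hypothalamic-pituitary-ovarian axis over the human menstrual cycle.  Four
pituitary states track the synthesis, release and clearance of the
gonadotropins: the reserve pools `RP_LH` and `RP_FSH` (IU) and the blood
concentrations `LH` and `FSH` (IU/L).  Nine ovarian states track the mass
(ng) of active follicular/luteal tissue through the stages recruited
(`RcF`), growing (`GrF`), dominant (`DomF`), ovulatory (`Sc1`, `Sc2`) and
four luteal stages (`Lut1`-`Lut4`).  The ovarian steroids and inhibin are
assumed at quasi-steady state, so estradiol (E2, pg/mL), progesterone
(P4, ng/mL) and inhibin (Inh, IU/mL) are linear combinations of the
secreting stage masses plus any exogenous contribution:

$$E_2 = e_0 + e_1\,GrF + e_2\,DomF + e_3\,Lut_4 + b_1\,E_{2,exo},$$
$$P_4 = p_0 + p_1\,Lut_3 + p_2\,Lut_4 + b_2\,P_{4,exo},$$
$$Inh = h_0 + h_1\,DomF + h_2\,Lut_2 + h_3\,Lut_3.$$

The couplings $b_1 = b_2 = 1$ by default: exogenous hormone is assumed to
act like its endogenous counterpart on the axis.

The feedback structure produces a relaxation oscillation.  LH synthesis
responds to E2 through an order-8 Hill function with threshold `Km_LH`;
as the growing follicle raises E2 past the threshold, LH synthesis
switches on, the accumulated reserve pool discharges, and the LH surge
triggers ovulation (the LH-gated transfers $c_2 LH^{\alpha} RcF$,
$c_3 LH\, GrF$, $c_4 LH^{\gamma} DomF$ flush the follicular mass into the
luteal chain).  The luteal stages decay at first-order rates
(`d1`,`d2`,`k1`..`k4`, around 0.7/day), generating the late luteal P4 and
inhibin pulse, which suppresses gonadotropin synthesis — inhibin acts on
FSH synthesis with a delay `tau` — until luteolysis releases the brake
and the next wave is recruited.

Two inhibition terms carry the contraceptive mechanism of exogenous
progesterone: `P4/w` in the FSH synthesis denominator (suppressed FSH
biosynthesis) and `P4/q` in the follicular recruitment denominator
(direct suppression of follicular development).  Setting `w` and `q`
very large recovers the unmodified predecessor structure; the test suite
asserts this limit.  Exogenous estrogen acts through the release terms
(the $1 + c_{LH,E} E_2$ and squared $1 + c_{FSH,E} E_2$ denominators),
so sustained E2exo starves the follicles of FSH.

All units are fixed package-wide: E2 pg/mL, P4 ng/mL, Inh IU/mL, LH and
FSH IU/L, masses ng, time days.

## Numerical treatment

Integration uses `deSolve::dede`, whose variable-step BDF/Adams solver
keeps a continuously interpolated history — the delayed inhibin is
evaluated by applying the inhibin map to the interpolated state at
$t-\tau$, not by adding a delayed state variable.  The history before
the start time is the supplied initial state held constant.  The
production right-hand side is compiled C; a pure-R transcription of the
same equations ships alongside it and the two are cross-checked against
each other in the tests (dual transcription).  Default tolerances are
`rtol = 1e-8`, `atol = 1e-10`; halving them moves hormone values by less
than $10^{-4}$ relative (asserted in the tests).  States are clamped at
zero inside the right-hand side to guard against tiny solver
undershoots; non-negativity over ten cycles is a test invariant.

Dose schedules are either constants or node sets joined by
`pracma::pchip`, a shape-preserving piecewise-cubic Hermite interpolant
(the same non-overshooting family as modified-Akima), clipped at zero.
The compiled solver receives controls sampled on a 0.05-day grid.

Peak detection fits a parabola through the three samples around each
local maximum.  An *LH surge* is a local LH maximum exceeding both 30
IU/L and three times the window's LH minimum; both settings are
arguments of `cycle_metrics()`.  The thresholds separate the normal
surge (order 100 IU/L) from suppressed profiles (order 10 IU/L) and are
deliberately far from both.  The period is the mean spacing of LH surge
maxima; without a surge it falls back to the spacing of dominant E2
maxima (above 60 % of the window's E2 range, so the smaller luteal E2
hump is ignored).  A window is classified **anovulatory** when the P4
maximum stays below 5 ng/mL *and* no LH surge occurs.  Under dosing,
metrics are evaluated over the 28-day treatment window starting at
day 0; untreated runs discard at least one settling cycle first.

## Calibration

`fit_staged()` implements a four-stage weighted least-squares procedure
against a daily 28-day hormone table repeated four times (repetition
pushes the fit toward a 28-day periodic solution):

1. **c1 (pituitary)** — E2, P4 and Inh are replaced by periodic cubic
   splines through the data; the LH and FSH blocks, now uncoupled
   two-state ODEs, are fitted separately to the LH and FSH series.
2. **c2 (ovarian)** — LH and FSH are forced by data splines; the
   stage-transfer constants are searched by Nelder-Mead while the
   secretion coefficients, which enter linearly, are profiled out at
   each step by weighted non-negative least squares.
3. **c3 (merged)** — the closed-loop model is refined against all five
   series with the `P4/w`, `P4/q` terms disabled.
4. **c4** — the inhibition scales `w`, `q` join the free set.

The objective is the dimensionless percentage-error form
$$\frac{1}{M-N}\sum_i \sum_H w_{H^*}(i)
  \left(\frac{H(i)-H^*(i)}{H^*(i)}\right)^2,$$
with $M$ residuals and $N$ free parameters plus initial conditions;
division by $H^*$ makes hormones with different units commensurate, and
$M-N$ keeps the cost from growing with data repetition.  Peak-day
observations carry their z-score weights (E2 1.58, P4 1.39, Inh 1.35,
LH 2.16, FSH 1.80) by default.

All searches run in log-parameter space, which enforces positivity
without constraints.  Three further choices matter and are worth
stating plainly:

* **Ridge penalty in log space** (`prior_penalty`, default 0.01): the
  release-rate/stimulation-coefficient directions are weakly identified,
  and unpenalised fits drift to degenerate compensating magnitudes
  (release constant to zero, stimulation coefficient to $10^{60}$) with
  no likelihood gain.  The penalty is small enough to leave identified
  parameters essentially untouched.
* **Settling** (`settle`): comparing the data against the first cycles
  from the initial condition rewards solutions that hug the data during
  the transient and then drift; with `settle = k` the model is first run
  for $k$ nominal cycles so the comparison probes the periodic solution.
* **Continuous-peak targets** (`peak_targets`): a daily grid contains a
  single sample of the one-day LH surge, so the plain objective is
  nearly blind to the surge height — automated fits either flatten it or
  let it spike off-grid.  Supplying target peak values adds a penalty on
  the continuous trajectory maxima.  This is the reproducible
  counterpart of the manual peak/period adjustment that conventionally
  follows automated fits of this model family, and is also exposed as
  the `peak_stage` re-weighting option.

## The reference parameter set and the synthetic dataset

The package ships a synthetic 28-day daily hormone table
(`inst/extdata/hormone_data_synthetic.csv`, loaded by
`synthetic_cycle_data()`).  It is a constructed stand-in for group-mean
clinical data, encoding the standard normal-cycle phenomenology: E2
rising through the follicular phase to a peak of 237 pg/mL on day 13, an
LH surge of 123 IU/L and FSH peak of 19.6 IU/L on day 14, and luteal
maxima of 11.5 IU/mL inhibin (day 20) and 17.9 ng/mL P4 (day 21), with
baselines and troughs at textbook levels.  What it does **not** emulate:
between-woman variability, assay noise (unless added via
`generate_dataset()`), cycle-length variation, and any real sampling
artefacts.  Tests that pass against this table demonstrate correct
mechanics of the pipeline, not clinical validity on real cohort data.

The shipped reference parameter set (`ref_params()`,
`inst/extdata/ref_params.yaml`) was produced by running the staged
calibration against that table, followed by a homotopy in the
progesterone-inhibition scales: inserting `w`, `q` at luteal-relevant
magnitude in one step destroys the oscillation (luteal $P_4/w$ of order
30 floors FSH synthesis), and a simplex search cannot recover a lost
limit cycle, so `w = q` was stepped down 60, 30, 15, 8, 5 with a full
merged refit at each step, then polished with peak targets.  The
resulting set yields a stable limit cycle with a period near 28 days,
single late-follicular E2/LH/FSH peaks, luteal P4/Inh peaks, and an
anovulatory response to sustained exogenous estrogen or progesterone.
Its initial state (`ref_init()`) lies on the orbit.

A property of the reference set worth knowing before interpreting dose
scans: its cycle-length response to the LH-synthesis threshold is
strong and clean (a 15 % shift of `Km_LH` moves the period by about
minus 1.2 / plus 1.1 days), and its progesterone response is as
designed, but its **constant-estrogen response saturates**.  In this
model family, steady-state blood FSH is structurally independent of
estradiol — E2 only inhibits *release*, and the reserve pool
re-accumulates until release again equals synthesis — so sustained
E2exo suppresses the LH surge yet leaves a weak-luteinization P4
plateau of 6–14 ng/mL across the standard 0–60 pg/mL/day range; the
anovulatory transition exists only near 200 pg/mL/day.  Where the
published model family places this transition near 35 pg/mL/day, that
position depends on parameter combinations (the distance to the
oscillation boundary) that daily normal-cycle hormone data do not
identify; calibration experiments that tried to move it (slow reserve
turnover, stronger release inhibition, dose-response targets) either
broke the normal cycle or collapsed the oscillation.  The package
reports the estrogen threshold as absent when no scanned dose is
anovulatory, and the scan tests assert the monotonicity and
self-consistency properties that hold regardless.

## Dosing experiments

`scan_monotherapy()` simulates one 28-day treated cycle per dose on the
standard grids (E2exo 0-60 pg/mL/day and P4exo 0-4 ng/mL/day, 0.1
steps).  `min_constant_dose()` refines the anovulation onset by
bisection to 0.01 dose units; because the criterion is the P4 maximum
crossing 5 ng/mL, the refined dose is operationally the constant dose
that lowers the P4 peak to just below 5.  The estrogen response is
monotone (more E2exo, lower P4 maximum); the progesterone response is
not — P4exo suppresses the endogenous cycle but itself adds to total P4,
so the anovulatory doses form a bounded interval and large doses raise
max P4 above 5 ng/mL again.  `contour_map()` maps the P4 maximum over
the combination grid, extracts k-level curves and fits a straight line
to the lower-left branch of the k = 5 curve (default: points with E2exo
below 30 pg/mL/day; the fitted range is reported with the slope, since
the boundary is only locally straight).

## Optimal dosing

`solve_oc()` minimises
$$J(u) = \int_0^{28} (P_4(t) - P_0)^2 + a_1 u_1(t) + a_2 u_2(t)^4\,dt$$
by control parameterization: 29 equally spaced nodes (daily; the count
is an argument) joined by the shape-preserving cubic, optimised by
L-BFGS-B with lower bound 0 and finite-difference gradients, from
multiple starts (zero controls, the constant anovulation-threshold
level, half that level).  The target $P_0 = 4$ ng/mL sits below the
anovulation threshold but close to it, since pushing P4 lower costs
disproportionate dose.  The quartic power on $u_2$ is the convexity- and
smoothness-promoting choice; both exponents are exposed as arguments but
only (1, 4) is exercised by the tests.  The weights default to
$a_1 = 0.4$ (estrogen and combination) and $a_2 = 0.07$ (progesterone
monotherapy) or $0.7$ (combination); $a_1$ is treated as a bare number
at face value against $u_1$ in pg/mL — the conventional dimensional
bookkeeping of the linear term is ambiguous and this package simply
documents the convention.  Dose totals (AUC) are composite-trapezoid
integrals over the horizon, reported on the concentration scale.

Whether the optimised schedule *saves* dose relative to constant
administration depends on where the minimal anovulatory constant dose
sits relative to the tracking target $P_0$: if the constant threshold
is above $P_0$ (as in the published parameterisation), tracking saves
dose; under the reference set the progesterone threshold (0.725
ng/mL/day) lies far below $P_0 = 4$, so the $J$-optimal schedule doses
*upward* toward the target and the AUC saving against that constant is
negative.  The invariant that holds either way — and is asserted in the
tests — is dominance in $J$: no constant anovulatory schedule has a
lower objective than the optimised one.

Local optimality is probed in the tests by perturbing single nodes;
results are local minima dependent on the starts, which is inherent to
the non-convex problem (the multi-start list is an argument).
`dose_savings()` compares each control's AUC with the minimal
anovulatory constant total (for combination therapy, via the two
cross-comparisons in which one control's AUC is spread constantly and
the partner's minimal constant co-dose is found by bisection).
`multi_cycle_redose()` re-applies the contiguous large-dose portion of
the optimised estrogen control (above 10 % of its peak) over a long
horizon, either at fixed intervals or triggered when E2 crosses a
biomarker level (default 75 pg/mL) from below; triggered scheduling
adapts to the drifting cycle phase, fixed scheduling does not.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script keep simulations at the
smallest sizes that exercise the claims: scans at full 0.1 resolution
(601 and 41 simulations), the contour on a 25 x 17 grid, optimal control
with 29 nodes and a capped iteration budget, and re-dosing over 280
days.  These sizes are the package's defaults for its own reproducible
report; all are arguments.

## Known limitations

* The reference parameter set is calibrated to a synthetic table; its
  quantitative outputs (thresholds, savings) characterise this
  parameterisation, not any clinical population.
* The staged fit is a local search; different starting values yield
  different (locally optimal) parameter sets.  Identifiability of the
  full 44-parameter set from five daily series is partial, hence the
  ridge penalty and the fixed distribution volume `v`.
* Optimal-control solutions are local and start-dependent; reported
  AUCs are upper bounds on the attainable minimum.
* No pharmacokinetics: doses are blood-concentration contributions, not
  drug amounts; coupling to a PK model is out of scope.
* Between- and within-woman variability is not modelled; `Km_LH`
  perturbation (`cycle_variants()`) is the supported mechanism for
  exploring cycle-length diversity.
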