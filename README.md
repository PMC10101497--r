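# ovucycle

Delay-differential modelling of the human menstrual cycle and optimal
contraceptive dosing, in R.

## The problem

Hormonal contraceptives induce **anovulation** — a cycle in which the
progesterone (P4) concentration stays below 5 ng/mL and no LH surge
occurs — but high doses of exogenous estrogen and progesterone carry
thrombotic and cardiovascular risk.  How small can the total dose be,
and when should it be given?  `ovucycle` is built for modellers studying
that question.  It implements:

* a 13-state delay differential equation model of the
  pituitary–ovarian axis (reserve pools and blood concentrations of LH
  and FSH; nine staged follicular/luteal masses; estradiol,
  progesterone and inhibin as quasi-steady linear combinations of the
  stage masses, with exogenous E2/P4 entering those combinations);
* staged weighted least-squares calibration against daily 28-day
  hormone tables;
* constant-dose anovulation scans, combination-therapy contour maps and
  threshold refinement;
* optimal time-varying dosing by control parameterization of the
  objective
  `J(u) = ∫ (P4(t) − P0)² + a1·u1(t) + a2·u2(t)⁴ dt`
  over piecewise-cubic node values (u1 = exogenous estradiol in pg/mL,
  u2 = exogenous progesterone in ng/mL, P0 = 4 ng/mL);
* biomarker-triggered multi-cycle re-dosing;
* a synthetic-data generator for parameter-recovery studies.

The pituitary block couples an order-8 Hill activation of LH synthesis
by estradiol (threshold `Km_LH`) with P4-inhibited synthesis and
E2-inhibited release; FSH synthesis is inhibited by inhibin delayed by
`tau` days and by P4 through the contraception-mechanism term `P4/w`,
with a second mechanism term `P4/q` inhibiting follicular recruitment.
See `vignette("cycle-model-methods")` for the full model and the
numerical choices.

## Worked example

```r
library(ovucycle)

## the calibrated reference parameterisation and its cycle-start state
p  <- ref_params()
y0 <- ref_init()

## simulate five cycles and summarise the settled normal cycle
sim <- simulate_cycle(p, init = y0, horizon = 140)
cycle_metrics(sim, settle_cycles = 2)
#> cycle metrics over [56.0, 140.0] days
#>   period: 28.00 days
#>   peaks:   E2 239.6 pg/mL, P4 18.08 ng/mL, Inh 11.48 IU/mL, LH 123.5 IU/L, FSH 20.3 IU/L
#>   LH surge: TRUE  | anovulatory: FALSE

## smallest constant progesterone dose that suppresses ovulation
min_constant_dose("progesterone", p, y0)
#> $dose
#> [1] 0.725
#> $total
#> [1] 20.3
#> $p4_max
#> [1] 4.988914
```

The period and hormone peaks are the package's reproduction of the
textbook normal cycle (28-day length, late-follicular E2/LH/FSH peaks,
luteal P4/inhibin peaks).  The threshold result says: under this
parameterisation, a constant exogenous progesterone contribution of
0.725 ng/mL per day for 28 days (a total of 20.3 ng/mL) lowers the
cycle's P4 maximum to just below the 5 ng/mL anovulation criterion —
and `scan_monotherapy()` shows the anovulatory doses form a bounded
interval, because the administered progesterone itself raises total P4
back over the criterion at higher doses.  `solve_oc()` finds
time-varying schedules that hold P4 near a sub-threshold target, and
`dose_savings()` compares their total dose with the constant
thresholds.  The constant-estrogen scan reports no anovulatory dose in
the standard 0–60 pg/mL/day range for this parameterisation; the
methods vignette explains the mechanism behind that saturation.

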