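---
title: "Model and methods: melanoma microsimulation in melscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: melanoma microsimulation in melscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melscreen)
```

## What the model is

`melscreen` is a continuous-time, discrete-event microsimulation of
cutaneous melanoma over individual lifetimes, built to compare
opportunistic skin checking (the status quo in Australia) with organised,
possibly risk-tailored, screening programmes. Each simulated individual
enters the model at exact age 15 in a *well* state and is followed until
melanoma-specific death, other-cause death, or age 85, whichever comes
first. Competing events are handled by sampling each candidate event
time from its own hazard by exact inversion of the cumulative hazard and
selecting the earliest; exact ties are broken by a fixed priority in
which death outranks diagnosis, so a same-instant diagnosis never
post-dates death.

The disease process has deliberately few explicit states. A first
primary melanoma *emerges* (becomes detectable) with a hazard

> baseline(age, sex) x cohort(birth year) x relative risk,

where the baseline is piecewise-constant over 5-year age bands, the
birth-cohort multiplier is flat at 1 for cohorts born up to 1972,
declines linearly to a floor (0.65 by default) at 1992 and is constant
thereafter — mirroring the lower lifetime UV exposure of cohorts who
grew up after sun-protection campaigns began — and the relative risk is
a lifetime risk-group multiplier fixed at entry. While a tumour remains
undiagnosed there are **no explicit stage states**: progression is
implicit, with stage at diagnosis a pure, non-decreasing function of the
tumour's histological subtype and its dwell (sojourn) time. A dwell of
zero maps to in situ disease (ICD-O-3 behaviour code 2); the default
schedules have nodular melanoma reaching stage IV after a 0.5-year dwell
and lentigo maligna after 20 years, with superficial spreading and
"other" in between. Within stages I–II, dwell cutpoints map to a
categorical Breslow thickness (≤1 mm, 1–4 mm, >4 mm); thickness is
categorical because survival depends on it but no continuous growth law
is part of the model.

Detection factorises into *attendance* (being seen) and *detection* (the
clinician recognising the lesion). Attendance comes through four
channels: background opportunistic clinician visits (a Poisson process
whose rate rises after emergence with the tumour's *progression* — the
fraction of its histology's dwell-to-stage-IV span already elapsed — so
a nodular melanoma prompts symptomatic presentation within months while
a lentigo maligna takes years; this histology-dependent clinical
surfacing is what lets screening over-sample slow-growing tumours),
routine skin checks (a one-off uptake event whose hazard
grows with calendar year, followed by annual scheduled checks thinned by
exponentially decaying compliance), organised screening rounds (fixed
calendar times, thinned by participation, gated by age range and
optionally risk group), and post-diagnosis surveillance (six-monthly for
higher-stage or high-risk patients, annual otherwise, to age 85, with
compliance decaying in time since diagnosis). Per-check detection
probability is the product of a histology-specific dwell curve (rising
for superficial spreading and lentigo maligna, flat for nodular, whose
vertical growth makes early visual detection no easier with time), a
two-level body-site visibility factor, a bounded calendar-period ramp
standing in for the dermoscopy-era improvement in diagnostic technology,
and — for organised rounds only — the programme's test sensitivity. At
attended checks of melanoma-free skin a false positive occurs with one
minus the channel's specificity; false positives carry a workup cost but
do not change state or behaviour (the behavioural consequence of a false
positive is real but unquantified, so we leave it out rather than invent
a magnitude).

Screening and routine checks are available **only before the first
diagnosis**; surveillance only after. Because of this gating, every
tumour detected by an organised round is a first primary — a fact the
overdiagnosis estimator relies on.

After a first diagnosis, subsequent primaries emerge with the
first-primary-style hazard scaled by a post-diagnosis multiplier that is
greater than one and non-decreasing in the number of previous primaries,
and by a histology factor (1 by default — the dependency is structural,
its magnitude unknown). The new primary shares the first's subtype with
probability equal to the concordance parameter (0.55 by default, >0.5 as
multiple-primary studies consistently find), otherwise it is drawn from
the marginal mix. Subsequent tumours progress under exactly the same
stage schedules as first tumours. There is no cap on the number of
primaries; a stress scenario in the fixture generator
(`high_risk_stress`) exercises histories with three or more.

Melanoma-specific death requires prior diagnosis and is driven by a
hazard that is piecewise-constant in time-since-diagnosis bands (0–1,
1–5, 5+ years — mimicking the shape of relative-survival curves without
a parametric commitment), indexed by stage at diagnosis and, within
stages I–II, Breslow category. The total hazard for an individual is the
**sum over all diagnosed invasive tumours** — there is no
count-dependent term, so having more primaries worsens survival only
through the tumours themselves. In situ disease carries no
melanoma-specific death hazard. The model honours the undiagnosed-tumour
death pathway indirectly: an undiagnosed tumour keeps progressing, so
late diagnosis occurs at high stage with a high death hazard.
Other-cause mortality comes from a sex- and age-banded life table.

## Random numbers and paired comparison

Every individual owns independent random substreams, one per event
channel, derived deterministically from `(root seed, individual id,
channel)`. Cohorts are therefore reproducible, invariant to execution
order, and a cohort split into halves reproduces the single run exactly.
Natural-history channels (first-primary emergence, tumour attributes,
other-cause death, skin-check uptake) are separate from policy-side
channels, so when two policies are compared under the same seed the same
first tumours emerge at the same ages with the same histologies and the
same other-cause death times — common random numbers. Subsequent
primaries are conditioned on the previous diagnosis (their hazard clock
starts at the previous diagnosis age, as the diagnosed-to-undiagnosed
transition requires), so their timing legitimately differs across
policies; the common-random-numbers guarantee applies to first-primary
natural history and other-cause death, which is exactly what the
overdiagnosis estimator needs.

Overdiagnosis is estimated by counterfactual pairing: a screen-detected
tumour is overdiagnosed if, in the paired unscreened history of the same
individual, that tumour is never clinically diagnosed before exit. No
consensus operational definition exists; this counterfactual definition
is our choice and is stated as such.

## Economics

Costs accrue at event times and are discounted continuously on an annual
base, `1/(1+r)^t`, with `r = 0.05` per year by default; life years and
QALYs are integrated over state occupancy (utility 1 in the well state,
stage-specific weights after diagnosis, using the worst stage diagnosed
so far) under the same discounting. Continuous discounting at event
times was chosen over annual-cycle bucketing because the engine is
continuous-time. Every skin check, in any channel, carries a
keratinocyte-cancer/benign-lesion adjunct cost, reflecting that checks
find and treat non-melanoma lesions even though those are not simulated
explicitly. Diagnosis triggers an excision cost plus stage-specific
initial treatment, and a continuing stage-specific annual cost for five
years. The decision metrics are the ICER per life year and per QALY and
the net monetary benefit at a willingness-to-pay of AUD 50,000 per QALY
(the conventional Australian health-technology-assessment settings).
Budget impact is reported undiscounted per calendar year over a 5-year
horizon (the standard convention; screening and diagnosis costs fall in
the calendar year of the event). The discounting reference time is
cohort entry.

## Calibration

The simulator's likelihood is intractable, so "Bayesian synthesis"
calibration is implemented as ABC-SMC: particles sampled from priors,
then resampled, perturbed with a Gaussian kernel (variance twice the
weighted empirical variance) and accepted when the weighted squared
relative error between simulated registry-style summaries (incidence and
melanoma mortality per 100,000 person-years by age band and sex, the
10-year second-primary proportion, the stage distribution) and the
targets falls below a threshold set at the median accepted distance of
the previous generation. Weights follow the standard prior/kernel
importance ratio. Any parameter path can be given a prior; the split
between calibrated and fixed parameters is configuration, not code.
Probabilistic sensitivity analysis re-simulates a policy pair under
common random numbers for each posterior draw and reports the
cost-effectiveness acceptability fraction.

## The synthetic fixture and what it does (and does not) show

No restricted Australian registry, Medicare, QSkin or survey data enters
the package. The `australia_like` fixture is a synthetic parameter set
whose age/sex gradients, birth-cohort decline, histology mix shifting
toward lentigo maligna with age, and cost/utility magnitudes are chosen
to be realistic in shape and order of magnitude for an Australian-like
population. One quantity is calibrated rather than merely plausible: the
post-diagnosis risk multipliers (6.0, 7.5, 9.0, 10.5 for 1–4+ previous
primaries) were fixed by a one-dimensional calibration sweep of the
simulated 10-year second-primary proportion against the ~16% figure
reported nationally, averaging several seeds at cohort size 50,000, and
then frozen. Fixture bundles are self-consistent: their calibration targets
are produced by simulating the bundled parameters, so calibration tests
have a known generating truth.

Passing tests on this fixture demonstrate that the machinery — competing
risks, implicit progression, channel gating, common random numbers,
calibration, economics — behaves as specified. They do not demonstrate
that the parameter values reproduce Australian registry data; fitting to
real data is precisely the calibration exercise the platform exists to
support.

## Numerical choices and problem sizes

Hazard inversion is exact (no time discretisation); piecewise-constant
hazards over 5-year age bands admit closed-form inversion. Check
processes are generated by thinning against the channel's maximal rate.
Ties in event times are resolved by the documented priority. Degenerate
inputs are handled explicitly: zero hazards yield "never" (`Inf`), empty
strata yield missing (not zero) rates, in situ tumours contribute zero
death hazard, and an ICER with zero incremental effect is flagged
undefined while the net monetary benefit is still reported.

Test and example problem sizes are chosen so the whole suite runs on a
single CPU in minutes: 10^4 individuals for structural and gating scans,
10^5 for the epidemiological anchor and survival ordering, 2×10^5 draws
for sampling oracles, and a deliberately reduced ABC budget (10
particles, 2 generations, 250 individuals per evaluation, 20 repeats)
for the coverage check. The per-run Monte-Carlo error at these sizes is
accounted for in the assertions (three standard errors unless a wider
stated tolerance applies).

## Known limitations

Body-site visibility and the histology factor for subsequent primaries
are structural placeholders (two levels and 1, respectively); melanoma
of unknown primary is not modelled beyond its ICD-O-3 label; there is no
emigration or censoring other than death and the age cap; treatment
effects of modern adjuvant therapy enter only through the survival
profiles; programme invitation costs attach to attended rounds (per
attendee) rather than to a separately modelled invitation process; and
value-of-information analysis is out of scope.
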