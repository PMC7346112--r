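---
title: "Methods: qNMR monitoring of oil oxidation with oxinmr"
author: "oxinmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qNMR monitoring of oil oxidation with oxinmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxinmr)
```

## The problem

When an edible oil rich in omega-6 polyunsaturated acyl groups is held under
mild oxidative conditions (70 °C with aeration, the accelerated-storage
regime), its linoleic chains degrade through a cascade of oxylipins:
monohydroperoxy conjugated dienes first, then dihydroperoxides,
hydroperoxy-/hydroxy-/keto-epoxy-monoenes, keto dienes, epoxy-monoenes,
aldehydes of several families, formic acid, and finally the poly-formate,
poly-ether and poly-hydroxy structures that polymerise the sample. ¹H NMR
can follow all of this in a single untargeted acquisition, because every
compound class has at least one proton whose chemical shift is (nearly)
specific to it, and because with full relaxation every proton contributes
the same area per mole.

`oxinmr` packages that workflow: a machine-readable assignment catalogue, a
window-integration quantifier with an internal reference and ordered overlap
subtractions, a stage-wise kinetics layer, and a synthetic-spectrum
generator so the whole chain is testable without an instrument.

## The quantification model

Concentrations are expressed in mmol per mol of triglyceride (mmol/mol TG).
With `A_X` the integrated area of the signal chosen for compound class X,
`n` the number of protons generating that signal, and `A_TG` the area of the
4 glyceryl *sn*-1/*sn*-3 protons of the triglyceride backbone,

```
[X] = (A_X / n) / (A_TG / 4) * 1000
```

(`eq1_concentration()`). The backbone works as an internal reference because
triglyceride hydrolysis is negligible under these conditions. The formula
assumes (i) areas proportional to proton counts with a single
proportionality constant — guaranteed by full relaxation, and enforced by
construction in the synthetic generator — and (ii) that the integrated
window contains only the protons attributed to it; deviations from (ii) are
handled by the corrections mechanism below, or are part of the error budget.

The reference is described as one catalogue row with two sub-windows
(4.10–4.18 and 4.26–4.34 ppm, 2 protons each) whose areas are summed. This
keeps the reference quantifiable late in oxidation, when methine carbinol
interlopers appear near 4.23–4.25 ppm *between* the two multiplets; those
interlopers are catalogued and listed in the reference's corrections so
that any window override that swallows them still subtracts them.

## The catalogue

One row per signal: center (ppm), closed integration window, proton count
`n`, multiplicity, role (`quantifier` / `reference` / `qualifier`), an
ordered corrections list, and provenance. Because the full instrument
integration table behind the study is not public, the packaged catalogue is
reconstructed from the shifts quoted in the running text and figure
captions; every entry's provenance field says whether its number is
`reported` (a quoted shift or window) or `assumed` (an editorial choice such
as an exact center inside a quoted range).

Window policy, where only a center is quoted: half-widths of 0.010–0.020 ppm
chosen channel by channel so that neighbouring quantifier windows never
overlap. The spectrum is crowded in places (7.47 vs 7.49 ppm for the
furanone and the *Z,E* keto-diene; 0.540/0.61/0.64/0.651 ppm for the sterol
methyls), which is why a uniform ±0.04 ppm default is not usable; the
`audit_collisions()` check proves the packaged windows are pairwise
disjoint up to declared corrections. Proton counts not derivable from the
text (composite signals such as the 3.24 ppm hydroxy-keto channel) are set
to `n = 1` and flagged `assumed_n` — explicit uncertainty instead of silent
invention.

## Overlap-subtraction corrections

Several windows are shared. The 2.88–2.98 ppm epoxide window of the
*Z*-epoxy-*Z*-monoenes also contains epoxydic protons of hydroxy- and
keto-epoxy-monoenes; the broad 3.38–3.46 ppm dihydroxy band contains a
hydroxy-epoxide dd at 3.41 ppm; the broad 8.3–9.3 ppm hydroperoxide window
contains the 2,3-epoxyalkanal CHO at 9.01 ppm. In each case the contributor
is quantified first on a clean channel of its own, its predicted area in
the shared window (`concentration × protons-in-window × A_TG/4 / 1000`) is
subtracted, and only then is the shared window converted to a
concentration. The corrections lists form a directed acyclic graph over
signals; `apply_corrections()` processes them in topological order. A
subtraction that overshoots (near-equal areas under noise) clamps the
corrected area to zero and sets a flag rather than failing.

The total-hydroperoxide channel is *derived*: it is quantified from its own
window but never rendered by the generator, so its area arises entirely
from the OOH qualifier protons of the hydroperoxide-bearing classes. Until
other OOH carriers appear (day 9) the narrow 8.38–8.52 ppm window is used,
afterwards the broad 8.3–9.3 ppm one; the switch day is configurable.

## The synthetic-data generator

`render_spectrum()` draws every catalogued signal of every compound with a
nonzero concentration as a Lorentzian with analytic area
`area_scale × concentration × n / 1000`, the reference always at
1000 mmol/mol TG. That makes proportionality — the assumption behind the
quantification formula — true by construction, so `quantify ∘ render`
should be the identity up to integration error; this is the package's
central test property.

Defaults, chosen once:

* **Grid** 0–10 ppm, step 3.125×10⁻⁵ ppm (320 001 points), at least four
  points per linewidth.
* **Linewidth** fwhm 1.25×10⁻⁴ ppm (0.05 Hz at 400 MHz). This is
  deliberately much narrower than a real oil spectrum (≈1 Hz). The reason
  is structural: the quantifier integrates fixed windows with no lineshape
  fitting, so a window of half-width `w` captures only the fraction
  `(2/π)·atan(2w/fwhm)` of a Lorentzian's mass. At a realistic 1 Hz
  linewidth the narrow windows forced by the crowded shift list would
  capture ~96 % against ~99.8 % for the wide reference windows — a
  systematic −3 to −4 % on every narrow channel, plus percent-level
  tail cross-talk between neighbours 0.02–0.04 ppm apart. The narrow
  default keeps truncation mismatch and wing leakage below ~1 % so that
  integration fidelity, not lineshape realism, is what the round trip
  measures. Users simulating realistic linewidths can widen `fwhm` and
  should expect correspondingly larger systematic recovery errors.
* **Wing-leakage floor.** Even at the narrow default, channels a few
  hundredths of a ppm from a vastly larger neighbour inherit an absolute
  offset from its Lorentzian wings. The dominant case is the bis-allylic
  linoleic signal at 2.77 ppm (up to 1461.6 mmol/mol TG × 2 H) next to the
  epoxy-monoene windows at 2.66–2.73 and 2.88–2.98 ppm: its wings
  contribute the equivalent of ~0.1–0.5 mmol/mol TG there while linoleic
  is still abundant. The round-trip tests therefore assert 2 % relative
  accuracy *above* a 0.4 mmol/mol TG floor, and the two affected epoxide
  channels carry raised per-signal detection limits (0.4 and
  0.8 mmol/mol TG) so that they do not report phantom epoxides at day 0 —
  mirroring the real situation, where those signals only become readable
  once the substrate is substantially degraded.
* **Noise** additive Gaussian, default off; seeded, so identical seeds give
  bit-identical spectra. Duplicate tables with independent noise emulate
  the study design of duplicate determinations.
* **No J-splitting** by default (an optional cosmetic symmetric doublet
  split exists): only areas matter to the quantifier. No baseline or phase
  artefacts, no solvent peak, no ¹³C satellites.

What the generator does *not* emulate — rolling baselines, phase errors,
multiplet fine structure, the hundreds of uncatalogued signals of a real
oil — bounds what passing tests show: they validate the bookkeeping
(integration, referencing, subtraction order, kinetics), not robustness to
instrumental artefacts.

## The trajectory fixture

`packaged_fixture()` carries (day, concentration) anchors per compound over
days 0–16, interpolated piecewise linearly by `make_timecourse()`; a
compound is zero before its first anchor (its appearance day). Anchor
status is `reported` (a printed concentration), `derived` (computed from a
printed rate), or `assumed`. Piecewise-linear interpolation is used
because the study's kinetic language is stage rates per day; no sigmoid or
mechanistic model is fitted. Inter-anchor behaviour and the day-16 values
of classes whose endpoint was never printed are modelling choices — in
particular the six unprinted aldehyde endpoints were chosen so that all
eight classes sum to the printed ≈69 mmol/mol TG total. Where only a
maximum is known, the trailing anchor repeats the last value.

Acyl classes other than linoleic (oleic, saturated, linolenic) carry
anchors but no spectral channel: their clean determination requires
combining several heavily overlapped regions, which is out of scope here;
they participate in composition arithmetic (`percent_to_mmol()`, the
day-0 sum of 3000 mmol/mol TG for three chains per TG) but not in the
spectral round trip.

## Detection limits

The study quotes no numeric LOD, so the package default (0.1 mmol/mol TG)
was set just below the smallest concentration it reports as detected
(0.14 mmol/mol TG for the 5β,6β-epoxysterols), keeping every reported
appearance day reproducible. It is configurable globally and per signal
(`lod_override`, used for the two epoxide channels discussed above).
Concentrations below the effective limit are reported as 0 with a
`below_lod` flag, which is what gives "appearance day" its operational
meaning.

## Kinetics

`stage_rates()` fits an ordinary least-squares slope per stage; the default
breakpoints `c(0, 8, 11, 14, 16)` partition the course into the four
regimes of linoleic degradation, and γ-tocopherol uses its own two-stage
scheme `c(0, 2, 11)`. A shared breakpoint day belongs to both adjacent
stages, matching the inclusive "from day 8 to day 11" phrasing. Rates are
signed (negative = degradation). On the exactly piecewise-linear fixture
the OLS slopes equal the segment slopes; under 2 % concentration noise the
steepest linoleic rate is recovered within 10 % in essentially all seeds.

`formation_fraction()` divides a product's stage rate by the absolute
substrate rate: over days 8–11 the two hydroperoxide isomer rates
(4.7 + 15.1 = 19.8 mmol/mol TG per day) against linoleic's −28.9 give
68.5 %, leaving ≥31.5 % of the degraded substrate in other products. The
analogous days 11–13 fraction is *not* exactly reconstructible from the
printed anchors (the printed 18 % does not follow from the printed
endpoint values); the package computes the analogous quantity and leaves
the discrepancy documented rather than forcing agreement. Similarly, the
fixture anchors day 16 of linoleic at the printed 291.2 mmol/mol TG, which
makes the computed last-stage rate −126.4 rather than the printed −123.7
(2 %); the printed numbers are not jointly consistent under a
piecewise-linear model, and the concentration anchor was given precedence.

`detect_events()` reports the first sampled day above the LOD, the day and
value of the maximum (ties to the earliest day), and the first day after
appearance back at or below the LOD.

## Numerical choices

* Integration: trapezoid on the native grid (the instrument-software rule
  is unspecified); error is controlled by grid density and checked against
  the closed-form Lorentzian mass `(2/π)·atan(2w/fwhm)`.
* Negative corrected areas clamp to 0 with a flag.
* The reference has a configurable floor (`a_tg_floor`); below it the run
  stops with a "reference lost" error instead of dividing by ~0.
* Windows are closed intervals on a descending-by-convention ppm axis;
  internally the trace is sorted ascending before integration.
* Test and acceptance problem sizes: 17 days × one replicate for the
  noise-free round trip, 320 001-point grids, 50 seeds for the stochastic
  rate-recovery property, 4 seed pairs for the replicate-averaging check —
  sizes chosen to exercise every code path while keeping a full run in
  minutes on one CPU.

## Known limitations

* The catalogue is a reconstruction; exact instrument integration limits
  and several proton counts are declared assumptions (flagged in the
  files), so absolute agreement with the original instrument workup is not
  claimed beyond the printed anchor values.
* Quantification is window bookkeeping: no deconvolution, so heavily
  overlapped real signals (the 3.3–4.1 ppm carbinol region at late days)
  are only separable where a corrections chain exists.
* No absolute molar calibration against an external standard; everything
  is relative to the triglyceride backbone.
* The kinetics layer estimates slopes, not mechanisms: no radical
  rate-constant fitting, no ODE model.
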