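---
title: "IAP and lung mechanics during laparoscopy: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IAP and lung mechanics during laparoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaplung)
```

## The problem

CO₂ insufflation of the abdomen during laparoscopy raises the
intra-abdominal pressure (IAP) to a regulated plateau (typically
12–15 mmHg). The inflated abdomen loads the diaphragm and acts against
the ventilator's driving pressure, so the respiratory system's apparent
compliance falls. Under volume control (VCV) the ventilator defends the
set tidal volume and peak inspiratory pressure (PIP) rises; under
pressure control (PCV) it defends the set pressure P~ins,max~ and the
delivered tidal volume V~T~ falls. `iaplung` turns raw multi-device OR
streams — or synthetic ones with known ground truth — into per-breath
mechanics and per-subject correlation statistics of this coupling.

The quantity at the centre is the dynamic compliance per breath,

$$C_{dyn} = \frac{V_T}{PIP - PEEP} \quad [\mathrm{ml/mbar}],$$

computed entirely from measured waveform quantities: PIP is the maximum
airway pressure in the breath, PEEP the mean airway pressure over the
last 100 ms before the inspiration onset, and V~T~ the rise of the
displayed volume channel within the breath. The *set* PEEP enters only
as a regression predictor, never Eq.\ above — so a discrepancy between
set and achieved PEEP shows up as data, not as an artefact.

## The simulator's stated world

Clinical OR recordings are rarely shareable, so the package's
first-class data source is a simulator whose defaults encode the
documented clinical conditions.

**Lung model.** A single compartment with volume state $V$ above FRC:
$P_{aw} = PEEP_{set} + V/C_{eff}(t) + R_{aw} Q$, integrated by forward
Euler at 1 ms and resampled to the device-native rates (ventilator
waves 20 ms, insufflator 40 ms, settings 60 s). The IAP-compliance
coupling is phenomenological and linear with a floor:

$$C_{eff}(t) = \max\!\big(C_{min},\; C_0 - k\cdot IAP(t) + \Delta C_{repo}(t)\big).$$

No mechanism beyond monotone co-variation is claimed by the source
material, so none is modelled. $k$ is expressed in ml/mbar per mmHg of
IAP deliberately: the insufflator reports mmHg and the ventilator mbar,
Pearson and multiple correlation are invariant to affine rescaling, and
keeping device-native units means the statistical layer never converts
(1 mmHg = 1.333 mbar would only matter for a transmural-pressure
model, which is out of scope). Defaults: C₀ 35–55 ml/mbar, R~aw~
0.006–0.015 mbar·s/ml — adult anaesthetised ranges; k ≈ 1–1.3 ml/mbar
per mmHg puts the compliance drop at plateau IAP near 30%, the size of
drop anaesthesia texts report for pneumoperitoneum.

**Ventilator controller.** VCV delivers constant inspiratory flow
$Q = V_{T,target}/T_{insp}$ with $T_{insp} = (60/RR)\cdot IE/(1+IE)$
(the single-decimal I:E convention: 1:1.5 → 0.667 = T~insp~/T~exp~).
PCV drives airway pressure toward P~ins,max~, bidirectionally — excess
elastic recoil is vented, so an ideal PCV breath has PIP = P~ins,max~
exactly. Expiration is passive through R~aw~ (time constant
$R_{aw}C_{eff}$, floored at 50 ms so the $R_{aw}=0$ limit stays well
posed). The volume channel is the running integral of flow reset at
each inspiration onset, matching ventilator display convention.
Settings changes take effect at the next inspiration onset.

**The pressure-limited-from-below regime.** Clinically, some
pressure-controlled subjects show PIP *below* P~ins,max~ that tracks
IAP while V~T~ stays flat (typically after the anaesthesiologist raises
P~ins,max~ by a large step). A slew limit on the drive pressure cannot
produce this in a single-compartment model: a slew-limited drive makes
PIP = PEEP + slew·T~insp~, a constant independent of the load. What
does produce it is a limit on the ventilator's *flow capacity*: when
the cap $Q_{max}$ binds for the whole inspiration, $V_T = Q_{max}
T_{insp}$ is constant and $PIP = P_{alv} + R_{aw}Q_{max}$ rides on the
elastic load, hence on IAP. The profile therefore carries both a
`rise_rate_limit` (drive slew, mbar/s) and an `insp_flow_limit`
(ml/s); the `pcv_limited` preset uses the flow limit (225 ml/s, i.e.
13.5 l/min — a modest but plausible capacity) with a
P~ins,max~ schedule 18 → 32 → 38 mbar (+14 then +6). With the low
initial P~ins,max~ the pressure phase is reached and PIP clamps near
18 while V~T~ carries the IAP signal; after the raise the flow cap
binds and the regimes switch. One mechanism, both phases.

**IAP trajectory.** Zero before insufflation (gauge pressure),
first-order ramp (τ = 20–25 s — insufflators reach target within a
minute) to the plateau, Ornstein–Uhlenbeck fluctuations with
stationary s.d. σ = 0.3 mmHg and mean-reversion time 2 s (regulation
jitter small relative to the ~14 mmHg insufflation swing), optional
transient partial deflations (trocar changes; target drops to 30% of
plateau), first-order decay after deflation.

**Acquisition degradation.** Each device stream is rewritten onto a
relative clock running at $(1-CF_{true})\times$ the absolute rate
(injected skew 4.63·10⁻⁴ — the value the correction-factor definition
$CF = (\Delta t_{abs} - \Delta t_{rel})/\Delta t_{abs}$ gives for ~5 s
lost over 3 h), and samples are deleted at random (pipeline default
0.2%; every deletion is logged). Paired absolute/relative clock
observations every 5 minutes emulate the monitor's configuration
telegram. These observations are kept at float resolution: the real
absolute timestamp has 1 s resolution, and with 5-minute telegram
spacing that quantisation alone would bound end-of-stream realignment
near 0.2 s, not the sub-sample level the repair chain otherwise
achieves — a documented idealisation, not an accident.

**What the simulator does not emulate** — and hence what a green test
does *not* establish: cardiovascular coupling, gas exchange and CO₂
absorption, multi-compartment/viscoelastic lung behaviour, leaks,
spontaneous breathing efforts, vendor protocol artefacts, and the 1 s
absolute-clock quantisation above. Tests green against this world show
the *pipeline* is correct, not that the physiology is complete.

## The analysis chain, and its numerical choices

**Clock repair.** CF and offset are estimated by least squares over all
paired clock observations (reducing to the two-point definition when
only two exist), then applied multiplicatively:
$t_{corr} = offset + t_{rel}(1 + CF)$. Correcting with the true CF
leaves a residual of order $CF^2 T$ — 2.3 ms over 3 h, under half a
40 ms sample.

**Gap flagging.** Samples snap to the nominal grid only within half a
sampling interval; grid points with no sample become NaN. Nothing is
interpolated at this stage — silent resampling is how artefacts enter
pipelines. Breaths whose windows contain NaN are dropped, and counted.
The session's first breath is also dropped: PEEP needs a 100 ms
end-expiratory window *before* the onset, and measuring it at the onset
instead produced PIP ≈ PEEP outliers that destroyed per-subject r — a
single such breath moved r(C~dyn~, IAP) from −0.999 to −0.15.

**IAP filtering.** Kaiser-window linear-phase FIR: passband 40 mHz at
0.5 dB, stopband 80 mHz at 50 dB, 25 Hz rate (the published passband
and stopband edges coincide at 40 mHz, which no realisable filter
satisfies; one octave of transition keeps both attenuation figures as
printed). The designed response is verified against the spec on a dense
grid at design time and the design rejected if it misses. The tap count
(1833) is forced odd so the group delay (n−1)/2 is an integer number of
samples; the output is shifted back by exactly that delay, and edge
effects are handled by edge-value padding. NaN runs shorter than the
filter are bridged linearly before filtering; longer runs propagate.

**Breath segmentation.** Inspiration onsets are upward crossings of
+2 l/min on flow, with true hysteresis: after an onset, no new onset is
accepted until the flow has crossed −2 l/min (an expiration actually
happened). This matters in PCV, where inspiratory flow decays toward
zero and IAP-fluctuation-induced wiggles re-cross a naive threshold
mid-breath. Breaths shorter than 1 s or longer than 15 s are discarded
and counted.

**Settings.** Previous-value hold at each breath's inspiration onset —
settings are stepwise anaesthesiologist actions; linear interpolation
between a P~ins,max~ of 18 and one of 32 would manufacture pressures no
one ever set.

**Per-breath IAP.** The mean of the filtered IAP over the full breath
span; the alternative (IAP at the PIP instant) is a single-sample read
of a filtered signal and strictly noisier.

**Detrending.** For drifting pressure-limited subjects, an OLS line of
PIP against breath time is removed and the mean level restored.
Configuration-gated and off by default — detrending every subject would
remove real IAP-driven trends too.

**Statistics.** Observations are breaths. "C" is signed Pearson r with
the two-sided t-transform p; "MLR" is the multiple correlation
coefficient $R = \sqrt{R^2}$ of the OLS fit with intercept, p from the
overall F test. Group summaries average |r| (the source tables are
all-positive and the sign convention unstated; the per-subject output
keeps the sign, which is physiologic: negative for C~dyn~ and for V~T~
in PCV). V~T~-vs-IAP is not applicable under VCV — the controller holds
V~T~ at target, so the correlation is between noise and IAP; similarly
a response with literally zero variance (PIP under the *ideal* PCV
drive) degrades to not-applicable rather than erroring, a case real
ventilators never produce but the idealised simulator does. No
autocorrelation correction and no multiple-testing adjustment are
applied — breaths are serially correlated, so the p-values are
optimistic; they are reported raw as a known limitation, and the effect
sizes (r), not the p-values, carry the conclusions. Exclusions from
group summaries (e.g. a repositioned subject) are configuration-driven,
never automatic.

## Design choices where the design was open

* **Inspiratory V~T~** is used (max volume minus volume at onset), not
  expiratory: it is what the delivered-volume question asks about, and
  the display-volume reset convention makes it the well-defined one.
* **Sensor noise** (0.05 mbar s.d. on pressure, scaled on flow/volume)
  is on by default only in the orchestrated pipeline, off in direct
  simulator calls, so closed-form identity tests stay exact while
  cohort statistics see realistic measurement texture.
* **Repositioning** is modelled as a compliance step of +12 ml/mbar
  (~30% of C₀ — the order of reported position effects) active between
  toggle times (lithotomy → supine → back). It degrades |r(C~dyn~,
  IAP)| from ≈1.0 to ≈0.4 in the preset: the Subject-11-style
  confound, reproduced rather than fitted.
* **Determinism.** All randomness flows from integer seeds through a
  saved-and-restored RNG scope; identical profile + seed gives
  bit-identical sessions, and the pipeline writes byte-identical CSVs
  under a fixed config.

## Known limitations

Single compartment, linear elastance; no cardiogenic oscillations on
the waveforms; the MLR predictors enter linearly; p-values ignore
serial correlation of breaths; the synthetic clock telegrams are
noise-free; and the correlation design is associative — nothing here
estimates a causal IAP → mechanics transfer function.
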