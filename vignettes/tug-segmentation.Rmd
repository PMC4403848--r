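---
title: "Detecting and segmenting Timed-Up-and-Go activities from inertial sensors"
author: "tugseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and segmenting Timed-Up-and-Go activities from inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugseg)
```

# The problem

The Timed-Up-and-Go (TUG) is a clinical mobility task: the subject stands
up from a chair, walks a set distance (here 5 or 10 m), turns 180 degrees,
walks back, turns again, and sits down.  Four gross activities (Standing,
Walking, Turning, Sitting) performed continuously generate six segments —
Stand up, Walk-out, Turn 180, Walk-in, Turn 180, Sit down — separated by
seven transition points (sit-to-stand, stand-to-walk-out, walk-out-to-turn,
turn-to-walk-in, walk-in-to-turn, turn-to-stand, stand-to-sit).  `tugseg`
detects the activities and estimates the seven transition timestamps from
body-worn inertial sensors (tri-axial accelerometers and gyroscopes plus
fused orientation quaternions, sampled at 60 Hz), replacing the slow and
examiner-dependent practice of marking transitions by eye on an avatar
replay.

# The method

## Signal conditioning

Every channel is conditioned in a fixed order before any peak logic runs:

1. **Detrend** — the least-squares straight line over the whole trace is
   subtracted, removing slow sensor drift.  A mean-only correction would
   leave ramps that defeat extremum search, so the linear model is the
   minimal adequate one.
2. **Normalize** — division by the absolute maximum makes every channel
   unitless with peak amplitude 1, so the same peak thresholds apply to
   all subjects and channels.
3. **Ideal band-pass** — a brick-wall filter in the discrete Fourier
   domain: bins with $|f| \in [w_1, w_2]$ (inclusive) keep unit gain, all
   other bins are zeroed, and the real part of the inverse transform is
   returned.  No windowing or padding is applied; the filter is an exact
   projection (idempotent and linear) and the edge ringing that a
   brick-wall response implies is accepted.  The low cut is fixed at
   $w_1 = 0.0025$ Hz for every channel, which at trial lengths of 15–30 s
   removes only the DC bin and thereby centers the trace.  The high cut
   $w_2$ is channel- and transition-specific (below); the one exception is
   the walking channel, filtered up to the Nyquist frequency (30 Hz) so
   the stride oscillation survives.

Whether normalization precedes or follows filtering is a genuinely open
choice; `tugseg` fixes detrend → normalize → filter, and the conditioned-
trace invariants (max amplitude at most 1 before filtering, near-zero
mean) are defined under that order.

## Activity detection

Detection keys on the dominant kinematic peaks of specific channels:

* **Standing / Sitting** — major extrema of the trunk vertical
  acceleration ($a_z$, 1.57 Hz band).  The sign of the time derivative of
  the hip acceleration ($\dot a_y$) at the extremum disambiguates:
  positive while rising into upright (Standing), negative while lowering
  (Sitting).  An exactly-zero derivative falls back to a ±2-sample
  neighborhood mean and is an error if still zero.
* **Turning** — major extrema of the trunk yaw angular velocity
  ($\omega_y$, 1.0 Hz band), each verified by a same-sign head $\omega_y$
  extremum within ±0.5 s (head and trunk yaw are near-synchronous in a
  whole-body turn); unverified peaks are dropped, and the head peak's
  sign gives the turn direction.
* **Walking** — a 0.5 s window slides over the hip $\omega_x$ conditioned
  to the full 30 Hz band.  A window is walking-positive when its RMS
  exceeds 10% of the whole-trace RMS *and* the signal alternates at least
  twice between excursions above $+h$ and below $-h$ with $h$ = half the
  window RMS.  The hysteresis form of the zero-crossing count is this
  package's refinement: counting raw sign changes admits windows that
  straddle a pulse onset, where broadband noise supplies crossings and the
  ramp supplies RMS; requiring alternating half-RMS excursions accepts a
  genuine stride oscillation (~1–2 Hz) and rejects one-sided ramps and
  quiescent noise.
* **Precedence** — stepping continues through turns, so samples flagged
  both Walking and Turning are labeled Turning.  The turn's extent for
  this rule is the span between the first extrema left and right of the
  turn peak (the same rule segmentation uses), which covers the turn
  shoulders that the 30%-of-peak square indicator leaves out.

Square indicator signals at 30% of each event's peak amplitude are
emitted for inspection, as in the original protocol.

Major extrema are local extrema (strictly greater/smaller than both
neighbors; plateaus credited to their earliest sample, for determinism)
whose magnitude reaches 30% of the trace maximum, thinned so no two
survive within 2.0 s (the larger magnitude wins).  The separation radius
is wider than the 1 s one might first choose: the biomechanical
counter-movements that flank a stand, sit or turn (trunk dips before
seat-off, yaw reversals braketing a turn) produce sub-dominant extrema up
to ~1.7 s from the main peak, and they belong to the same event, not to a
new one.

## Segmentation: the first-extremum rule

Each transition is estimated per configured channel as follows: condition
the channel with its calibrated $w_2$; re-locate the governing activity
peak as the largest-magnitude sample within 1.5 s of the anchoring
detection event on the transition's side; then scan outward from the peak
— left for transitions entering the activity, right for leaving it — and
take the first local extremum of the opposite polarity (first minima
around a positive peak, first maxima around a negative one).  If the
trace boundary arrives first, the boundary time is returned but flagged,
and flagged candidates are dropped from the combination whenever any
channel produced an interior extremum (boundary times are artifacts of
trial cropping).  The transition estimate is the mean of the per-channel
candidates; averaging absorbs lead/lag between sensor sites.

The two turns are anchored at the two largest-magnitude Turning peaks in
time order, so a sub-dominant extremum can never masquerade as a turn.
The final two transitions are split between anchors: turn-to-stand is the
right bound of the second turn (its channels are the trunk/hip yaw
velocities), while stand-to-sit is the right bound of the Sitting peak on
the hip vertical acceleration.

## Channel combinations and calibrated cutoffs

The per-transition channel sets and high cutoffs encoded by
`defaultConfig()` (and listed by `defaultCutoffTable()`):

```{r}
defaultConfig()
```

The lateral angular-velocity table entries are interpreted as gyroscope
$\omega_y$ (overridable in a config file).  Turn-to-walk-in deliberately
uses the hip $\omega_y$ alone — the single channel that best matched the
reference segmentation — although the head $\omega_x$ at 0.41 Hz remains
in the cutoff table for calibration experiments.  The stand-to-walk-out
combination includes the left-knee range of motion, computed on the fly
from orientation quaternions (below).  All of these remain defaults, not
constraints: `loadConfig()` merges YAML overrides onto them.

## Knee range of motion from quaternions

Orientation quaternions are scalar-first $[w\; x\; y\; z]$ under the
Hamilton product.  For a joint spanned by segments 1 and 2 the relative
orientation is $q_{rel} = q_1^{-1} q_2$; its change against the reference
captured at trial start (the initial pose) is
$q_\Delta = q_{ref}^{-1} q_{rel}$, and the scalar joint angle is
$\theta = 2\arccos(|w_\Delta|)$ in degrees.  The absolute value on the
scalar part resolves the double cover ($q$ and $-q$ encode the same
rotation) and simultaneously enforces the small-angle (< 180°)
representation; successive $q_\Delta$ are hemisphere-aligned before angle
extraction so the trace is continuous.  Knee ROM is thigh vs. shin; hip
ROM is pelvis vs. thigh.

## Calibrating the high cutoffs

`optimizeW2()` reproduces the exhaustive-search calibration: for a given
channel and transition, the cost of a candidate $w_2$ is the sum over
trials of the squared difference between the re-estimated and the
reference transition times,
$\sum_k (T_{ref,k} - T_{sensor,k})^2$, evaluated on an evenly spaced grid
of 2000 points spanning 0.5–10 Hz (endpoints included; ties resolve to
the lowest frequency).  The per-trial detrended/normalized spectra are
cached so the 2000-point sweep refilters rather than recomputes.  Here
the reference times are the simulator's ground truth — the human
examiners of the original protocol are exactly what the simulation twin
replaces.  `selectSensorCombination()` scores every subset of candidate
channels by the cost of the subset's mean estimate, each channel at its
own optimized cutoff.

## Evaluation metrics

`scoreDetection()` counts per ground-truth segment instance (6 per
trial): an instance is a true positive when an event of its activity
peaks inside it, a false negative otherwise; the same instance is the
negative-class opportunity, becoming a false positive when an event of a
*different* activity peaks inside it and a true negative otherwise.  This
opportunity-based negative class is one consistent reading of a
specificity quoted over the same n as sensitivity; it is a definition
this package fixes explicitly.  `deltaT()` reports, per transition, the
cohort mean absolute difference between estimated and reference times
together with the spread of the signed differences.

# The synthetic TUG generator

`simulateTug()` produces labeled trials carrying the kinematic signatures
the detectors assume; `simulateCohort()` draws per-subject parameters by
jittering every duration, the gait speed, the stride frequency and the
channel amplitudes by independent uniform factors in $[1-v,\,1+v]$
(default $v = 0.1$), two trials per subject, fully seeded.

Default study conditions: lead-in/out 0.8 s of quiet sitting, stand-up
and sit-down 1.8 s, turns 3.0 s, gait speed 1.05 m/s and stride frequency
1.8 Hz — an unhurried older-adult pace giving a 10 m trial of ~30 s and a
5 m trial of ~20 s, with per-channel linear drift (slope up to
0.02 units/s) and broadband Gaussian noise (SD 0.02 of the unit pulse
amplitude, a few percent of peak signal as in body-worn gyroscopes) on
every inertial channel, and small re-normalized jitter on the
quaternions.

Each activity pulse is a raised-cosine bump on a shallow (−0.1) pedestal:
the waveform is exactly −0.1 at the segment boundaries with zero slope,
rises strictly monotonically to +1 at the activity peak, and tapers to
zero over 1 s outside.  The design is deliberate on three counts.
First, the stationary boundary minima are the physiologic
counter-movement dips real stand/turn traces show, and they are what the
first-extremum rule finds — so the generator's ground-truth transition
times are the template boundaries themselves, not a post-hoc annotation.
Second, strict monotonicity between boundary and peak guarantees no
interior extremum intercepts the outward scan (an earlier single-cycle
cosine shape violated this and biased every boundary estimate inward by
~0.1 of the pulse duration).  Third, the pulse and taper spectra lie
below the narrowest calibrated band (0.41–0.53 Hz), so brick-wall
conditioning at any Table cutoff preserves the boundary minima; this is
why the turns last 3 s (carrier ~0.33 Hz).  The pedestal depth stays
well below the 30% detection threshold so the dips are never counted as
events of their own.

Channel layout: trunk and hip $a_z$ carry the stand pulse and an
inverted sit pulse; hip $a_y$ is a smooth step up during stand-up and
down during sit-down, giving the derivative sign rule its signal; trunk
and head $\omega_y$ (and head $\omega_x$, at reduced gain) carry two
same-sign turn pulses; hip $\omega_x$ carries the stride sinusoid with a
smooth envelope spanning both walks — attenuated to 40% through the
first turn, so walking genuinely is detected during turning and the
precedence rule is exercised — plus a pitch pulse during stand-up; hip
$\omega_y$ mirrors the turns at 80% and the stride at 15%.  The thigh
orientation rotates 90° from seated to upright (with a small extension
overshoot at the end of stand-up and a ±6° stride swing) against static
hip and shin quaternions, so the knee ROM trace runs 0° → ~90° → 0°.

What the simulator does **not** model: translational gait accelerations,
double-support timing, magnetometer output, soft-tissue artifact,
non-linear drift, arm channels beyond noise, or asymmetric/multi-step
turns.  Passing tests on these trials therefore show that the algorithm
recovers its own assumptions under drift, noise and subject variability —
not that it segments arbitrary real recordings; the calibration machinery
exists precisely so real reference segmentations can re-tune the cutoffs.

# Numerical choices and degenerate inputs

* Time is seconds from trial start; samples are on a 60 Hz grid and
  extremum times are reported on that grid (no sub-sample interpolation,
  keeping candidates identical across reruns).
* Extrema on plateaus take the earliest sample; ties in the calibration
  grid take the lowest frequency — both for determinism.
* A constant or all-zero trace is rejected by normalization
  (`"degenerate signal"`); a trace that is linear to machine precision is
  snapped to exact zero by the detrender so it is caught the same way.
* Band edges are validated (`0 <= w1 < w2 <= Nyquist`), orientation
  quaternions are renormalized on construction and rejected beyond a 0.5
  norm deviation, and a walking window longer than the trial is an error.
* Missing channels fail fast with the absent (site, quantity) named;
  non-monotone transition estimates raise `"inconsistent segmentation"`
  with the offending pair.

# Problem sizes

The packaged tests and the acceptance script run cohorts of 16 subjects
× 2 trials per distance (32 trials, 192 segment instances, 224
transition points), the full 2000-point calibration grid over one
channel/transition, and 1000-signal brute-force cross-checks of the
extremum search — sizes chosen to mirror the study design while keeping
a complete run in a few minutes on one core.

# Known limitations

* The generator's phenomenology is stylized (see above); amplitudes after
  normalization are free parameters chosen for qualitative resemblance to
  real conditioned traces.
* The calibrated optimum $w_2$ lies in a shallow cost valley; its argmin
  can move by a few milli-hertz grid steps as subjects are added or
  resampled.  The package reports the full cost curve so users can judge
  valley width rather than trust a point estimate.
* Specificity depends on the opportunity-based negative class defined
  above; other definitions (e.g. time-based) would give different
  denominators.
* Detection assumes the canonical TUG order (stand, walk, turn, walk,
  turn, sit); trials missing an activity fail with a structural error
  rather than being re-ordered.
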