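---
title: "A conductance-based model of the micturition circuit, spinal cord injury, and magnetic stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of the micturition circuit, spinal cord injury, and magnetic stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micturinet)
```

## The model

micturinet simulates the neural circuit that switches the lower urinary
tract between urine storage and voiding, as a network of single-compartment
Hodgkin-Huxley nodes. Each node represents a neuronal population: bladder
stretch afferents in the pelvic nerve (Node 5, a multi-compartment axonal
cable), sympathetic preganglionic/hypogastric efferents that relax the
detrusor during storage (Node 4), the parasympathetic preganglionic drive
that contracts it during voiding (Node 8), the somatic motor neurons of the
Nucleus of Onuf controlling the external urethral sphincter (Node 9), a
lumbar interneuron implementing a latent, threshold-triggered spinal voiding
reflex (Node 7) with its dedicated inhibitory gate (Node 6), three
TMS-responsive lumbar interneurons relaying descending commands (excitatory
Nodes 1 and 3, inhibitory Node 2), and the brainstem loop: the pontine
storage and micturition centres (PSC, PMC) and the periaqueductal grey
(PAG), which gates the micturition command on when the ascending afferent
rate passes a fullness threshold and the higher centres permit voiding.

Every node obeys the standard Hodgkin-Huxley membrane equation in which all
ionic and synaptic currents oppose the capacitive current,

$$ c\,\dot v = -(g_{Na} m^3 h + g_{TMS})(v - v_{Na}) - g_K n^4 (v - v_K)
   - g_L (v - v_L) - \textstyle\sum_s s\,(v - v_{syn}) + I_{inj}. $$

Some published statements of this equation carry mixed signs on the
potassium and leak terms; those signs would make both currents regenerative
and the rest state unstable, so the package uses the standard convention
throughout. Units are mV, ms, mS/cm&sup2;, &mu;F/cm&sup2; and &mu;A/cm&sup2;
(1 k&Omega;&#8315;&sup1;/cm&sup2; = 1 mS/cm&sup2;).

Magnetic stimulation enters as a transient addition $g_{TMS}$ to the sodium
conductance of the lumbar interneurons (Nodes 1-3 only), driven by the
induced electromotive force $u(t)$ of the coil through

$$ g_{TMS} + \tau\,\dot g_{TMS} = k\,u(t), \qquad \tau = 30\ \mathrm{ms}. $$

The long closing time constant is what converts a 210 &mu;s pulse into tens
of milliseconds of elevated sodium conductance, and hence into bursting; it
stands in for network reverberation inside a population node. The EMF is the
time derivative of the coil current: a biphasic coil pulse (one full sine
cycle) induces a tri-phasic EMF (+,&minus;,+), a monophasic pulse (fast
quarter-sine rise, slow return) a two-lobed EMF whose positive lobe carries
half the charge. Both EMFs integrate to zero because the coil current
returns to baseline. By default the negative EMF lobes are clipped before
they reach the conductance equation (`tms_drive = "rectified"`), since a
negative lobe cannot close channels that are not open; a signed mode with a
floor at zero is available and nearly indistinguishable at
$\tau \gg$ pulse width. All TMS runs use the standard pulse: width
210 &mu;s, peak $k\,u = 4$ mS/cm&sup2;, at 1 Hz or 30 Hz.

## Membrane classes and the differential TMS sensitivity

Cell-resolved recordings of the spinal interneurons involved are not
available, so the membrane parameter sets are the package's own calibration,
built from the classical squid-axon kinetics with per-node density scales
and gating voltage shifts (both are first-class fields of
`membrane_params()`):

* **Projection/effector nodes** (4, 8, 9, PSC, PMC, cable compartments) use
  the classical set unchanged. They behave as relays: a suprathreshold
  synaptic kick yields one spike, so efferent rates can track afferent rates
  one-to-one.
* **Inhibitory interneurons** (Nodes 2 and 6, `interneuron_params("inhibitory")`)
  scale all channel densities and the capacitance by 0.03. This preserves
  the classical spike shape and resting potential exactly while dividing
  every current threshold by ~33, producing a low-threshold, fast-recruited
  cell whose potassium conductance (1.08 mS/cm&sup2;) lies far below that of
  any excitatory node — the key difference behind the differential TMS
  sensitivity. A single standard TMS pulse elicits a 3-6 spike burst that
  decays back to rest within ~50 ms.
* **Excitatory TMS interneurons** (Nodes 1 and 3,
  `interneuron_params("excitatory")`) are high-threshold slow integrators:
  sparse channels (gNa = 20, gK = 6 mS/cm&sup2;) recruited only well above
  rest (m/h kinetics shifted +16 mV, n shifted +25 mV), a high input
  resistance (gL = 0.02 mS/cm&sup2; anchored at &minus;65 mV), and a shallow
  after-spike reset (vK = &minus;70 mV). An isolated pulse depolarises such
  a cell by ~15 mV and dies away silently; a 30 Hz train, whose
  time-averaged conductance drive is thirty-fold larger, carries it across
  threshold, after which the pulses entrain close to one spike per
  stimulus. The same membrane, driven synaptically, serves as the
  voiding-reflex integrator Node 7: it converts the afferent *rate* into a
  depolarisation and fires only above a fullness threshold (between 25 and
  45 Hz at the healthy weight), which is exactly the infantile reflex
  threshold behaviour.

One consequence is worth stating plainly: in any deterministic,
time-invariant membrane the first pulse of a 30 Hz train is identical to an
isolated 1 Hz pulse. A node that is silent under 1 Hz stimulation therefore
cannot fire on the first pulse at 30 Hz; entrainment starts at the second
pulse, and a 10-pulse train yields 9 spikes. "One spike per stimulation" is
realised from the second pulse onward.

## Circuit function

During **storage** (higher centres withholding voiding), the afferent
staircase 10 &rarr; 25 &rarr; 45 Hz drives Node 4 and Node 9 one-to-one
through spinal reflex arcs, the PSC (driven by a smoothed ascending rate
estimate) activates Node 3 and thereby Node 6, whose inhibition keeps the
voiding-reflex integrator Node 7 silent even at a full bladder; Node 8
stays quiet. Deleting Node 6's inhibition unmasks threshold voiding at the
45 Hz step — the latent infantile reflex. During **voiding** (permit on,
bladder full) the PAG gate drives both PMC nodes; the inhibitory PMC node
silences the PSC (reciprocal switching), Node 2 suppresses Node 4 and
relaxes Node 9, and Node 1 plus the disinhibited Node 7 drive Node 8.

An **upper (T10) injury** zeroes every edge crossing the lesion plane. The
local arcs then co-activate Nodes 4, 8 and 9 at a full bladder — the
dyssynergic pattern — with the post-injury plasticity overlay (6&rarr;7,
5&rarr;7 and 2&rarr;4 doubled, the sympathetic limb halved; directions are
physiological, the magnitudes are the smallest round factors that flip the
relevant gains). A **conus injury** clamps Nodes 8 and 9 at rest and
unresponsive: filling then only raises Node 4 — the flaccid, dripping
bladder.

Under an upper injury, **1 Hz TMS** recruits only inhibitory Node 2, whose
post-pulse burst silences Node 4 and pauses Node 9 while the disinhibited
reflex keeps Node 8 active: a coordinated voiding event within a few hundred
milliseconds of each pulse, lasting tens of milliseconds. **30 Hz TMS**
additionally recruits Nodes 1 and 3; Node 3 re-engages Node 6 (suppressing
the reflex) and drives Node 9 continuously, so no voiding event occurs and
storage is favoured. The event detector operationalises "coordinated
voiding" as: detrusor burst, sphincter pause and sympathetic pause
overlapping; a pause is a local inter-spike gap exceeding 1.8&times; the
train's own median interval (scale-free across rates), and the stated
expectations are onset within 500 ms of the pulse and duration under
100 ms — all config-exposed.

## Numerics

The network integrator is fixed-step classical Runge-Kutta (RK4) on a shared
clock, compiled in C++, with `dt = 0.01` ms by default — the 210 &mu;s TMS
pulse demands sub-0.05 ms resolution; stimulus waveforms are sampled on the
half-step grid the scheme needs. Synaptic gates jump by the edge weight at
presynaptic spike times (detected as upward 0 mV crossings with a 2 ms dead
time, interpolated linearly) and decay exponentially otherwise; relays are
first-order filters with unit DC gain; the PAG is a rate threshold (35 Hz by
default, so the micturition command engages between the 25 and 45 Hz
afferent steps) on a 100 ms rate estimate. Gating variables are clamped to
[0,1] and $g_{TMS}$ floored at 0 after each step; any |v| > 200 mV aborts
with the node and time. Everything is deterministic — the only random
element is the optional Poisson afferent mode behind a seed. Spike counts
are insensitive to halving `dt`, which the test suite asserts.

The pelvic afferent is a chain of 5-20 identical classical compartments with
ohmic axial coupling (0.25 mS/cm&sup2; by default); a proximally injected
spike regenerates compartment to compartment, giving a conduction delay of
roughly 1 ms per compartment (~11 ms at the default 10), inside the
physiological 5-15 ms window, monotone in compartment count, and one-to-one
at 40 Hz.

## What the synthetic fixtures do and do not show

`generate_fixture()` produces regular spike trains, Gaussian-bump voltage
traces and miniature scenario bundles with sidecar ground truth; the
analysis layer is tested by exact recovery on these. They emulate clean,
regular activity — real recordings carry jitter, bursting variability and
measurement noise that these fixtures deliberately omit, so passing tests
validate the metric definitions, not their robustness to noisy data (the
Poisson afferent mode exists for such robustness probes).

## Scenario durations and problem sizes

Storage runs 3 s (three 1 s steps), voiding 2 s, both injuries 2-3 s, 1 Hz
TMS 2 s (pulses at 0 and 1000 ms) and 30 Hz TMS 1 s (30 pulses) — enough for
every behaviour to express while keeping a full scenario sweep to a few
minutes on one CPU. All durations, weights, lesion/plasticity settings and
detector thresholds are config-exposed; `scripts/calibrate.R` re-derives the
calibrated operating points.

## Known limitations

No bladder/urethra biomechanics (pressures and flows are not computed);
no distinction between A-delta and C afferent fibre classes; no pudendal
afferents; no calcium dynamics or receptor-level plasticity — the post-injury
state is a fixed reweighting, so only acute TMS effects are modelled, not
the slow neuroplastic changes under repeated stimulation. Populations are
single nodes: the long TMS closing constant absorbs what is really network
reverberation. The absolute sphincter rate under 30 Hz TMS follows the
descending relay (about 29 Hz) rather than exceeding the dyssynergic
baseline; what the model preserves is the qualitative contrast — sustained,
pause-free sphincter drive at 30 Hz versus pulse-locked sphincter pauses at
1 Hz.

## A worked example

```{r example, eval = FALSE}
res <- run_scenario("healthy_storage")
res$report
# mean rates (Hz):
#   step1 step2 step3
# 4    10    25    45
# 8     0     0     0
# 9    15    37    54
fc <- tms_frequency_contrast(c(1, 30))
fc[["1"]]$events_per_pulse   # 1
nrow(fc[["30"]]$events)      # 0
```
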