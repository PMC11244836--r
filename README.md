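# micturinet

Conductance-based simulation of the spinal and brainstem circuit that
controls urine storage and voiding. The package is aimed at computational
neuroscientists and neuro-urology researchers who want a mechanistic,
spiking-level testbed for how the micturition reflex degrades after spinal
cord injury (SCI) and how transcutaneous magnetic stimulation (TMS) of the
lumbar spine acutely restores (1 Hz) or suppresses (30 Hz) coordinated
voiding.

Every neuronal population is a single-compartment Hodgkin-Huxley node,

```
c dv/dt = -(gNa m^3 h + gTMS)(v - vNa) - gK n^4 (v - vK) - gL (v - vL) - Σ s (v - vsyn)
```

with classical m³h / n⁴ gating (per-node density scales and gating voltage
shifts define the cell classes). TMS enters as a transient sodium
conductance on the lumbar interneurons, driven by the coil's induced EMF
`u(t)` through `gTMS + τ dgTMS/dt = k u`, with τ = 30 ms, 210 µs pulses and
peak `k·u` = 4 mS/cm². The bladder afferent is a 5–20 compartment axonal
cable; lesions are overlays (a T10 transection severs every edge crossing
the lesion plane; a conus lesion clamps the sacral efferent nodes) and the
post-SCI state is a synaptic reweighting of four connection groups. A
fixed-step RK4 engine (compiled, dt = 0.01 ms) advances all nodes, cable
compartments, synaptic gates and relays on one clock, deterministically.

The analysis layer turns spike trains into the physiological statements:
firing rates, burst statistics, post-train persistence, a dyssynergia
coactivation index, and a coordinated voiding-event detector (detrusor burst
+ sphincter pause + sympathetic pause).

See the methods vignette (`vignettes/micturition-model.Rmd`) for the model,
its assumptions, the calibrated parameters and known limitations.

## A worked example

```r
library(micturinet)

# healthy storage: bladder fills in three afferent steps, 10 -> 25 -> 45 Hz
res <- run_scenario("healthy_storage")
res$report
#> mean rates (Hz):
#>   step1 step2 step3
#> 4    10    25    45
#> 8     0     0     0
#> 9    15    37    54
```

The hypogastric efferent (Node 4, detrusor relaxation) tracks the afferent
staircase exactly; the parasympathetic detrusor drive (Node 8) stays silent;
the sphincter motor drive (Node 9) grows with filling — urine is stored.

```r
# after an upper (T10) injury, 1 Hz TMS elicits one coordinated voiding
# event shortly after each pulse; 30 Hz TMS prevents voiding entirely
fc <- tms_frequency_contrast(c(1, 30))
fc[["1"]]$events
#>   onset offset duration
#> 1    20     60       40
#> 2  1020   1060       40
nrow(fc[["30"]]$events)
#> [1] 0
```

A thin command-line front end ships in `inst/cli/micturinet`
(`micturinet scenario sci_upper --out out/`,
`micturinet analyze out/spikes.csv --out metrics.json`).

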