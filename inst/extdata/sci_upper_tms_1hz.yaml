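# Example scenario: 1 Hz biphasic TMS applied after an upper (T10) injury.
# Units: times ms, rates Hz, conductances mS/cm^2, pulse width us.
name: sci_upper_tms
duration: 2000.0
dt: 0.01
lesion: upper_T10
plasticity: sci
hc_permit: no
afferent:
  start: 0.0
  rate: 40.0
tms:
  shape: biphasic
  width_us: 210.0
  peak_ku: 4.0
  frequency: 1.0
  n_pulses: 2
  onset: 0.0
  targets: ["1", "2", "3"]
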