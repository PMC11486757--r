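# Nutrient excess: substrate feed raised to 60 g/h at unchanged total flow,
# applied as a transient from the high steady state. Growth outruns the
# dilution rate, MSG accumulates in the broth much faster than glucose, and
# amino-acid secretion appears; the carbon balance closes to 0.79.
name: overfeed
v_reactor: 2.0
tfr: 120.0
sfr: 60.0
wfr: 60.0
evaporation: 46.0
feed_stock:
  msg: 76.0
  glucose: 36.0
true_mu: 0.054
q_uptake:            # uptake ratio msg/glucose = 1.83
  msg: 0.119
  glucose: 0.065
q_production:
  trehalose: 0.009
  valine: 0.005
  glycine: 0.002
  alanine: 0.0015
unmeasured_sink_fraction: 0.21
x0: 16.2
s0:                  # carried over from the high steady state
  msg: 4.65
  glucose: 0.5
p0:
  trehalose: 3.94
  valine: 0.44
  glycine: 0.22
  alanine: 0.13
grid: {from: 0.0, to: 6.0, by: 1.5}
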