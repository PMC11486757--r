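# Baseline condition: moderate cell density, no substrate accumulation.
# Dual-feed chemostat at total flow 90 g/h (substrate feed 22.5, water 67.5),
# evaporative loss at cultivation temperature reduces the bleed.
name: low
v_reactor: 2.0
tfr: 90.0
sfr: 22.5
wfr: 67.5
evaporation: 28.0
feed_stock:
  msg: 76.0
  glucose: 36.0
true_mu: 0.031
q_uptake:            # uptake ratio msg/glucose = 2.30
  msg: 0.165
  glucose: 0.0717
q_production:
  trehalose: 0.003
  valine: 0.0005
  glycine: 0.0003
  alanine: 0.0002
unmeasured_sink_fraction: 0.10
x0: 5.0
grid: {from: 0.0, to: 24.0, by: 6.0}
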