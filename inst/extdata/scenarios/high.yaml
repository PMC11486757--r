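# Elevated nutrient availability without C-source accumulation: total flow
# 120 g/h (substrate feed 40, water 80), higher cell density, carbon balance
# closing to 0.80 via the unmeasured sink.
name: high
v_reactor: 2.0
tfr: 120.0
sfr: 40.0
wfr: 80.0
evaporation: 46.0
feed_stock:
  msg: 76.0
  glucose: 36.0
true_mu: 0.037
q_uptake:            # uptake ratio msg/glucose = 1.90
  msg: 0.0832
  glucose: 0.0438
q_production:
  trehalose: 0.009
  valine: 0.001
  glycine: 0.0005
  alanine: 0.0003
unmeasured_sink_fraction: 0.20
x0: 16.2
grid: {from: 0.0, to: 24.0, by: 6.0}
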