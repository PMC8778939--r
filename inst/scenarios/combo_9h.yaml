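# Combination therapy: TSL-Dox bolus at t = 0, AMF (13 kA/m, 400 kHz,
# 60 min) applied 9 h post-injection, followed to 72 h.
schedule:
  mode: combination
  delay_h: 9
  horizon_h: 72
field:
  amplitude_ka_per_m: 13
  frequency: 400000
  safety_product_limit: 5.3e+9
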