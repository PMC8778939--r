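# Magnetic hyperthermia alone, 13 kA/m at 400 kHz for 60 min.
# H*f = 5.2e9 A/(m s): the safety limit is raised explicitly for this
# exposure (the base-case field of the modeled treatment).
schedule:
  mode: mht_only
  delay_h: 0
field:
  amplitude_ka_per_m: 13
  frequency: 400000
  safety_product_limit: 5.3e+9
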