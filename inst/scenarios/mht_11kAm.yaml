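# Magnetic hyperthermia alone, 11 kA/m at 400 kHz for 60 min.
schedule:
  mode: mht_only
  delay_h: 0
field:
  amplitude_ka_per_m: 11
  frequency: 400000
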