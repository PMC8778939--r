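# Conventional chemotherapy: free doxorubicin bolus, no heating.
schedule:
  mode: chemo
  horizon_h: 72
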