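# Example partial override: undiscounted outcomes, interval detection off.
# Every field not listed here falls back to the bundled baseline.
config:
  discount_rate: 0.0
  detection_mode: screen_only
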