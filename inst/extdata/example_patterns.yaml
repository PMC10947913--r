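# Extraction pattern overrides. Keys replace the built-in defaults of
# lvef_patterns(); omit a key to keep the default.
lv_context:
  - left\s+ventricular\s+ejection\s+fraction
  - lv\s+ejection\s+fraction
  - ejection\s+fraction
  - \blvef\b
  - \bef\b
  - systolic performance
non_cardiac_context:
  - gall\s*-?\s*bladder
  - right\s+ventricular
  - \brvef\b
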