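# GOLD-style intensity ladder for COPD (reconstruction; review before
# interpreting conformance). Labels are canonical: alphabetical "+"-joined
# class sets; fixed-combination inhalers (LABA-LAMA etc.) are atomic.
disease: copd
levels:
  "SABA": 1
  "SAMA": 1
  "SABA-SAMA": 1
  "SABA+SAMA": 1
  "LABA": 2
  "LAMA": 2
  "LABA-LAMA": 3
  "LABA-ICS": 3
  "LABA+LAMA": 3
  "LABA-LAMA-ICS": 4
  "ICS+LABA-LAMA": 4
  "LABA-ICS+LAMA": 4
level_rules:
  "PDE4": 5
  "xanthines": 5
  "steroid_maintenance": 5
rescue_classes: ["SABA", "SAMA", "SABA-SAMA"]
strict_transitions:
  - ["SABA", "LABA"]
  - ["SABA", "LAMA"]
  - ["SAMA", "LABA"]
  - ["SAMA", "LAMA"]
  - ["LABA", "LABA-LAMA"]
  - ["LAMA", "LABA-LAMA"]
  - ["LABA-LAMA", "LABA-LAMA-ICS"]
  - ["LABA-ICS", "LABA-LAMA-ICS"]
  - ["LABA-LAMA-ICS", "LABA-LAMA"]
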