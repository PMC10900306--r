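# GINA-style intensity ladder for asthma (reconstruction; review before
# interpreting conformance). Labels are canonical: alphabetical "+"-joined
# class sets; fixed-combination inhalers (LABA-ICS etc.) are atomic.
disease: asthma
levels:
  "SABA": 1
  "SAMA": 1
  "SABA-SAMA": 1
  "ICS": 2
  "LTRA": 2
  "LABA-ICS": 3
  "ICS+LTRA": 3
  "ICS+LABA": 3
  "LABA-LAMA-ICS": 4
  "LABA-ICS+LTRA": 4
  "LABA-ICS+LAMA": 4
level_rules:
  "biologics": 5
  "steroid_maintenance": 5
rescue_classes: ["SABA", "SAMA", "SABA-SAMA"]
strict_transitions:
  - ["SABA", "ICS"]
  - ["SABA", "LABA-ICS"]
  - ["ICS", "LABA-ICS"]
  - ["ICS", "ICS+LTRA"]
  - ["ICS", "SABA"]
  - ["LABA-ICS", "LABA-LAMA-ICS"]
  - ["LABA-ICS", "LABA-ICS+LAMA"]
  - ["LABA-ICS", "ICS"]
  - ["LABA-LAMA-ICS", "LABA-ICS"]
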