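grid_n: 1001
inputs:
  radon:
    domain:
    - 0.0
    - 1000.0
    levels:
      low:
      - 0.0
      - 0.0
      - 100.0
      - 148.0
      medium:
      - 100.0
      - 148.0
      - 200.0
      - 300.0
      high:
      - 200.0
      - 300.0
      - 1000.0
      - 1000.0
  fc:
    domain:
    - 0.0
    - 10.0
    levels:
      low:
      - 0.0
      - 0.0
      - 2.333333333333333
      - 4.333333333333334
      medium:
      - 2.333333333333333
      - 4.333333333333334
      - 5.666666666666667
      - 7.666666666666667
      high:
      - 5.666666666666667
      - 7.666666666666667
      - 10.0
      - 10.0
output:
  name: rr
  domain:
  - 0.0
  - 100.0
  levels:
    very_low:
    - 0.0
    - 0.0
    - 15.0
    - 25.0
    low:
    - 15.0
    - 25.0
    - 35.0
    - 45.0
    medium:
    - 35.0
    - 45.0
    - 55.0
    - 65.0
    high:
    - 55.0
    - 65.0
    - 75.0
    - 85.0
    very_high:
    - 75.0
    - 85.0
    - 100.0
    - 100.0
rules:
- var1: radon
  lev1: low
  var2: fc
  lev2: low
  consequent: very_low
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: low
  var2: fc
  lev2: medium
  consequent: low
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: low
  var2: fc
  lev2: high
  consequent: medium
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: medium
  var2: fc
  lev2: low
  consequent: low
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: medium
  var2: fc
  lev2: medium
  consequent: medium
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: medium
  var2: fc
  lev2: high
  consequent: high
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: high
  var2: fc
  lev2: low
  consequent: medium
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: high
  var2: fc
  lev2: medium
  consequent: high
  weight: 1.0
  polarity: direct
  key_var: radon
- var1: radon
  lev1: high
  var2: fc
  lev2: high
  consequent: very_high
  weight: 1.0
  polarity: direct
  key_var: radon
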