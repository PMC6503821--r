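# Worked example scenario set: reconstructed colonization hypotheses with
# desk-scale priors (synthetic reconstruction, not an archived analysis config).
analysis: ausable
models:
- name: SAB_FCP_single
  generation_time: 2.0
  demes:
    SAB:
      hyper: gl_ne
    FCP:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    CDP:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    FDP:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
  hyperpriors:
    gl_ne:
      dist: loguniform
      lower: 500.0
      upper: 5000.0
  class_priors:
    SF:
      dist: uniform
      lower: 0.05
      upper: 0.5
    RF:
      dist: uniform
      lower: 0.005
      upper: 0.3
  sampling:
    SAB: 20
    FCP: 20
    CDP: 20
    FDP: 20
  events:
  - time: 9.0
    derived: FCP
    source: SAB
    duration: 1.0
    class: RF
    severity: RF
  - time: 7.0
    derived: CDP
    source: FCP
    duration: 1.0
    class: RF
    severity: RF
  - time: 5.0
    derived: FDP
    source: CDP
    duration: 1.0
    class: RF
    severity: RF
  migration:
  - from: CDP
    to: FCP
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
  - from: FDP
    to: CDP
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
- name: SAB_FCP_CDP_multiple
  generation_time: 2.0
  demes:
    SAB:
      hyper: gl_ne
    FCP:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    CDP:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    FDP:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
  hyperpriors:
    gl_ne:
      dist: loguniform
      lower: 500.0
      upper: 5000.0
  class_priors:
    SF:
      dist: uniform
      lower: 0.05
      upper: 0.5
    RF:
      dist: uniform
      lower: 0.005
      upper: 0.3
  sampling:
    SAB: 20
    FCP: 20
    CDP: 20
    FDP: 20
  events:
  - time: 9.0
    derived: FCP
    source: SAB
    duration: 1.0
    class: RF
    severity: RF
  - time: 9.0
    derived: CDP
    source: SAB
    duration: 1.0
    class: RF
    severity: RF
  - time: 5.0
    derived: FDP
    source: CDP
    duration: 1.0
    class: RF
    severity: RF
  migration:
  - from: CDP
    to: FCP
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
  - from: FDP
    to: CDP
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
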