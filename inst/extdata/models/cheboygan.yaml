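# Worked example scenario set: reconstructed colonization hypotheses with
# desk-scale priors (synthetic reconstruction, not an archived analysis config).
analysis: cheboygan
models:
- name: LocalEast
  generation_time: 2.0
  demes:
    SAB:
      hyper: gl_ne
    CBR:
      hyper: gl_ne
    MLL:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    BTL:
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
    CBR: 20
    MLL: 20
    BTL: 20
  events:
  - time: 12.0
    derived: CBR
    source: SAB
    duration: 1.0
    class: SF
    severity: SF
  - time: 8.0
    derived: MLL
    source: CBR
    duration: 1.0
    class: RF
    severity: RF
  - time: 5.0
    derived: BTL
    source: MLL
    duration: 1.0
    class: RF
    severity: RF
  migration:
  - from: MLL
    to: BTL
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
- name: SAB_MLL
  generation_time: 2.0
  demes:
    SAB:
      hyper: gl_ne
    CBR:
      hyper: gl_ne
    MLL:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    BTL:
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
    CBR: 20
    MLL: 20
    BTL: 20
  events:
  - time: 12.0
    derived: CBR
    source: SAB
    duration: 1.0
    class: SF
    severity: SF
  - time: 8.0
    derived: MLL
    source: SAB
    duration: 1.0
    class: RF
    severity: RF
  - time: 5.0
    derived: BTL
    source: MLL
    duration: 1.0
    class: RF
    severity: RF
  migration:
  - from: MLL
    to: BTL
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
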