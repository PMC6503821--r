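# Worked example scenario set: reconstructed colonization hypotheses with
# desk-scale priors (synthetic reconstruction, not an archived analysis config).
analysis: flint
models:
- name: LocalSAB
  generation_time: 2.0
  demes:
    SAB:
      hyper: gl_ne
    LKM:
      hyper: gl_ne
    HWR:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    MTL:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    BML:
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
    LKM: 20
    HWR: 20
    MTL: 20
    BML: 20
  events:
  - time: 13.0
    derived: LKM
    source: SAB
    duration: 1.0
    class: SF
    severity: SF
  - time: 10.0
    derived: BML
    source: SAB
    duration: 1.0
    class: RF
    severity: RF
  - time: 8.0
    derived: MTL
    source: BML
    duration: 1.0
    class: RF
    severity: RF
  - time: 6.0
    derived: HWR
    source: MTL
    duration: 1.0
    class: RF
    severity: RF
  migration:
  - from: BML
    to: MTL
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
  - from: MTL
    to: HWR
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
- name: SAB_HWR
  generation_time: 2.0
  demes:
    SAB:
      hyper: gl_ne
    LKM:
      hyper: gl_ne
    HWR:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    MTL:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    BML:
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
    LKM: 20
    HWR: 20
    MTL: 20
    BML: 20
  events:
  - time: 13.0
    derived: LKM
    source: SAB
    duration: 1.0
    class: SF
    severity: SF
  - time: 10.0
    derived: HWR
    source: SAB
    duration: 1.0
    class: RF
    severity: RF
  - time: 8.0
    derived: MTL
    source: HWR
    duration: 1.0
    class: RF
    severity: RF
  - time: 6.0
    derived: BML
    source: MTL
    duration: 1.0
    class: RF
    severity: RF
  migration:
  - from: BML
    to: MTL
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
  - from: MTL
    to: HWR
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
- name: MIC_HWR
  generation_time: 2.0
  demes:
    SAB:
      hyper: gl_ne
    LKM:
      hyper: gl_ne
    HWR:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    MTL:
      dist: loguniform
      lower: 10.0
      upper: 1000.0
    BML:
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
    LKM: 20
    HWR: 20
    MTL: 20
    BML: 20
  events:
  - time: 13.0
    derived: LKM
    source: SAB
    duration: 1.0
    class: SF
    severity: SF
  - time: 10.0
    derived: HWR
    source: LKM
    duration: 1.0
    class: RF
    severity: RF
  - time: 8.0
    derived: MTL
    source: HWR
    duration: 1.0
    class: RF
    severity: RF
  - time: 6.0
    derived: BML
    source: MTL
    duration: 1.0
    class: RF
    severity: RF
  migration:
  - from: BML
    to: MTL
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
  - from: MTL
    to: HWR
    rate:
      dist: loguniform
      lower: 0.001
      upper: 0.1
    start: 0.0
    end: Inf
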