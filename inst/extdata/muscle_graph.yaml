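segments:
- muscle: pvm
  segment: pvm
  origin:
    type: point
    structure: pvm
    role: origin
    index: 1
  insertion:
    type: point
    structure: pam
    role: insertion
    index: 2
- muscle: pvam
  segment: pvam
  origin:
    type: auxiliary
    index: 1
  insertion:
    type: midpoint
    points:
    - type: point
      structure: pvam
      role: insertion
      index: 1
    - type: point
      structure: pvam
      role: insertion
      index: 2
- muscle: ppm
  segment: ppm
  origin:
    type: auxiliary
    index: 2
  insertion:
    type: point
    structure: ppm
    role: insertion
    index: 1
- muscle: pam
  segment: pam
  origin:
    type: auxiliary
    index: 3
  insertion:
    type: point
    structure: pam
    role: insertion
    index: 2
- muscle: prm
  segment: prm
  origin:
    type: point
    structure: prm
    role: origin
    index: 2
  insertion:
    type: point
    structure: prm
    role: insertion
    index: 1
- muscle: icm
  segment: icm_1
  origin:
    type: point
    structure: icm
    role: origin
    index: 1
  insertion:
    type: point
    structure: icm
    role: insertion
    index: 1
- muscle: icm
  segment: icm_2
  origin:
    type: point
    structure: icm
    role: origin
    index: 4
  insertion:
    type: point
    structure: icm
    role: insertion
    index: 2
- muscle: coc
  segment: coc_1
  origin:
    type: point
    structure: ischial_spine
    role: bone
    index: 1
  insertion:
    type: point
    structure: coc
    role: insertion
    index: 1
- muscle: coc
  segment: coc_2
  origin:
    type: point
    structure: ischial_spine
    role: bone
    index: 1
  insertion:
    type: point
    structure: coc
    role: insertion
    index: 2
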