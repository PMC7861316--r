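# Default plan-scoring rubric: 18 metrics, 164 max points.
# Max points follow the published lung IMRT training rubric; the award
# thresholds (full credit at `full`, zero credit at `zero`, linear ramp
# between) are package defaults informed by RTOG-style lung planning
# constraints and are fully configurable here.
# `rel_rx: true` means the threshold is a multiple of the prescription.
name: default
version: 1
metrics:
  - id: ptv_d98
    label: "PTV D98%"
    structure: ptv
    quantity: dose_at_volume
    args: {volume_percent: 98}
    units: Gy
    max_points: 21
    direction: higher
    full: {value: 0.98, rel_rx: true}
    zero: {value: 0.90, rel_rx: true}
  - id: ptv_min
    label: "PTV min dose"
    structure: ptv
    quantity: min_dose
    units: Gy
    max_points: 10
    direction: higher
    full: {value: 0.93, rel_rx: true}
    zero: {value: 0.80, rel_rx: true}
  - id: gtv_min
    label: "GTV min dose"
    structure: gtv
    quantity: min_dose
    units: Gy
    max_points: 10
    direction: higher
    full: {value: 0.95, rel_rx: true}
    zero: {value: 0.85, rel_rx: true}
  - id: cn95
    label: "CN 95%"
    structure: ptv
    quantity: conformation_number
    args: {iso_fraction: 0.95}
    units: ratio
    max_points: 12
    direction: higher
    full: {value: 0.85}
    zero: {value: 0.50}
  - id: ci50
    label: "CI 50%"
    structure: ptv
    quantity: conformity_index
    args: {iso_fraction: 0.5}
    units: ratio
    max_points: 12
    direction: lower
    full: {value: 4.0}
    zero: {value: 8.0}
  - id: max_dose_location
    label: "Location of max dose"
    structure: ptv
    quantity: max_in_ptv
    units: boolean
    max_points: 10
    direction: binary
  - id: lung_max
    label: "Lung max dose"
    structure: lungs
    quantity: max_dose
    units: Gy
    max_points: 5
    direction: lower
    full: {value: 1.05, rel_rx: true}
    zero: {value: 1.15, rel_rx: true}
  - id: lung_mean
    label: "Lung mean dose"
    structure: lungs
    quantity: mean_dose
    units: Gy
    max_points: 5
    direction: lower
    full: {value: 15}
    zero: {value: 25}
  - id: lung_v20
    label: "Lung V20 Gy"
    structure: lungs
    quantity: volume_at_dose
    args: {dose_gy: 20}
    units: percent
    max_points: 10
    direction: lower
    full: {value: 20}
    zero: {value: 37}
  - id: lung_v5
    label: "Lung V5 Gy"
    structure: lungs
    quantity: volume_at_dose
    args: {dose_gy: 5}
    units: percent
    max_points: 15
    direction: lower
    full: {value: 50}
    zero: {value: 70}
  - id: heart_max
    label: "Heart max dose"
    structure: heart
    quantity: max_dose
    units: Gy
    max_points: 5
    direction: lower
    full: {value: 0.95, rel_rx: true}
    zero: {value: 1.05, rel_rx: true}
  - id: heart_mean
    label: "Heart mean dose"
    structure: heart
    quantity: mean_dose
    units: Gy
    max_points: 7
    direction: lower
    full: {value: 20}
    zero: {value: 35}
  - id: heart_v30
    label: "Heart V30 Gy"
    structure: heart
    quantity: volume_at_dose
    args: {dose_gy: 30}
    units: percent
    max_points: 5
    direction: lower
    full: {value: 30}
    zero: {value: 50}
  - id: heart_v40
    label: "Heart V40 Gy"
    structure: heart
    quantity: volume_at_dose
    args: {dose_gy: 40}
    units: percent
    max_points: 5
    direction: lower
    full: {value: 20}
    zero: {value: 35}
  - id: esophagus_max
    label: "Esophagus max dose"
    structure: esophagus
    quantity: max_dose
    units: Gy
    max_points: 7
    direction: lower
    full: {value: 0.95, rel_rx: true}
    zero: {value: 1.10, rel_rx: true}
  - id: esophagus_mean
    label: "Esophagus mean dose"
    structure: esophagus
    quantity: mean_dose
    units: Gy
    max_points: 5
    direction: lower
    full: {value: 24}
    zero: {value: 34}
  - id: cord_max
    label: "Cord max dose"
    structure: cord
    quantity: max_dose
    units: Gy
    max_points: 10
    direction: lower
    full: {value: 45}
    zero: {value: 50.5}
  - id: cord3mm_max
    label: "Cord+3 mm max dose"
    structure: "cord+3mm"
    quantity: max_dose
    units: Gy
    max_points: 10
    direction: lower
    full: {value: 48}
    zero: {value: 54}
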