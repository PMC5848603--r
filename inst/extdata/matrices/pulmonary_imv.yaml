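# Adult pulmonary rehabilitation matrix for patients under invasive
# mechanical ventilation: six variables, severity levels X/Y/Z (1/2/3 points).
# Printed numeric thresholds are taken literally; values that fall between two
# printed intervals (PEEP 6-7 and 9-10, FiO2 30-31 and 50-51, static
# compliance 34-35 and 49-50) are resolved by gap_policy "nearest-worse".
id: pulmonary_imv
name: Adult Pulmonary Rehabilitation, invasive mechanical ventilation
specialty: Pulmonary Rehabilitation
recat_policy:
  mode: on-event
  event_kinds: [ventilatory-support-change]
variables:
- name: auscultation
  label: Auscultation
  domain: {type: labels, labels: [normal, diminished, abolished], ordered: true}
  criteria:
    'X':
      labels: [normal]
      description: Normal lung sounds
    'Y':
      labels: [diminished]
      description: Diminished lung sounds and/or wheezing, diffuse crepitation pulmonary edema
    'Z':
      labels: [abolished]
      description: Abolished lung sounds and/or wheezing both phases and/or pulmonary edema bronchial breathing
- name: ventilatory_assistance
  label: Ventilatory assistance
  domain: {type: labels, labels: [spontaneous, assist-control, control], ordered: true}
  criteria:
    'X': {labels: [spontaneous]}
    'Y': {labels: [assist-control]}
    'Z': {labels: [control]}
- name: secretion
  label: Amount of secretion
  domain: {type: labels, labels: ['+', '++', '+++'], ordered: true}
  criteria:
    'X': {labels: ['+']}
    'Y': {labels: ['++']}
    'Z': {labels: ['+++']}
- name: minute_volume
  label: Minute volume
  units: L/min
  domain: {type: numeric, min: 0, max: 60}
  gap_policy: nearest-worse
  criteria:
    'X': {max: 7, max_open: true}
    'Y': {min: 7, max: 12}
    'Z': {min: 12, min_open: true}
- name: peep_fio2
  label: PEEP / FiO2
  compound: true
  combine: worst
  gap_policy: nearest-worse
  components:
  - name: peep
    units: cmH2O
    domain: {type: numeric, min: 0, max: 40}
    criteria:
      'X': {max: 6, max_open: true}
      'Y': {min: 7, max: 9}
      'Z': {min: 10, min_open: true}
  - name: fio2
    units: '%'
    domain: {type: numeric, min: 21, max: 100}
    criteria:
      'X': {max: 30}
      'Y': {min: 31, max: 50}
      'Z': {min: 51}
- name: static_compliance
  label: Static compliance
  units: cmH2O
  domain: {type: numeric, min: 0, max: 200}
  # "Not measurable or > 50 cmH2O" is printed in the 1-point column
  not_measurable_level: X
  gap_policy: nearest-worse
  criteria:
    'X': {min: 50, min_open: true}
    'Y': {min: 35, max: 49}
    'Z': {max: 34, max_open: true}
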