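# Motor rehabilitation matrix for ICU patients: four functional assessments,
# each scored 1/2/3 points by severity level (X/Y/Z).
id: icu_motor
name: Motor Rehabilitation, ICU patients
specialty: Adult ICU
recat_policy:
  mode: daily
  event_kinds: [ventilatory-support-change]
variables:
- name: mrc_sum
  label: MRC-Sum Score
  units: points
  domain: {type: numeric, min: 0, max: 60}
  not_measurable_level: Z
  gap_policy: nearest-worse
  criteria:
    'X': {min: 48, max: 60}
    'Y': {min: 37, max: 47}
    'Z': {min: 0, max: 36}
- name: fss_icu
  label: FSS-ICU
  units: points
  domain: {type: numeric, min: 0, max: 35}
  not_measurable_level: Z
  gap_policy: nearest-worse
  criteria:
    'X': {min: 29, max: 35}
    'Y': {min: 16, max: 28}
    'Z': {min: 0, max: 15}
- name: handgrip
  label: Handgrip dynamometry
  units: kg
  domain: {type: numeric, min: 0, max: 120}
  sex_conditional: true
  gap_policy: nearest-worse
  criteria:
    'X':
      male: {min: 30, min_open: true}
      female: {min: 18, min_open: true}
    'Y':
      male: {min: 27, max: 30}
      female: {min: 15, max: 18}
    'Z':
      male: {max: 27, max_open: true}
      female: {max: 15, max_open: true}
- name: s5q
  label: S5Q
  units: points
  domain: {type: numeric, min: 0, max: 5}
  gap_policy: nearest-worse
  criteria:
    'X': {min: 4, max: 5}
    'Y': {min: 3, max: 3}
    # printed as "< 2"; read as <= 2 so the 0-5 scale has no hole at 2
    'Z': {min: 0, max: 2}
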