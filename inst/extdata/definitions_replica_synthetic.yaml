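version: replica-synthetic-1
resources:
- id: sepsis_identify_bundle
  label: Synthetic identify bundle for sepsis
  category: consumable
- id: sepsis_treat_bundle
  label: Synthetic treat bundle for sepsis
  category: consumable
- id: sepsis_monitor_modify_bundle
  label: Synthetic monitor_modify bundle for sepsis
  category: consumable
- id: haemorrhage_treat_bundle
  label: Synthetic treat bundle for haemorrhage
  category: consumable
- id: haemorrhage_monitor_modify_bundle
  label: Synthetic monitor_modify bundle for haemorrhage
  category: consumable
- id: hypertension_identify_bundle
  label: Synthetic identify bundle for hypertension
  category: consumable
- id: hypertension_treat_bundle
  label: Synthetic treat bundle for hypertension
  category: consumable
- id: hypertension_monitor_modify_bundle
  label: Synthetic monitor_modify bundle for hypertension
  category: consumable
- id: retained_placenta_treat_bundle
  label: Synthetic treat bundle for retained_placenta
  category: consumable
- id: retained_placenta_monitor_modify_bundle
  label: Synthetic monitor_modify bundle for retained_placenta
  category: consumable
- id: incomplete_abortion_identify_bundle
  label: Synthetic identify bundle for incomplete_abortion
  category: consumable
- id: incomplete_abortion_treat_bundle
  label: Synthetic treat bundle for incomplete_abortion
  category: consumable
- id: incomplete_abortion_monitor_modify_bundle
  label: Synthetic monitor_modify bundle for incomplete_abortion
  category: consumable
- id: antibiotic_tracer_bundle
  label: Synthetic tracer bundle for antibiotic
  category: consumable
- id: uterotonic_tracer_bundle
  label: Synthetic tracer bundle for uterotonic
  category: consumable
- id: anticonvulsant_tracer_bundle
  label: Synthetic tracer bundle for anticonvulsant
  category: consumable
- id: retained_placenta_removal_tracer_bundle
  label: Synthetic tracer bundle for retained_placenta_removal
  category: consumable
- id: rpoc_removal_tracer_bundle
  label: Synthetic tracer bundle for rpoc_removal
  category: consumable
cascades:
- emergency: sepsis
  label: Sepsis—infection
  stages:
    identify:
      groups:
      - alternatives:
        - sepsis_identify_bundle
    treat:
      groups:
      - alternatives:
        - sepsis_treat_bundle
    monitor_modify:
      groups:
      - alternatives:
        - sepsis_monitor_modify_bundle
- emergency: haemorrhage
  label: Haemorrhage
  stages:
    identify:
      skill_only: yes
    treat:
      groups:
      - alternatives:
        - haemorrhage_treat_bundle
    monitor_modify:
      groups:
      - alternatives:
        - haemorrhage_monitor_modify_bundle
- emergency: hypertension
  label: Hypertensive emergency
  stages:
    identify:
      groups:
      - alternatives:
        - hypertension_identify_bundle
    treat:
      groups:
      - alternatives:
        - hypertension_treat_bundle
    monitor_modify:
      groups:
      - alternatives:
        - hypertension_monitor_modify_bundle
- emergency: retained_placenta
  label: Retained placenta
  stages:
    identify:
      skill_only: yes
    treat:
      groups:
      - alternatives:
        - retained_placenta_treat_bundle
    monitor_modify:
      groups:
      - alternatives:
        - retained_placenta_monitor_modify_bundle
- emergency: incomplete_abortion
  label: Incomplete abortion
  stages:
    identify:
      groups:
      - alternatives:
        - incomplete_abortion_identify_bundle
    treat:
      groups:
      - alternatives:
        - incomplete_abortion_treat_bundle
    monitor_modify:
      groups:
      - alternatives:
        - incomplete_abortion_monitor_modify_bundle
signal_functions:
- id: antibiotic
  label: Antibiotic
  type: medical_treatment
  emergency: sepsis
  tracer:
    groups:
    - alternatives:
      - antibiotic_tracer_bundle
- id: uterotonic
  label: Uterotonics
  type: medical_treatment
  emergency: haemorrhage
  tracer:
    groups:
    - alternatives:
      - uterotonic_tracer_bundle
- id: anticonvulsant
  label: Anticonvulsant
  type: medical_treatment
  emergency: hypertension
  tracer:
    groups:
    - alternatives:
      - anticonvulsant_tracer_bundle
- id: retained_placenta_removal
  label: Removal of retained placenta
  type: manual_procedure
  emergency: retained_placenta
  tracer:
    groups:
    - alternatives:
      - retained_placenta_removal_tracer_bundle
- id: rpoc_removal
  label: Removal of retained products of conception
  type: manual_procedure
  emergency: incomplete_abortion
  tracer:
    groups:
    - alternatives:
      - rpoc_removal_tracer_bundle
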