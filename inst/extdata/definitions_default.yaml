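# Default emergency obstetric readiness definitions.
#
# Reconstruction of the study resource lists from the published operational
# definitions and standard WHO BEmOC tracer/commodity lists: parenteral
# antibiotics operationalised as the three-step escalation sequence
# (ampicillin AND gentamicin AND metronidazole); uterotonic = oxytocin;
# anticonvulsant = magnesium sulfate (WHO first line); electrical power as
# proxy for refrigeration; electrical power or an operational flashlight as
# proxy for a light source. Proxies are extra alternatives inside a group.
# Stage 1 (identify) of the haemorrhage and retained-placenta cascades relies
# on staff skill alone and carries no commodities (skill_only).
#
# Assisted vaginal delivery is deliberately absent: its tracers are not
# measurable from this kind of commodity inventory. The engine accepts a
# user-supplied AVD cascade if one is added here.
version: default-2016-reconstructed-1

resources:
  - {id: ampicillin,        label: "Ampicillin, injectable",                 category: drug}
  - {id: gentamicin,        label: "Gentamicin, injectable",                 category: drug}
  - {id: metronidazole,     label: "Metronidazole, injectable",              category: drug}
  - {id: oxytocin,          label: "Oxytocin, injectable",                   category: drug}
  - {id: magnesium_sulfate, label: "Magnesium sulfate, injectable",          category: drug}
  - {id: calcium_gluconate, label: "Calcium gluconate (MgSO4 antidote)",     category: drug}
  - {id: diazepam,          label: "Diazepam, injectable",                   category: drug}
  - {id: iv_fluids,         label: "Intravenous crystalloid fluids",         category: drug}
  - {id: analgesic,         label: "Parenteral analgesic",                   category: drug}
  - {id: gloves,            label: "Sterile gloves",                         category: consumable}
  - {id: long_gloves,       label: "Long sterile (gauntlet) gloves",         category: consumable}
  - {id: syringes_needles,  label: "Syringes with needles",                  category: consumable}
  - {id: iv_infusion_set,   label: "IV infusion set with cannula",           category: consumable}
  - {id: urinary_catheter,  label: "Urinary catheter",                       category: consumable}
  - {id: urine_dipstick,    label: "Urine protein test strips",              category: consumable}
  - {id: thermometer,       label: "Thermometer",                            category: durable}
  - {id: bp_apparatus,      label: "Blood pressure apparatus",               category: durable}
  - {id: stethoscope,       label: "Stethoscope",                            category: durable}
  - {id: reflex_hammer,     label: "Patellar reflex hammer",                 category: durable}
  - {id: speculum,          label: "Vaginal speculum",                       category: durable}
  - {id: mva_kit,           label: "Manual vacuum aspiration kit",           category: durable}
  - {id: refrigeration,     label: "Refrigerator (cold chain)",              category: durable}
  - {id: electricity,       label: "Electrical power",                       category: durable}
  - {id: flashlight,        label: "Operational flashlight",                 category: durable}
  - {id: protocol_sepsis,              label: "Maternal sepsis management protocol",      category: protocol}
  - {id: protocol_haemorrhage,         label: "Postpartum haemorrhage protocol",          category: protocol}
  - {id: protocol_hypertension,        label: "Severe pre-eclampsia/eclampsia protocol",  category: protocol}
  - {id: protocol_retained_placenta,   label: "Retained placenta management protocol",    category: protocol}
  - {id: protocol_incomplete_abortion, label: "Post-abortion care protocol",              category: protocol}

cascades:
  - emergency: sepsis
    label: "Sepsis—infection"
    stages:
      identify:
        groups:
          - alternatives: [thermometer]
          - alternatives: [stethoscope]
          - alternatives: [gloves]
      treat:
        groups:
          - alternatives: [ampicillin]
          - alternatives: [gentamicin]
          - alternatives: [metronidazole]
          - alternatives: [syringes_needles]
          - alternatives: [iv_infusion_set]
          - alternatives: [iv_fluids]
          - alternatives: [gloves]
      monitor_modify:
        groups:
          - alternatives: [protocol_sepsis]
          - alternatives: [thermometer]
          - alternatives: [urinary_catheter]

  - emergency: haemorrhage
    label: "Haemorrhage"
    stages:
      identify:
        skill_only: true
      treat:
        groups:
          - alternatives: [oxytocin]
          - alternatives: [refrigeration, electricity]
            note: "electrical power as proxy for refrigeration (oxytocin cold chain)"
          - alternatives: [iv_infusion_set]
          - alternatives: [iv_fluids]
          - alternatives: [syringes_needles]
          - alternatives: [gloves]
      monitor_modify:
        groups:
          - alternatives: [protocol_haemorrhage]
          - alternatives: [urinary_catheter]
          - alternatives: [bp_apparatus]

  - emergency: hypertension
    label: "Hypertensive emergency"
    stages:
      identify:
        groups:
          - alternatives: [bp_apparatus]
          - alternatives: [urine_dipstick]
      treat:
        groups:
          - alternatives: [magnesium_sulfate]
          - alternatives: [calcium_gluconate]
          - alternatives: [syringes_needles]
          - alternatives: [gloves]
      monitor_modify:
        groups:
          - alternatives: [protocol_hypertension]
          - alternatives: [reflex_hammer]
          - alternatives: [urinary_catheter]

  - emergency: retained_placenta
    label: "Retained placenta"
    stages:
      identify:
        skill_only: true
      treat:
        groups:
          - alternatives: [long_gloves, gloves]
            note: "standard sterile gloves accepted where gauntlet gloves unavailable"
          - alternatives: [oxytocin]
          - alternatives: [iv_infusion_set]
          - alternatives: [iv_fluids]
          - alternatives: [analgesic, diazepam]
      monitor_modify:
        groups:
          - alternatives: [protocol_retained_placenta]
          - alternatives: [ampicillin]

  - emergency: incomplete_abortion
    label: "Incomplete abortion"
    stages:
      identify:
        groups:
          - alternatives: [speculum]
          - alternatives: [gloves]
          - alternatives: [electricity, flashlight]
            note: "electrical power or operational flashlight as proxy for a light source"
      treat:
        groups:
          - alternatives: [mva_kit]
          - alternatives: [analgesic, diazepam]
          - alternatives: [gloves]
      monitor_modify:
        groups:
          - alternatives: [protocol_incomplete_abortion]
          - alternatives: [oxytocin]

signal_functions:
  - id: antibiotic
    label: "Antibiotic"
    type: medical_treatment
    emergency: sepsis
    tracer:
      groups:
        - alternatives: [ampicillin]
        - alternatives: [gentamicin]
        - alternatives: [metronidazole]

  - id: uterotonic
    label: "Uterotonics"
    type: medical_treatment
    emergency: haemorrhage
    tracer:
      groups:
        - alternatives: [oxytocin]

  - id: anticonvulsant
    label: "Anticonvulsant"
    type: medical_treatment
    emergency: hypertension
    tracer:
      groups:
        - alternatives: [magnesium_sulfate]

  - id: retained_placenta_removal
    label: "Removal of retained placenta"
    type: manual_procedure
    emergency: retained_placenta
    tracer:
      groups:
        - alternatives: [long_gloves, gloves]
        - alternatives: [oxytocin]

  - id: rpoc_removal
    label: "Removal of retained products of conception"
    type: manual_procedure
    emergency: incomplete_abortion
    tracer:
      groups:
        - alternatives: [mva_kit]
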