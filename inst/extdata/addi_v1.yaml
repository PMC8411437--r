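name: ADDI
version: '1.0'
max_total: 27
categories:
- category_id: reproductive
  name: Reproductive
  max_points: 2
  item_ids:
  - sub_infertility
  - amenorrhea
- category_id: renal_amyloidosis
  name: Renal/amyloidosis
  max_points: 6
  item_ids:
  - amyloidosis
  - proteinuria
  - renal_insufficiency
- category_id: developmental
  name: Developmental
  max_points: 3
  item_ids:
  - growth_failure
  - puberty_delay
- category_id: serosal
  name: Serosal
  max_points: 1
  item_ids:
  - serosal_scarring
- category_id: neurological
  name: Neurological
  max_points: 6
  item_ids:
  - developmental_delay
  - cognitive_impairment
  - elevated_intracranial_pressure
  - cns_involvement
- category_id: ears
  name: Ears
  max_points: 2
  item_ids:
  - hearing_loss
- category_id: ocular
  name: Ocular
  max_points: 3
  item_ids:
  - ocular_involvement
- category_id: musculoskeletal
  name: Musculoskeletal
  max_points: 4
  item_ids:
  - joint_restriction
  - bone_deformity
  - osteoporosis
  - musculoskeletal_pain
items:
- item_id: sub_infertility
  name: Sub/infertility
  category_id: reproductive
  base_points: 2
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: A disease of the reproductive system defined by the failure to achieve
    a clinical pregnancy after 12 months or more of regular unprotected sexual intercourse,
    not due to known disorders in the unaffected partner.
- item_id: amenorrhea
  name: Amenorrhea
  category_id: reproductive
  base_points: 1
  levels: []
  pediatric_only: no
  applicable_sex: female_relevant
  criterion: 'Primary amenorrhea: absence of menarche at the age of 16 years or absence
    of menarche 5 years after thelarche. Secondary amenorrhea: absence of the menses
    for six consecutive months or more in a woman who previously had menstrual cycles.'
- item_id: amyloidosis
  name: Amyloidosis
  category_id: renal_amyloidosis
  base_points: 0
  levels:
  - label: limited
    points: 2
    criterion: Amyloidosis affecting one organ.
  - label: extensive
    points: 3
    criterion: Amyloidosis affecting more than one organ.
  pediatric_only: no
  applicable_sex: any
  criterion: Symptomatic amyloidosis confirmed by examination of tissue sections by
    Congo red dye or serum amyloid P component (SAP) scintigraphy.
- item_id: proteinuria
  name: Proteinuria
  category_id: renal_amyloidosis
  base_points: 1
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Persistent urinary protein-to-creatinine ratio of >20 mg/mmol in the
    first morning void; and/or a daily protein excretion of >0.3 g/24 hours, or urine
    albumin-to-creatinine ratio of >15 mg/mmol.
- item_id: renal_insufficiency
  name: Renal insufficiency
  category_id: renal_amyloidosis
  base_points: 0
  levels:
  - label: moderate
    points: 2
    criterion: Glomerular filtration rate (GFR) between 15 and 60 mL/min/1.73 m2.
  - label: severe
    points: 3
    criterion: GFR <15 mL/min/1.73 m2, dialysis or transplantation.
  pediatric_only: no
  applicable_sex: any
  criterion: Glomerular filtration rate (GFR) of <60 mL/min/1.73 m2, dialysis or transplantation.
- item_id: growth_failure
  name: Growth failure
  category_id: developmental
  base_points: 2
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: 'Presence of at least two of the three features: height lower than the
    third percentile or -2 SD for age; growth velocity over 6 months lower than the
    third percentile or -2 SD for age; crossing at least two centiles on the growth
    chart. For patients older than 18 years: pathological short stature.'
- item_id: puberty_delay
  name: Puberty delay
  category_id: developmental
  base_points: 1
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: A Tanner stage below -2 SDs for age or below the third percentile for
    age, or any Tanner stage after pharmacological induction of puberty.
- item_id: serosal_scarring
  name: Serosal scarring
  category_id: serosal
  base_points: 1
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Symptomatic adhesions or fibrosis affecting pericardium, pleura, peritoneum
    and/or retroperitoneum, supported by imaging techniques, endoscopy or surgery.
- item_id: developmental_delay
  name: Developmental delay
  category_id: neurological
  base_points: 2
  levels: []
  pediatric_only: yes
  applicable_sex: any
  criterion: Failure to reach age-appropriate developmental milestones, including
    language/speech, motor, social/emotional and cognitive milestones. Only for paediatric
    patients.
- item_id: cognitive_impairment
  name: Cognitive impairment
  category_id: neurological
  base_points: 3
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Requirement of special education because of cognitive impairment or IQ
    below 70 as defined by neuropsychological assessment.
- item_id: elevated_intracranial_pressure
  name: Elevated intracranial pressure
  category_id: neurological
  base_points: 2
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Signs and/or symptoms of elevated intracranial pressure supported by
    appropriate techniques such as funduscopy, neuroimaging or lumbar CSF pressure
    measurement.
- item_id: cns_involvement
  name: Central nervous system involvement
  category_id: neurological
  base_points: 3
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Focal deficits (gross and/or fine sensorimotor), diffuse deficits (eg,
    memory, behaviour), seizures and spinal cord symptoms. Neuropsychiatric disorders
    unrelated to the disease should not be scored.
- item_id: hearing_loss
  name: Hearing loss
  category_id: ears
  base_points: 0
  levels:
  - label: moderate
    points: 1
    criterion: Hearing impairment without requirement of hearing aids or a cochlear
      implant.
  - label: severe
    points: 2
    criterion: Hearing impairment requiring hearing aids or a cochlear implant.
  pediatric_only: no
  applicable_sex: any
  criterion: Sensorineural hearing impairment of better ear, confirmed by audiometry
    or another age-appropriate technique, or requirement of hearing aids or a cochlear
    implant.
- item_id: ocular_involvement
  name: Ocular involvement
  category_id: ocular
  base_points: 0
  levels:
  - label: mild
    points: 1
    criterion: Ocular damage without visual impairment.
  - label: moderate
    points: 2
    criterion: Ocular damage with visual impairment.
  - label: severe
    points: 3
    criterion: Legal blindness.
  pediatric_only: no
  applicable_sex: any
  criterion: Ocular damage (eg, optic nerve atrophy, elevated intraocular pressure
    or cataract) of better eye, documented by an ophthalmologist, with or without
    visual impairment.
- item_id: joint_restriction
  name: Joint restriction
  category_id: musculoskeletal
  base_points: 2
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Fixed limitation in the normal range of motion of joints affecting function,
    with or without destructive arthropathy or avascular necrosis.
- item_id: bone_deformity
  name: Bone deformity
  category_id: musculoskeletal
  base_points: 2
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Bone deformation or overgrowth on clinical examination and/or imaging
    studies.
- item_id: osteoporosis
  name: Osteoporosis
  category_id: musculoskeletal
  base_points: 1
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Reduced bone mineral density with vertebral collapse and/or pathological
    fractures confirmed with imaging. Requires both evidence of decreased bone density
    and fracture; 'low bone density' by itself is insufficient.
- item_id: musculoskeletal_pain
  name: Musculoskeletal pain
  category_id: musculoskeletal
  base_points: 1
  levels: []
  pediatric_only: no
  applicable_sex: any
  criterion: Non-inflammatory musculoskeletal pain impairing activities of daily living.
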