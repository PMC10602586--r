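infection_types:
  circulatory:
    label: Circulatory
    icd10:
    - I33.0
    - I38
    icd9: '421.0'
  digestive:
    label: Digestive
    icd10:
    - K65.0
    - K83.0
    icd9: '567.2'
  genitourinary:
    label: Genitourinary
    icd10:
    - N39.0
    - N10
    icd9:
    - '599.0'
    - '590.1'
  intestinal:
    label: Intestinal
    icd10:
    - A04.7
    - A09
    icd9:
    - '008.45'
    - '009.0'
  musculoskeletal:
    label: Musculoskeletal
    icd10:
    - M86.9
    - M00.9
    icd9:
    - '730.2'
    - '711.0'
  neurologic:
    label: Neurologic
    icd10:
    - G00.9
    - G04.2
    icd9: '320.9'
  other_bacterial:
    label: Other bacterial
    icd10:
    - A41
    - A49
    icd9:
    - 038
    - '041'
  respiratory:
    label: Respiratory
    icd10:
    - J18.9
    - J15
    icd9:
    - '486'
    - '482'
  skin:
    label: Skin
    icd10:
    - L03
    - L02
    icd9: '682'
  other:
    label: Other
    icd10:
    - B99.9
    - T81.4
    icd9: '999.39'
antibiotics:
- vancomycin
- piperacillin-tazobactam
- cefepime
- ceftriaxone
- levofloxacin
- meropenem
- ampicillin-sulbactam
- azithromycin
- metronidazole
- cefazolin
exclusions:
  cardiac_surgery:
    cpt:
    - '33510'
    - '33533'
    - '33405'
    icd9:
    - '36.10'
    - '36.11'
    icd10: []
  cardiogenic_shock:
    cpt: []
    icd9: '785.51'
    icd10: R57.0
  transplantation:
    cpt:
    - '50360'
    - '47135'
    - '33945'
    icd9: '996.80'
    icd10: T86.00
covid: U07.1
shock_codes:
  icd9:
  - '995.92'
  - '785.52'
  icd10:
  - R65.20
  - R65.21
ventilation:
  cpt:
  - '94002'
  - '94003'
  - '94004'
  - '94660'
  icd9:
  - '96.70'
  - '96.71'
  - '96.72'
  icd10:
  - 5A1935Z
  - 5A1945Z
  - 5A1955Z
icu:
  cpt:
  - '99291'
  - '99292'
vasopressors:
  norepinephrine:
  - norepinephrine
  - levophed
  conditional:
  - dobutamine
  - dopamine
stress_echo_cpt:
- '78452'
- '93015'
- '93016'
- '93017'
- '93018'
- '93351'
keywords:
- infection
- sepsis
- septic
severe_renal:
- N18.4
- N18.5
- N18.6
- N18.9
- '585.4'
- '585.5'
- '585.6'
- '585.9'
- '586'
- Z99.2
- Z49.0
- Z49.31
- '39.95'
- V45.11
- V56.0
charlson:
  myocardial_infarction:
    label: Myocardial infarction
    icd9:
    - '410'
    - '412'
    icd10:
    - I21
    - I22
    - I25.2
  congestive_heart_failure:
    label: Congestive heart failure
    icd9: '428'
    icd10: I50
  peripheral_vascular:
    label: Peripheral vascular disease
    icd9:
    - '440'
    - '441'
    - '443.9'
    icd10:
    - I70
    - I71
    - I73.9
  cerebrovascular:
    label: Cerebrovascular disease
    icd9:
    - '430'
    - '431'
    - '432'
    - '433'
    - '434'
    - '435'
    - '436'
    - '438'
    icd10:
    - I60
    - I61
    - I62
    - I63
    - I64
    - I65
    - I66
    - G45
  dementia:
    label: Dementia
    icd9: '290'
    icd10:
    - F00
    - F01
    - F02
    - F03
    - G30
  chronic_pulmonary:
    label: Chronic pulmonary disease
    icd9:
    - '490'
    - '491'
    - '492'
    - '493'
    - '494'
    - '495'
    - '496'
    icd10:
    - J40
    - J41
    - J42
    - J43
    - J44
    - J45
    - J46
    - J47
  rheumatic:
    label: Rheumatic disease
    icd9:
    - '714'
    - '710.0'
    - '710.1'
    icd10:
    - M05
    - M06
    - M32
    - M33
    - M34
  peptic_ulcer:
    label: Peptic ulcer disease
    icd9:
    - '531'
    - '532'
    - '533'
    - '534'
    icd10:
    - K25
    - K26
    - K27
    - K28
  mild_liver:
    label: Mild liver disease
    icd9:
    - '571.2'
    - '571.5'
    - '571.6'
    icd10:
    - B18
    - K73
    - K74
    - K76.0
  diabetes_uncomplicated:
    label: Diabetes without chronic complication
    icd9:
    - '250.0'
    - '250.1'
    - '250.2'
    - '250.3'
    icd10:
    - E10.9
    - E11.9
    - E13.9
  diabetes_complicated:
    label: Diabetes with chronic complication
    icd9:
    - '250.4'
    - '250.5'
    - '250.6'
    - '250.7'
    icd10:
    - E10.2
    - E10.3
    - E11.2
    - E11.3
    - E11.4
    - E11.5
  hemiplegia_paraplegia:
    label: Hemiplegia or paraplegia
    icd9:
    - '342'
    - '343'
    - '344'
    icd10:
    - G81
    - G82
    - G83
  renal_disease:
    label: Renal disease
    icd9:
    - '582'
    - '583'
    - '585'
    - '586'
    - V42.0
    - V45.1
    - V56
    icd10:
    - N03
    - N05
    - N18
    - N19
    - Z49
    - Z94.0
    - Z99.2
  malignancy:
    label: Malignancy, including lymphoma and leukemia, except malignant neoplasm
      of skin
    icd9:
    - '153'
    - '162'
    - '174'
    - '185'
    - '200'
    - '202'
    - '204'
    - '205'
    icd10:
    - C18
    - C34
    - C50
    - C61
    - C81
    - C85
    - C91
    - C92
  moderate_severe_liver:
    label: Moderate or severe liver disease
    icd9:
    - '456.0'
    - '456.1'
    - '456.2'
    - '572.2'
    - '572.3'
    - '572.4'
    icd10:
    - I85.0
    - I86.4
    - K70.4
    - K72.1
    - K72.9
    - K76.6
    - K76.7
  metastatic_tumor:
    label: Metastatic solid tumor
    icd9:
    - '196'
    - '197'
    - '198'
    - '199.0'
    icd10:
    - C77
    - C78
    - C79
    - C80.0
  aids_hiv:
    label: AIDS/HIV
    icd9: '042'
    icd10:
    - B20
    - B21
    - B22
    - B24
phecodes:
- phecode: 81.0
  label: Infection of internal prosthetic device
  icd9: '996.6'
  icd10: T85.7
  exclude_lo: 80.0
  exclude_hi: 82.0
  target: yes
- phecode: 38.0
  label: Septicemia
  icd9: 038
  icd10:
  - A40
  - A41
  exclude_lo: 38.0
  exclude_hi: 42.0
  target: yes
- phecode: 994.1
  label: Systemic inflammatory response syndrome (SIRS)
  icd9:
  - '995.90'
  - '995.93'
  - '995.94'
  icd10:
  - R65.10
  - R65.11
  exclude_lo: 994.0
  exclude_hi: 995.0
  target: yes
- phecode: 994.2
  label: Sepsis
  icd9: '995.91'
  icd10: R65.20
  exclude_lo: 994.0
  exclude_hi: 995.0
  target: yes
- phecode: 994.21
  label: Septic shock
  icd9:
  - '785.52'
  - '995.92'
  icd10: R65.21
  exclude_lo: 994.0
  exclude_hi: 995.0
  target: yes
- phecode: 41.0
  label: Bacterial infection NOS
  icd9: '041'
  icd10: A49
  exclude_lo: 38.0
  exclude_hi: 42.0
  target: no
- phecode: 80.0
  label: Other device/implant infection
  icd9: '996.7'
  icd10: T82.7
  exclude_lo: 80.0
  exclude_hi: 82.0
  target: no
- phecode: 994.0
  label: Sepsis/SIRS family NOS
  icd9: '995.99'
  icd10: R65.9
  exclude_lo: 994.0
  exclude_hi: 995.0
  target: no
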