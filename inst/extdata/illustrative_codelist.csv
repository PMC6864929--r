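code,system,category,site
I60,icd10,bleeding,intracranial
I61,icd10,bleeding,intracranial
I62,icd10,bleeding,intracranial
I71.3,icd10,bleeding,aortic_aneurysm_ruptured
I31.2,icd10,bleeding,haemopericardium
K25.0,icd10,bleeding,gastrointestinal
K26.0,icd10,bleeding,gastrointestinal
K62.5,icd10,bleeding,gastrointestinal
K92.2,icd10,bleeding,gastrointestinal
R04.0,icd10,bleeding,other_site
R31,icd10,bleeding,other_site
N93.9,icd10,bleeding,other_site
H11.3,icd10,bleeding,other_site
F001.,readlike,bleeding,intracranial
F002.,readlike,bleeding,intracranial
G401.,readlike,bleeding,haemopericardium
G402.,readlike,bleeding,aortic_aneurysm_ruptured
J120.,readlike,bleeding,gastrointestinal
J121.,readlike,bleeding,gastrointestinal
J122.,readlike,bleeding,gastrointestinal
R200.,readlike,bleeding,other_site
R201.,readlike,bleeding,other_site
K197.,readlike,bleeding,other_site
X33,opcs4,transfusion,
X34,opcs4,transfusion,
G45,opcs4,endoscopy,
G16,opcs4,endoscopy,
H22,opcs4,endoscopy,
H25,opcs4,endoscopy,
L67,opcs4,surgical_arrest_bleeding,
S47,opcs4,surgical_arrest_bleeding,
A05,opcs4,haematoma_evacuation,
D50,icd10,iron_deficiency_anaemia,
D000.,readlike,iron_deficiency_anaemia,
C18,icd10,cancer,
C34,icd10,cancer,
C50,icd10,cancer,
C61,icd10,cancer,
B100.,readlike,cancer,
K70,icd10,liver_disease,
K74,icd10,liver_disease,
J610.,readlike,liver_disease,
N18,icd10,renal_disease,
N19,icd10,renal_disease,
K050.,readlike,renal_disease,
I48,icd10,cvd_af,
G573.,readlike,cvd_af,
I21,icd10,cvd_mi,
I22,icd10,cvd_mi,
G300.,readlike,cvd_mi,
I20.0,icd10,cvd_ua,
G311.,readlike,cvd_ua,
I20.9,icd10,cvd_sa,
I25.1,icd10,cvd_sa,
G330.,readlike,cvd_sa,
bs01.,readlike,antithrombotic_aspirin,
bs02.,readlike,antithrombotic_aspirin,
bp01.,readlike,antithrombotic_adp,
bp02.,readlike,antithrombotic_adp,
ba01.,readlike,antithrombotic_vka,
ba02.,readlike,antithrombotic_vka,
E11,icd10,comorbidity_diabetes,
C100.,readlike,comorbidity_diabetes,
I63,icd10,comorbidity_stroke,
I64,icd10,comorbidity_stroke,
G660.,readlike,comorbidity_stroke,
I73.9,icd10,comorbidity_pad,
G730.,readlike,comorbidity_pad,
K27,icd10,comorbidity_peptic_ulcer,
J110.,readlike,comorbidity_peptic_ulcer,
D68,icd10,comorbidity_bleeding_diathesis,
44P0.,readlike,comorbidity_bleeding_diathesis,
D64,icd10,comorbidity_chronic_anaemia,
D210.,readlike,comorbidity_chronic_anaemia,
J44,icd10,other,
R99,icd10,other,
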