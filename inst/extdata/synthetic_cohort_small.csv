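patient_id,entry_context,ebl_ml,diagnosis,minutes_from_entry,pulse,sbp,dbp,died,end_organ_failure,icu_admission,transfusion_units,emergency_hysterectomy,age_years,parity
P001,tertiary,1000,uterine_atony,0,108,95,60,FALSE,FALSE,FALSE,2,FALSE,27,1
P001,tertiary,1000,uterine_atony,15,118,82,55,FALSE,FALSE,FALSE,2,FALSE,27,1
P001,tertiary,1000,uterine_atony,30,NP,88,58,FALSE,FALSE,FALSE,2,FALSE,27,1
P002,phc,800,ectopic,0,125,70,45,TRUE,FALSE,TRUE,6,FALSE,31,3
P002,phc,800,ectopic,15,132,64,40,TRUE,FALSE,TRUE,6,FALSE,31,3
P003,tertiary,900,retained_placenta,0,104,98,,FALSE,FALSE,FALSE,6,FALSE,24,2
P003,tertiary,900,retained_placenta,15,101,101,,FALSE,FALSE,FALSE,6,FALSE,24,2
P004,tertiary,1200,ruptured_uterus,0,115,85,50,FALSE,FALSE,FALSE,3,TRUE,35,4
P004,tertiary,1200,ruptured_uterus,15,110,90,55,FALSE,FALSE,FALSE,3,TRUE,35,4
P005,phc,600,abortion_complications,0,NP,NP,,FALSE,FALSE,FALSE,0,FALSE,22,0
P006,tertiary,1000,previa,0,112,88,57,,FALSE,FALSE,1,FALSE,29,2
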