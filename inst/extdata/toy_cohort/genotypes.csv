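patient_id,gene,allele1,allele2,quality_ok
T001,CYP2D6,*1,*1,TRUE
T001,CYP2C19,*1,*1,TRUE
T002,CYP2D6,*4,*4,TRUE
T002,CYP2C19,*1,*2,TRUE
T003,CYP2D6,*1,*4,TRUE
T003,CYP2C19,*17,*17,TRUE
T004,CYP2D6,*1,*41,TRUE
T004,CYP2C19,*1,*17,TRUE
T005,CYP2D6,*1,*1,FALSE
T005,CYP2C19,*2,*2,TRUE
T006,CYP2D6,*2,*41,TRUE
T006,CYP2C19,*1,*1,TRUE
T007,CYP2D6,*1,*1,TRUE
T007,CYP2C19,*1,*1,TRUE
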