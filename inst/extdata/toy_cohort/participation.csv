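patient_id,period,assessed
T001,1,TRUE
T001,2,TRUE
T001,3,TRUE
T001,4,TRUE
T001,5,TRUE
T001,6,TRUE
T001,7,TRUE
T001,8,TRUE
T001,9,TRUE
T001,10,TRUE
T001,11,TRUE
T002,1,TRUE
T002,2,TRUE
T002,3,TRUE
T002,4,TRUE
T002,5,TRUE
T002,6,TRUE
T002,7,TRUE
T002,8,TRUE
T002,9,TRUE
T002,10,TRUE
T002,11,TRUE
T003,1,TRUE
T003,2,TRUE
T003,3,TRUE
T003,4,TRUE
T003,5,TRUE
T003,6,TRUE
T003,7,TRUE
T003,8,TRUE
T003,9,TRUE
T003,10,TRUE
T003,11,TRUE
T004,1,TRUE
T004,2,TRUE
T004,3,TRUE
T004,4,TRUE
T004,5,FALSE
T004,6,FALSE
T004,7,FALSE
T004,8,FALSE
T004,9,FALSE
T004,10,FALSE
T004,11,FALSE
T005,1,TRUE
T005,2,TRUE
T005,3,TRUE
T005,4,TRUE
T005,5,TRUE
T005,6,TRUE
T005,7,TRUE
T005,8,TRUE
T005,9,TRUE
T005,10,TRUE
T005,11,TRUE
T006,1,TRUE
T006,2,TRUE
T006,3,TRUE
T006,4,TRUE
T006,5,TRUE
T006,6,TRUE
T006,7,TRUE
T006,8,TRUE
T006,9,TRUE
T006,10,TRUE
T006,11,TRUE
T007,1,TRUE
T007,2,TRUE
T007,3,TRUE
T007,4,TRUE
T007,5,TRUE
T007,6,TRUE
T007,7,TRUE
T007,8,TRUE
T007,9,TRUE
T007,10,TRUE
T007,11,TRUE
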