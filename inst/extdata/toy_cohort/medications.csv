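patient_id,period,atc
T001,1,N06AB05
T001,2,N06AB05
T001,3,N06AB05
T001,4,N06AB05
T001,5,N06AB05
T001,6,N06AB05
T001,7,N06AB05
T001,8,N06AB05
T001,9,N06AB05
T001,10,N06AB05
T002,2,N06AB04
T002,3,N06AB04
T002,6,N06AB03
T002,7,N06AB03
T002,8,N06AB03
T002,9,N06AB03
T002,10,N06AB03
T003,2,N06AB06
T003,3,N06AB06
T003,4,N06AB06
T004,1,N06AA09
T004,2,N06AA09
T004,3,N06AA09
T004,4,N06AA09
T005,3,N06AB04
T005,3,N06AX11
T006,1,N06AX16
T006,2,N06AX16
T006,3,N06AX16
T006,4,N06AX16
T006,5,N06AX16
T006,6,N06AX16
T006,7,N06AX16
T006,8,N06AX16
T006,6,N06AX11
T006,7,N06AX11
T006,8,N06AX11
T007,1,N06AB05
T007,2,N06AB05
T007,3,N06AB05
T007,4,N06AB05
T007,5,N06AB05
T007,6,N06AB05
T007,7,N06AB05
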