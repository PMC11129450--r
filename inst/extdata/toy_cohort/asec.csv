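patient_id,period,atc,item_01,item_02,item_03,item_04,item_05,item_06,item_07,item_08,item_09,item_10,item_11,item_12
T001,3,N06AB05,0,1,0,1,1,0,0,0,0,1,1,0
T001,5,N06AB05,0,1,1,0,0,1,0,0,1,1,0,0
T003,3,N06AB06,1,1,1,0,1,1,0,0,0,1,1,0
T006,7,N06AX16,1,0,1,1,0,1,1,1,1,1,0,0
T006,7,N06AX11,1,1,0,0,0,1,1,1,1,0,0,0
T007,5,N06AB05,1,0,1,1,0,1,1,1,0,1,0,0
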