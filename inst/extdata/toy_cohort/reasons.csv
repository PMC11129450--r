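patient_id,period,atc,reason
T007,7,N06AB05,symptom_free
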