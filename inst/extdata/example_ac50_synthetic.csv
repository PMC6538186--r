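chemical_id,assay_endpoint,ac50,hit_call,flags
EX-0001,ASSAY_01,3.2,TRUE,
EX-0001,ASSAY_02,0.8,TRUE,noisy
EX-0002,ASSAY_01,11.5,TRUE,
EX-0002,ASSAY_02,6.3,TRUE,
EX-0003,ASSAY_01,,FALSE,
EX-0003,ASSAY_02,1.9,TRUE,
EX-0004,ASSAY_01,45.0,TRUE,
EX-0005,ASSAY_02,0.2,TRUE,
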