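chemical_id,study_id,study_type,effect_category,effect_type,effect_target,dose,study_length
EX-0001,STUDY-1,chronic,systemic,pathology,liver,10,730
EX-0001,STUDY-1,chronic,systemic,pathology,liver,3,730
EX-0002,STUDY-2,subchronic,systemic,pathology,liver,25,90
EX-0003,STUDY-3,chronic,systemic,pathology,liver,8,730
EX-0004,STUDY-4,multigenerational,reproductive,clinical,body_weight,5,
EX-0005,STUDY-5,developmental,systemic,clinical,body_weight,1.5,21
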