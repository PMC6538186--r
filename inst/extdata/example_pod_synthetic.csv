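chemical_id,pod_type,dose,dose_units,study_type,route,duration_days
EX-0001,LOEL,5,mg/kg/day,chronic,oral,730
EX-0001,LOAEL,12,mg/kg/day,subchronic,oral,90
EX-0002,LOEL,30,mg/kg/day,chronic,oral,730
EX-0003,LOEL,0,mg/kg/day,chronic,oral,730
EX-0003,LOAEL,9,mg/kg/day,subacute,oral,28
EX-0005,LOEL,2,mg/kg/day,chronic,dermal,730
EX-0005,LOAEL,4,mg/kg/day,chronic,oral,730
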