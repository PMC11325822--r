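source_code,source_vocabulary_id,target_concept_id,target_concept_name,placeholder
female,Gender,8532,FEMALE,false
male,Gender,8507,MALE,false
other,Gender,0,No matching concept,false
unknown,Gender,0,No matching concept,false
positive,Meas Value,9191,Positive,false
negative,Meas Value,9189,Negative,false
unknown,Meas Value,0,No matching concept,false
C92.0,ICD10GM,2000000101,Acute myeloid leukemia (local),true
E05.0,ICD10GM,2000000102,Graves disease (local),true
E83.1,ICD10GM,2000000103,Hemochromatosis (local),true
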