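domain,kind,code,system,description,unit,low,high
endocrinology,lab,3016-3,LOINC,Thyrotropin serum,mU/L,0.01,50
endocrinology,lab,3024-7,LOINC,Free thyroxine serum,ng/dL,0.1,6
endocrinology,medication,H03AA01,ATC,Levothyroxine,,,
endocrinology,medication,H03BB02,ATC,Thiamazole,,,
endocrinology,procedure,5-061,OPS,Thyroid resection,,,
endocrinology,procedure,3-705,OPS,Thyroid scintigraphy,,,
gastroenterology,lab,1742-6,LOINC,Alanine aminotransferase serum,U/L,5,800
gastroenterology,lab,2276-4,LOINC,Ferritin serum,ug/L,10,3000
gastroenterology,medication,J05AF10,ATC,Entecavir,,,
gastroenterology,procedure,1-440,OPS,Endoscopic biopsy upper GI,,,
pneumonology,lab,6690-2,LOINC,Leukocytes blood,10*3/uL,1,50
pneumonology,lab,1988-5,LOINC,C reactive protein serum,mg/L,0.1,400
pneumonology,medication,J04AB02,ATC,Rifampicin,,,
pneumonology,procedure,3-202,OPS,CT of thorax,,,
hematology,lab,718-7,LOINC,Hemoglobin blood,g/dL,4,18
hematology,lab,777-3,LOINC,Platelets blood,10*3/uL,5,450
hematology,medication,L01BC01,ATC,Cytarabine,,,
hematology,procedure,8-800,OPS,Transfusion of red cells,,,
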