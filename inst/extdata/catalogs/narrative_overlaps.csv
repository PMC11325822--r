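group_set,symptom_name,hpo_code
Gastroenterology|Pneumonology|Endocrinology,Fever,HP:0001945
Gastroenterology|Pneumonology|Endocrinology,Diarrhea,HP:0002014
Gastroenterology|Pneumonology|Endocrinology,Fatigue,HP:0012378
Gastroenterology|Pneumonology|Endocrinology,Myalgia,HP:0003326
Pneumonology|Gastroenterology,Fatigue,HP:0012378
Pneumonology|Gastroenterology,Poor appetite,HP:0004396
Pneumonology|Gastroenterology,Fever,HP:0001945
Pneumonology|Gastroenterology,Icterus or Jaundice,HP:0000952
Pneumonology|Gastroenterology,Myalgia,HP:0003326
Pneumonology|Gastroenterology,Diarrhea,HP:0002014
Pneumonology|Gastroenterology,Nausea,HP:0002018
Pneumonology|Gastroenterology,Vomiting,HP:0002013
Pneumonology|Endocrinology,Fatigue,HP:0012378
Pneumonology|Endocrinology,Fever,HP:0001945
Pneumonology|Endocrinology,Malaise,
Pneumonology|Endocrinology,Myalgia,HP:0003326
Pneumonology|Endocrinology,Diarrhea,HP:0002014
Gastroenterology|Endocrinology,Fever,HP:0001945
Gastroenterology|Endocrinology,Fatigue,HP:0012378
Gastroenterology|Endocrinology,Myalgia,HP:0003326
Gastroenterology|Endocrinology,Diarrhea,HP:0002014
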