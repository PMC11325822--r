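rdcdm_module,omop_tables,vocabularies,default_table
Person,person,SNOMED;Gender,person
Diagnosis,condition_occurrence;procedure_occurrence;measurement;observation,SNOMED;ICD-10-GM;OrphaCode,condition_occurrence
Procedure,drug_exposure;procedure_occurrence;measurement;observation,SNOMED;OPS,procedure_occurrence
LaboratoryFindings,observation;measurement;procedure_occurrence,LOINC;UCUM,measurement
Medication,drug_exposure;observation,RxNorm;ATC,drug_exposure
Genotype,observation;measurement,OMOP Genomic,measurement
Phenotype,observation;measurement,HPO;SNOMED;LOINC,observation
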