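source_vocab,source_code,target_vocab,concept_code,concept_name,mapping_note
local_obs,systolic_bp,LOINC,8480-6,Systolic blood pressure,exact
local_obs,diastolic_bp,LOINC,8462-4,Diastolic blood pressure,exact
local_obs,heart_rate,LOINC,8867-4,Heart rate,exact
local_obs,bodyweight,LOINC,29463-7,Body weight,exact
local_obs,wellbeing,SNOMED-CT,365949003,Health-related finding,generic-concept
local_obs,medication_adherence,SNOMED-CT,418633004,Medication compliance,generic-concept
local_obs,clinical_note,LOINC,34109-9,Note,generic-concept
local_obs,telehealth_contact,SNOMED-CT,185317003,Telephone encounter,generic-concept
local_obs,date_of_death,SNOMED-CT,419620001,Death,exact
local_lab,ntprobnp,LOINC,33762-6,NT-proBNP,exact
local_lab,creatinine,LOINC,2160-0,Creatinine serum,exact
local_lab,potassium,LOINC,2823-3,Potassium serum,exact
icd10_source,I50.0,ICD-10,I50.0,Congestive heart failure,exact
icd10_source,I50.1,ICD-10,I50.1,Left ventricular failure,exact
icd10_source,I50.9,ICD-10,I50.9,Heart failure unspecified,exact
icd10_source,I25.9,ICD-10,I25.9,Chronic ischaemic heart disease,exact
icd10_source,I48.9,ICD-10,I48.9,Atrial fibrillation,exact
icd10_source,E11.9,ICD-10,E11.9,Type 2 diabetes mellitus,exact
ingredient,furosemide,ATC,C03CA01,furosemide,exact
ingredient,bisoprolol,ATC,C07AB07,bisoprolol,exact
ingredient,acetylsalicylic acid,ATC,B01AC06,acetylsalicylic acid,exact
ingredient,sacubitril/valsartan,ATC,C09DX04,sacubitril and valsartan,exact
ingredient,empagliflozin,ATC,A10BK03,empagliflozin,exact
ingredient,eplerenone,ATC,C03DA04,eplerenone,exact
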