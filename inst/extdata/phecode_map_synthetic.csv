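icd_code,vocabulary,phecode,phenotype,category
E11.9,ICD10CM,250.2,Type 2 diabetes,endocrine/metabolic
250.00,ICD9CM,250.2,Type 2 diabetes,endocrine/metabolic
E78.5,ICD10CM,272.1,Hyperlipidemia,endocrine/metabolic
272.4,ICD9CM,272.1,Hyperlipidemia,endocrine/metabolic
I10,ICD10CM,401.1,Essential hypertension,circulatory system
401.9,ICD9CM,401.1,Essential hypertension,circulatory system
I25.10,ICD10CM,411.4,Coronary atherosclerosis,circulatory system
414.01,ICD9CM,411.4,Coronary atherosclerosis,circulatory system
N18.9,ICD10CM,585.3,Chronic renal failure,genitourinary
585.9,ICD9CM,585.3,Chronic renal failure,genitourinary
N20.0,ICD10CM,592.1,Kidney stone,genitourinary
592.0,ICD9CM,592.1,Kidney stone,genitourinary
H25.9,ICD10CM,366.2,Senile cataract,sense organs
366.10,ICD9CM,366.2,Senile cataract,sense organs
H40.9,ICD10CM,365,Glaucoma,sense organs
365.9,ICD9CM,365,Glaucoma,sense organs
K31.84,ICD10CM,536.3,Gastroparesis,digestive
536.3,ICD9CM,536.3,Gastroparesis,digestive
K44.9,ICD10CM,550.2,Diaphragmatic hernia,digestive
553.3,ICD9CM,550.2,Diaphragmatic hernia,digestive
M86.9,ICD10CM,710.11,Acute osteomyelitis,musculoskeletal
730.00,ICD9CM,710.11,Acute osteomyelitis,musculoskeletal
M19.90,ICD10CM,740,Osteoarthrosis,musculoskeletal
715.90,ICD9CM,740,Osteoarthrosis,musculoskeletal
J96.90,ICD10CM,509.1,Respiratory failure,respiratory
518.81,ICD9CM,509.1,Respiratory failure,respiratory
J45.909,ICD10CM,495,Asthma,respiratory
493.90,ICD9CM,495,Asthma,respiratory
S91.309A,ICD10CM,871.3,Open wound of foot,injuries & poisonings
892.0,ICD9CM,871.3,Open wound of foot,injuries & poisonings
T81.9XXA,ICD10CM,939,Complications of surgical procedures,injuries & poisonings
998.9,ICD9CM,939,Complications of surgical procedures,injuries & poisonings
G47.00,ICD10CM,327.4,Insomnia,neurological
780.52,ICD9CM,327.4,Insomnia,neurological
G58.9,ICD10CM,351,Other peripheral nerve disorders,neurological
355.9,ICD9CM,351,Other peripheral nerve disorders,neurological
L97.909,ICD10CM,707.1,Chronic ulcer of skin,dermatologic
707.9,ICD9CM,707.1,Chronic ulcer of skin,dermatologic
L60.9,ICD10CM,703,Diseases of nail,dermatologic
703.9,ICD9CM,703,Diseases of nail,dermatologic
F17.200,ICD10CM,318,Tobacco use disorder,mental disorders
305.1,ICD9CM,318,Tobacco use disorder,mental disorders
F32.9,ICD10CM,296.2,Depression,mental disorders
311,ICD9CM,296.2,Depression,mental disorders
D63.1,ICD10CM,285.21,Anemia in chronic kidney disease,hematopoietic
285.21,ICD9CM,285.21,Anemia in chronic kidney disease,hematopoietic
D64.9,ICD10CM,282,Other anemias,hematopoietic
285.9,ICD9CM,282,Other anemias,hematopoietic
R60.9,ICD10CM,782.3,Edema,symptoms
782.3,ICD9CM,782.3,Edema,symptoms
R50.9,ICD10CM,780.6,Fever of unknown origin,symptoms
780.60,ICD9CM,780.6,Fever of unknown origin,symptoms
D12.6,ICD10CM,208,Benign neoplasm of colon,neoplasms
211.3,ICD9CM,208,Benign neoplasm of colon,neoplasms
C43.9,ICD10CM,172.2,Melanoma of skin,neoplasms
172.9,ICD9CM,172.2,Melanoma of skin,neoplasms
A08.4,ICD10CM,008,Intestinal infection,infectious diseases
008.8,ICD9CM,008,Intestinal infection,infectious diseases
A41.9,ICD10CM,038,Septicemia,infectious diseases
038.9,ICD9CM,038,Septicemia,infectious diseases
Q24.9,ICD10CM,747.1,Cardiac congenital anomalies,congenital anomalies
746.9,ICD9CM,747.1,Cardiac congenital anomalies,congenital anomalies
Q89.9,ICD10CM,758,Chromosomal anomalies,congenital anomalies
758.9,ICD9CM,758,Chromosomal anomalies,congenital anomalies
O24.419,ICD10CM,649.1,Diabetes complicating pregnancy,pregnancy complications
648.83,ICD9CM,649.1,Diabetes complicating pregnancy,pregnancy complications
O03.9,ICD10CM,634,Miscarriage,pregnancy complications
634.90,ICD9CM,634,Miscarriage,pregnancy complications
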