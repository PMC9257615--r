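code,description,ccsr_category,synonyms
I10,Essential primary hypertension,Essential hypertension,high blood pressure
I214,Non ST elevation myocardial infarction,Acute myocardial infarction,heart attack
I2510,Atherosclerotic heart disease of native coronary artery,Coronary atherosclerosis,coronary artery disease
I509,Heart failure unspecified,Heart failure,congestive heart failure
I639,Cerebral infarction unspecified,Cerebral infarction,stroke
I671,Cerebral aneurysm nonruptured,Cerebrovascular disease,brain aneurysm
E039,Hypothyroidism unspecified,Thyroid disorders,underactive thyroid
E1065,Type 1 diabetes mellitus with hyperglycemia,Diabetes mellitus with complication,type 1 diabetes
E119,Type 2 diabetes mellitus without complications,Diabetes mellitus without complication,type 2 diabetes
E669,Obesity unspecified,Obesity,
K219,Gastro esophageal reflux without esophagitis,Esophageal disorders,acid reflux
K359,Unspecified acute appendicitis,Appendicitis,
K5090,Crohn disease unspecified without complications,Inflammatory bowel disease,crohns disease
K7030,Alcoholic cirrhosis of the liver without ascites,Alcoholic liver disease,cirrhosis of the liver
K922,Gastrointestinal hemorrhage unspecified,Gastrointestinal hemorrhage,stomach bleeding
N179,Acute kidney failure unspecified,Acute renal failure,
N186,End stage renal disease,Chronic kidney disease,kidney failure
N200,Calculus of kidney,Nephrolithiasis,kidney stones
N390,Urinary tract infection site not specified,Urinary tract infections,urinary tract infection
N809,Endometriosis unspecified,Endometriosis,
A150,Pulmonary tuberculosis,Tuberculosis,tuberculosis
A419,Sepsis unspecified organism,Septicemia,sepsis
A6920,Lyme disease unspecified,Lyme disease,lyme disease
B182,Chronic viral hepatitis C,Chronic hepatitis,hepatitis c
B20,Human immunodeficiency virus disease,HIV infection,hiv infection
S0990,Unspecified injury of head,Head injury,head injury
S062X0,Diffuse traumatic brain injury,Traumatic brain injury,traumatic brain injury
S72001,Fracture of unspecified part of neck of femur,Hip fracture,broken hip
T300,Burn of unspecified body region,Burns,severe burns
V892,Person injured in motor vehicle accident,Motor vehicle traffic injury,car accident
F1020,Alcohol dependence uncomplicated,Alcohol related disorders,alcohol addiction
F329,Major depressive disorder single episode unspecified,Depressive disorders,severe depression
F419,Anxiety disorder unspecified,Anxiety disorders,anxiety disorder
F4310,Post traumatic stress disorder unspecified,Trauma and stressor related disorders,ptsd
M069,Rheumatoid arthritis unspecified,Rheumatoid arthritis,rheumatoid arthritis
M169,Osteoarthritis of hip unspecified,Osteoarthritis,arthritis of the hip
M545,Low back pain,Back problems,lower back pain
M5126,Intervertebral disc displacement lumbar region,Intervertebral disc disorders,herniated disc
C189,Malignant neoplasm of colon unspecified,Colorectal cancer,colon cancer
C50911,Malignant neoplasm of unspecified site of right female breast,Breast cancer,breast cancer
C50912,Malignant neoplasm of unspecified site of left female breast,Breast cancer,
C50919,Malignant neoplasm of unspecified site of unspecified female breast,Breast cancer,
C61,Malignant neoplasm of prostate,Prostate cancer,prostate cancer
C719,Malignant neoplasm of brain unspecified,Brain cancer,brain tumor
C9100,Acute lymphoblastic leukemia not having achieved remission,Leukemia,acute lymphoblastic leukemia
C9200,Acute myeloblastic leukemia not having achieved remission,Leukemia,myeloid leukemia
G20,Parkinsons disease,Parkinson disease,
G309,Alzheimers disease unspecified,Alzheimer disease,alzheimers
G35,Multiple sclerosis,Multiple sclerosis,
G40909,Epilepsy unspecified not intractable,Epilepsy,seizure disorder
G43909,Migraine unspecified not intractable,Migraine,chronic migraines
J189,Pneumonia unspecified organism,Pneumonia,pneumonia
J449,Chronic obstructive pulmonary disease unspecified,COPD,copd
J45909,Unspecified asthma uncomplicated,Asthma,asthma
J84112,Idiopathic pulmonary fibrosis,Interstitial lung disease,pulmonary fibrosis
J9601,Acute respiratory failure with hypoxia,Respiratory failure,respiratory failure
D649,Anemia unspecified,Anemia,
H269,Unspecified cataract,Cataract,
O80,Encounter for full term uncomplicated delivery,Uncomplicated delivery,
Q213,Tetralogy of Fallot,Congenital cardiovascular malformations,
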