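trait,probability,flagged_significant
Alanine aminotransferase,0.71,FALSE
Alkaline phosphatase,0.01,TRUE
Amylase,<0.01,TRUE
Aspartate aminotransferase,0.56,FALSE
Basophils,0.16,FALSE
Bicarbonate,0.71,FALSE
Blood urea nitrogen,0.03,FALSE
Body temperature,0.55,FALSE
Calcium,0.63,FALSE
Carbon dioxide,0.31,FALSE
Chloride,0.60,FALSE
Cholesterol,0.73,FALSE
Creatine phosphokinase,0.01,TRUE
Creatinine,0.72,FALSE
Eosinophils,0.64,FALSE
Gamma glutamyltransferase,0.74,FALSE
Glucose,0.37,FALSE
Haematocrit,0.01,TRUE
Haemoglobin,0.23,FALSE
Indirect bilirubin,0.20,FALSE
Iron,0.94,FALSE
Lactate dehydrogenase,0.20,FALSE
Lipase,0.06,FALSE
Lymphocytes,0.85,FALSE
Magnesium,0.49,FALSE
MCH,0.08,FALSE
MCHC,<0.01,TRUE
MCV,0.12,FALSE
Monocytes,0.02,TRUE
Neutrophilic bands,<0.01,TRUE
Osmolarity,0.92,FALSE
Phosphorus,0.01,TRUE
Platelet count,0.84,FALSE
Potassium,0.93,FALSE
Red blood cell count,0.27,FALSE
Segmented neutrophils,0.08,FALSE
Sodium,0.38,FALSE
Total bilirubin,0.31,FALSE
Triglyceride,0.18,FALSE
Uric acid,0.19,FALSE
White blood cell count,0.07,FALSE
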