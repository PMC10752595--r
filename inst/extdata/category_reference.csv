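category,description,odds_ratio,precision,recall,f1
PROT-A,Care plan,0.22,1.00,1.00,1.00
PROT-B,Senior healthcare professional role,0.32,0.60,1.00,0.75
PROT-C,Chronic physical comorbidity / symptom,0.50,0.67,0.44,0.53
PROT-D,Treatment for drug addiction or depot treatment,0.55,1.00,0.80,0.89
PROT-E,Food/meals/activities,0.57,0.95,0.88,0.91
PROT-F,Positive connotations,0.58,0.56,0.75,0.64
PROT-G,Items used on ward,0.58,0.80,0.89,0.84
RISK-H,Items of clothing,1.54,1.00,0.89,0.94
RISK-I,Subheadings of clerking/diagnosis/psychiatric symptoms,1.62,0.77,0.80,0.79
RISK-J,Interventions,1.62,0.75,0.62,0.68
RISK-K,Time- or life event- or person/relationship-related,1.63,0.89,0.93,0.91
RISK-L,"Suicide ""risk"" terms and formal clinical distancing language",1.64,0.79,0.79,0.79
RISK-M,Implement/mechanism of self-harm or suicide attempt,1.72,0.79,0.93,0.86
RISK-N,Negative connotations/judgemental language,1.72,0.86,0.63,0.73
RISK-O,Physical symptom or sign,1.84,0.60,0.67,0.63
RISK-P,Junior or multidisciplinary healthcare professional role,1.85,1.00,0.78,0.88
RISK-Q,Prescribed medications/drugs/overdose/poisoning/addiction,1.88,0.91,0.93,0.92
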