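intervention_id,cause,effectiveness,affected_fraction
act_malaria,malaria,0.97,0.80
itn_irs,malaria,0.55,0.90
ors_diarrhea,diarrhea,0.93,0.90
zinc_diarrhea,diarrhea,0.23,0.90
antibiotics_pneumonia,pneumonia,0.70,0.85
breastfeeding,diarrhea,0.32,0.45
breastfeeding,pneumonia,0.25,0.40
iptp,neonatal,0.35,0.30
vitamin_a,diarrhea,0.23,0.50
vitamin_a,other,0.12,0.20
labor_delivery,neonatal,0.40,0.45
immediate_assessment,neonatal,0.30,0.25
clean_birth,neonatal,0.25,0.30
syphilis_treatment,neonatal,0.50,0.05
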