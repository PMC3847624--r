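intervention_id,source,year,coverage_percent
ors_diarrhea,DHS2003,2003,12
ors_diarrhea,MICS2006,2006,17
antibiotics_pneumonia,MICS2006,2006,21
zinc_diarrhea,MICS2006,2006,0
breastfeeding,DHS2003,2003,19
itn_irs,MICS2006,2006,24
labor_delivery,DHS2003,2003,50
iptp,MICS2006,2006,30
vitamin_a,MICS2006,2006,92
immediate_assessment,DHS2003,2003,42
clean_birth,DHS2003,2003,46
syphilis_treatment,MICS2006,2006,15
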