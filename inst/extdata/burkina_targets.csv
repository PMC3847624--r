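intervention_id,target_percent
act_malaria,70
ors_diarrhea,60
antibiotics_pneumonia,60
zinc_diarrhea,60
breastfeeding,38
itn_irs,70
labor_delivery,79
iptp,70
vitamin_a,90
immediate_assessment,58
clean_birth,64
syphilis_treatment,64
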