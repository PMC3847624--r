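intervention_id,baseline_percent
act_malaria,26
ors_diarrhea,23
antibiotics_pneumonia,33
zinc_diarrhea,4
breastfeeding,33
itn_irs,64
labor_delivery,71
iptp,38
vitamin_a,89
immediate_assessment,56
clean_birth,60
syphilis_treatment,23
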