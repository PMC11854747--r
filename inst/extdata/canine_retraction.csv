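tooth_id,patient_sex,total_length,slot_to_cusp,slot_to_gingiva,gingiva_to_apex,fi1,fint1,y_crown_ca1,y_apex_ca1,fi2,fint2,y_crown_ca2,y_apex_ca2
C1,male,31,5,4.5,21.5,220,100,0.8,0.7,210,90,0.8,0.6
C2,male,30,5,4.5,20.5,230,110,0.8,0.7,210,85,0.9,0.6
C3,female,29.5,4.5,4.5,20.5,210,90,0.9,0.7,200,80,0.9,0.6
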