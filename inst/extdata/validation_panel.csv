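molecule_id,exp_conc_mg_ml,experimental_cP,acsins_expconc_cP,dls_expconc_cP,performance_expconc,acsins_150_cP,dls_150_cP,performance_150
V_1,154,25.9,11.5,23.6,TRUE,10.4,21.0,TRUE
V_2,143,34.2,12.8,17.5,False positive,15.7,21.6,TRUE
V_3,159,13.4,20.0,24.1,False negative,15.6,18.7,TRUE
V_4,158,10.6,19.9,14.5,TRUE,15.9,11.7,TRUE
V_5,152,8.1,14.3,12.7,TRUE,13.6,12.0,TRUE
V_6,154,9.1,14.6,14.6,TRUE,13.1,13.1,TRUE
V_7,165,42.5,22.1,21.8,TRUE,14.7,14.5,False positive
V_8,144,10.5,12.6,10.2,TRUE,15.0,12.1,TRUE
V_9,135,42.1,9.8,12.1,False positive,15.4,19.1,False positive
V_10,153,9.9,14.5,12.6,TRUE,13.4,11.6,TRUE
V_11,157,20.1,19.2,17.7,False positive,15.8,14.6,False positive
V_12,157,13.8,18.2,11.3,TRUE,15.0,9.4,TRUE
V_13,156,15,17.8,15.9,TRUE,15.1,13.5,TRUE
V_14,150,10,15.6,13.0,TRUE,15.6,13.0,TRUE
V_15,142,30.1,10.4,17.1,False positive,13.1,21.8,TRUE
V_16,160,10.9,15.5,17.5,TRUE,11.9,13.3,TRUE
V_17,152,9.1,15.2,11.4,TRUE,14.4,10.8,TRUE
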