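molecule_id,experimental_cP,acsins_cP,dls_cP,performance
Te_1,16.5,15.5,17.8,TRUE
Te_2,44,15.6,19.3,False positive
Te_3,8.8,15.8,10.4,TRUE
Te_4,49.3,15.2,14.4,False positive
Te_5,7.9,8.3,8.4,TRUE
Te_6,9.7,9.0,15.8,TRUE
Te_7,13.1,10.7,14.7,TRUE
Te_8,10.1,7.8,14.8,TRUE
Te_9,13.9,12.1,15.2,TRUE
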