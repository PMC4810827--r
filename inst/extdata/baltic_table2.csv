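configuration,offshore_1980s,offshore_2000s,coast_1980s,coast_2000s,sig_offshore_1980s,sig_offshore_2000s,sig_coast_1980s,sig_coast_2000s
arc,-5.1398,-5.7522,-11.3957,-12.0156,FALSE,TRUE,TRUE,TRUE
generalist,1.8165,2.1638,4.0303,4.5274,TRUE,TRUE,TRUE,TRUE
highly_predated,0.959,0.7339,2.164,2.0822,FALSE,FALSE,TRUE,TRUE
keystone,2.3523,2.2518,2.8967,3.6722,TRUE,TRUE,TRUE,TRUE
omnivory,0.2981,0.2741,-0.1033,-0.1157,FALSE,FALSE,FALSE,FALSE
tri_trophic,-0.702,-0.617,-0.3501,-0.4182,TRUE,TRUE,TRUE,TRUE
apparent_competition,-0.1096,-0.1099,-0.1779,-0.2373,FALSE,FALSE,TRUE,TRUE
exploitative_competition,NA,NA,NA,-0.0888,NA,NA,NA,TRUE
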