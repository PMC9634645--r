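population_id,ecotype,valley,date,duration_h,n_flowers_filmed,n_flowers_visited,n_moths,visits_per_h,moths_per_h
Del_Ca,Ca,Viroin,2019-06-01,7.25,34,1,1,0.14,0.14
Lom_Ca,Ca,Viroin,2019-05-31,2.17,40,1,1,0.46,0.46
Coi_Ca,Ca,Ourthe,2020-05-19,2.83,78,0,0,0,0
Coi_Ca,Ca,Ourthe,2020-05-20,2.83,58,4,2,1.41,0.71
Sy_Ca,Ca,Ourthe,2020-05-19,2.75,51,0,0,0,0
Sy_Ca,Ca,Ourthe,2020-05-20,4.58,85,16,7,3.49,1.53
Nes_Si,Si,Viroin,2019-05-31,7.67,28,0,1,0,0.13
Rav_Si,Si,Viroin,2019-06-01,7.5,15,12,7,1.6,0.93
Ham_Si,Si,Ourthe,2020-05-19,5.83,73,20,10,3.43,1.72
Ham_Si,Si,Ourthe,2020-05-20,2.67,35,10,6,3.75,2.25
Tom_Si,Si,Ourthe,2019-06-07,7.08,27,11,6,1.55,0.85
Tom_Si,Si,Ourthe,2020-05-19,2.75,69,0,0,0,0
Tom_Si,Si,Ourthe,2020-05-20,5.25,55,18,3,3.43,0.57
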