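population_id,ecotype,year,valley,Noctuidae,Coleophora,Coleoptera,Diptera_Delia,gall
Lom_Ca,Ca,2019,Viroin,7,0,0,0,0
Lom_Ca,Ca,2020,Viroin,2,0,0,0,0
Del_Ca,Ca,2019,Viroin,4,0,3,0,0
Sy_Ca,Ca,2020,Ourthe,1,0,0,0,0
Coi_Ca,Ca,2020,Ourthe,6,0,0,0,0
Nes_Si,Si,2019,Viroin,5,2,8,25,20
Nes_Si,Si,2020,Viroin,3,1,2,0,0
Rav_Si,Si,2019,Viroin,6,0,7,7,1
Rav_Si,Si,2020,Viroin,7,1,4,0,0
Tom_Si,Si,2019,Ourthe,8,34,0,1,0
Tom_Si,Si,2020,Ourthe,5,2,5,1,1
Ham_Si,Si,2019,Ourthe,18,0,0,0,0
Ham_Si,Si,2020,Ourthe,18,0,3,0,0
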