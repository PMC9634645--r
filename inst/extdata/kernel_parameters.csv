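population_id,ecotype,valley,morans_i,morans_significant,alpha,beta,delta_k,gamma,gamma_p_upper
Del_Ca,Ca,Viroin,0.01,FALSE,0.0001,0.20,18.1,-0.275,0.031
Rav_Si,Si,Viroin,0.10,FALSE,28.9,0.83,87.7,-0.477,0.001
Nes_Si,Si,Viroin,-0.01,FALSE,388.0,2.98,287.0,-0.393,0.001
Lom_Ca,Ca,Viroin,-0.01,FALSE,0.0001,0.16,2642.0,-0.441,0.001
Coi_Ca,Ca,Ourthe,0.52,TRUE,5.1,0.73,21.9,-0.456,0.001
Ham_Si,Si,Ourthe,-0.04,FALSE,99.3,1.08,173.0,-0.347,0.005
Tom_Si,Si,Ourthe,0.05,FALSE,NA,NA,NA,-0.011,0.923
Sy_Ca,Ca,Ourthe,0.23,TRUE,1.8,0.39,160.0,-0.480,0.001
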