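sample_id,accession,seq_length,location,state,source,type,species,group,class,avg_distance,pct_coverage,pct_identity
IIL04,MG703512,650,Itajai,SC,market,fresh,Carcharhinus brachyurus,Carcharhiniformes,elasmobranch,0.001,98,99
IIL05,MG703513,650,Itajai,SC,market,fresh,Carcharhinus brachyurus,Carcharhiniformes,elasmobranch,0.001,97,99
IIL14,MG703514,650,Itajai,SC,market,fresh,Carcharhinus brachyurus,Carcharhiniformes,elasmobranch,0.001,98,99
IIL04-2,MG703515,642,Itajai,SC,market,fresh,Carcharhinus falciformis,Carcharhiniformes,elasmobranch,0.003,98,99
IIL27,MG703516,650,Itajai,SC,market,fresh,Carcharhinus falciformis,Carcharhiniformes,elasmobranch,0.003,99,99
FA08,MG703517,650,Porto Alegre,RS,market,fresh,Galeorhinus galeus,Carcharhiniformes,elasmobranch,0.001,95,99
MP60,MG703518,650,Porto Alegre,RS,market,fresh,Genidens barbus,Siluriformes,teleost,,96,100
E14,MG703519,615,Arroio do Sal,RS,vessel,fresh,Gymnura altavela,Myliobatiformes,elasmobranch,0.020,99,99
IIL37,MG703520,650,Laguna,SC,market,fresh,Gymnura altavela,Myliobatiformes,elasmobranch,0.021,98,99
IIL36,MG703521,650,Laguna,SC,market,fresh,Myliobatis goodei,Myliobatiformes,elasmobranch,0.013,96,99
E13,MG703522,650,Torres,RS,vessel,fresh,Narcine brasiliensis,Torpediniformes,elasmobranch,0.003,99,99
IIL15,MG703523,650,Itajai,SC,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.001,99,99
IIL30,MG703524,650,Imbituba,SC,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,99,99
IIL31,MG703525,613,Imbituba,SC,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,100,100
IIL34,MG703526,650,Imbituba,SC,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,100,99
IIL35,MG703527,621,Imbituba,SC,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,100,99
O22,MG703528,607,Florianopolis,SC,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,97,100
FA02,MG703529,523,Tramandai,RS,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.002,100,99
FA03,MG703530,611,Tramandai,RS,market,fresh,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,96,100
FA23,MG703531,641,Porto Alegre,RS,market,frozen,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,99,100
FA24,MG703532,588,Porto Alegre,RS,market,frozen,Prionace glauca,Carcharhiniformes,elasmobranch,0.002,100,99
FA25,MG703533,612,Porto Alegre,RS,market,frozen,Prionace glauca,Carcharhiniformes,elasmobranch,0.003,100,99
FA26,MG703534,634,Porto Alegre,RS,market,frozen,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,100,100
FA27,MG703535,526,Porto Alegre,RS,market,frozen,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,100,99
FA29,MG703536,556,Porto Alegre,RS,market,frozen,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,100,100
FA31,MG703537,527,Porto Alegre,RS,market,frozen,Prionace glauca,Carcharhiniformes,elasmobranch,0.000,100,99
IIL26,MG703538,650,Itajai,SC,market,fresh,Rajiformes sp. BOLD AABB,Rajiformes,elasmobranch,0.000,96,100
E34,MG703539,650,Torres,RS,vessel,fresh,Pseudobatos horkelii,Rhinopristiformes,elasmobranch,0.003,97,100
E36,MG703540,610,Torres,RS,vessel,fresh,Pseudobatos horkelii,Rhinopristiformes,elasmobranch,0.002,98,100
E26,MG703541,650,Ararangua,SC,vessel,fresh,Rhizoprionodon lalandii,Carcharhiniformes,elasmobranch,0.001,94,100
IIL13,MG703542,521,Itajai,SC,market,fresh,Rhizoprionodon lalandii,Carcharhiniformes,elasmobranch,0.001,99,99
FA05,MG703543,590,Imbe,RS,market,fresh,Rhizoprionodon lalandii,Carcharhiniformes,elasmobranch,0.001,91,99
FA17,MG703544,512,Porto Alegre,RS,market,fresh,Rhizoprionodon lalandii,Carcharhiniformes,elasmobranch,0.001,100,99
O24,MG703545,650,Florianopolis,SC,market,fresh,Rhizoprionodon porosus,Carcharhiniformes,elasmobranch,0.001,95,100
E07,MG703546,519,Tramandai,RS,vessel,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.024,100,100
E08,MG703547,650,Tramandai,RS,vessel,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.021,98,99
E15,MG703548,619,Arroio do Sal,RS,vessel,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.022,97,100
E44,MG703549,650,Tramandai,RS,vessel,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.021,97,99
MG04,MG703550,650,Rio Grande,RS,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.034,97,99
MP55,MG703551,534,Porto Alegre,RS,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.024,100,99
MP57,MG703552,542,Porto Alegre,RS,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.023,97,100
MP58,MG703553,621,Porto Alegre,RS,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.022,97,100
O06,MG703554,608,Passo de Torres,SC,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.022,97,99
O07,MG703555,628,Passo de Torres,SC,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.021,97,100
O08,MG703556,612,Passo de Torres,SC,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.022,98,100
O09,MG703557,534,Passo de Torres,SC,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.024,100,99
O27,MG703558,534,Florianopolis,SC,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.024,100,100
O29,MG703559,650,Florianopolis,SC,market,fresh,Sphyrna lewini,Carcharhiniformes,elasmobranch,0.021,99,100
O28,MG703560,463,Florianopolis,SC,market,fresh,Sphyrna zygaena,Carcharhiniformes,elasmobranch,0.000,100,99
FA21,MG703561,642,Porto Alegre,RS,market,fresh,Sphyrna zygaena,Carcharhiniformes,elasmobranch,0.001,100,100
MP15,MG703562,630,Porto Alegre,RS,market,fresh,Squalus cubensis,Squaliformes,elasmobranch,0.000,98,100
MP18,MG703563,603,Porto Alegre,RS,market,fresh,Squalus mitsukurii,Squaliformes,elasmobranch,0.001,98,100
MP16,MG703564,641,Porto Alegre,RS,market,fresh,Squalus mitsukurii,Squaliformes,elasmobranch,0.001,96,100
FA16,MG703565,593,Porto Alegre,RS,market,fresh,Squatina guggenheim,Squatiniformes,elasmobranch,0.001,96,100
MG08,MG703566,204,Rio Grande,RS,market,fresh,Squatina occulta,Squatiniformes,elasmobranch,0.000,95,100
IIL01,MG703567,650,Itajai,SC,market,frozen,Xiphias gladius,Perciformes,teleost,,100,99
IIL03,MG703568,650,Itajai,SC,market,frozen,Xiphias gladius,Perciformes,teleost,,100,99
IIL16,MG703569,650,Itajai,SC,market,frozen,Xiphias gladius,Perciformes,teleost,,100,99
IIL18,MG703570,589,Itajai,SC,market,frozen,Xiphias gladius,Perciformes,teleost,,100,99
IIL19,MG703571,458,Itajai,SC,market,frozen,Xiphias gladius,Perciformes,teleost,,100,100
IIL25,MG703572,622,Itajai,SC,market,frozen,Xiphias gladius,Perciformes,teleost,,100,100
E50,MG703573,650,Passo de Torres,SC,vessel,fresh,Zapteryx brevirostris,Rhinopristiformes,elasmobranch,0.030,97,99
E54,MG703574,232,Passo de Torres,SC,vessel,fresh,Zapteryx brevirostris,Rhinopristiformes,elasmobranch,0.000,100,100
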