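compound,use_class,pP,pB,pvB,pM_conservative,pvM_conservative,pM_eu2023,pvM_eu2023,pT,printed_conservative,printed_eu2023
"2-ethylidene-1,5-dimethyl-3,3-diphenylpyrrolidine (EDDP)",OIDM,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,PBT,PBT
Atrazine,HERB,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,PMT,PMT
Chloramphenicol,ANTB,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,PMT,PMT
Citalopram,PDAM,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,PMT,
Clopidogrel,APLM,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,PMT,
Desmethylcitalopram,PDAM,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,PMT,
Lorazepam,SHA,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,PMT,PMT
Lormetazepam,PDAM,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,PMT,PMT
Methadone,OIDM,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,PMT,
Miconazole,ANTB,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,PBT,PBT
Nafronyl,AHCV,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,PBT,PBT
Norsertraline,PDAM,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,PBT,PBT
Olanzapine,PDAM,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,PMT,
Sertraline,PDAM,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,PBT,PBT
Sulfachloropyridazine,ANTB,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,PMT,PMT
Triclocarban,ANTB,TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,PBT+PMT,PBT
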