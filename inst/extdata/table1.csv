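pair_id,galler_name,n_galler,host_age_galler,nongaller_name,n_nongaller,host_age_nongaller,age_note
Euurina,Euurina,400,58,Nematus melanaspis-group,25,94,
Bacconematus,Bacconematus,1,35,Eitelius,2,35,
Pristolina,Pristolina,4,0,Pristicampus,3,0,
Micronematus,Micronematus,1,70,Pristiphora subgenus Sala,30,114,*
Kladothrips,Kladothrips,24,0,Rhopalothripoides,6,0,
Cynipidae,gall-inducing Cynipidae + Synergini,1369,144,Figitidae (in part): Charpinae; Anacharitinae; Figitinae; Aspicerinae,435,300,
Agaonidae,Agaonidae + Otitesellinae,690,60,Sycoryctinae,121,60,
Eurostina,Eurostina,41,0,Euaresta,46,0,
Oedapidina,Oedapidina,88,42,Tephrellini,210,45,
Hexomyza,Hexomyza,16,144,Ophiomyia + Tropicomyia,282,144,
Apiomorpha,Apiomorpha,150,65,Ourococcus,3,104,
Maskellia,Maskellia,2,65,Aspidiotini; Pseudaonidina; Odonaspidini; non-pupillarial Parlatorini,874,366,
Cerataphidini,Cerataphidini,73,0,Thelaxes (Thelaxinae),4,0,
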