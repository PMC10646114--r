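site,site_type,chronology_cal_bc,mni,skeletal_piece,n_observed,n_with_leh,leh_frequency_percent
Moita do Sebastiao,open air,6360-5350,85,skull,20,14,70
Cabeco da Arruda,open air,6270-4840,110,skull,64,26,41
Cova da Onca,open air,5880-5000,32,skull,21,4,19
Cabeco da Amoreira,open air,5830-4720,29,skull,7,2,29
Caldeirao,cave,5470-3540,16,tooth 33,4,3,75
Escoural,cave,4238-2626,109,tooth 33,36,24,67
Sobreira I,dolmen,3640-3380,6,permanent teeth,5 teeth / 21,2,33.3
Carrascal,dolmen,3650-3350,14,permanent teeth,8 teeth / 97,3,30
Ansiao,dolmen,3637-3094,37,tooth 22,13,2,15
Pedras Grandes,dolmen,3510-3100,13,permanent teeth,13 teeth / 55,3,23
Perdigoes Tomb I (tooth 13),tholos,2870-2460,103,tooth 13,43,7,16
Perdigoes Tomb I (tooth 43),tholos,2870-2460,103,tooth 43,24,10,42
Perdigoes Tomb II Chamber,tholos,2860-2200,30,permanent teeth,2 teeth / 266,1,0.4
Perdigoes Tomb II Atrium,tholos,2860-2200,26,permanent teeth,3 teeth / 212,1,0.5
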