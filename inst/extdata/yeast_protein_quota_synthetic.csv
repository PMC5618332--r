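species,coefficient,weight,byproduct
Ala_tRNA,0.4588,0.08909,tRNA_Ala
Arg_tRNA,0.1607,0.17420,tRNA_Arg
Asn_tRNA,0.1017,0.13212,tRNA_Asn
Asp_tRNA,0.2975,0.13310,tRNA_Asp
Cys_tRNA,0.0066,0.12116,tRNA_Cys
Gln_tRNA,0.1054,0.14615,tRNA_Gln
Glu_tRNA,0.3018,0.14713,tRNA_Glu
Gly_tRNA,0.2904,0.07507,tRNA_Gly
His_tRNA,0.0663,0.15515,tRNA_His
Ile_tRNA,0.1927,0.13117,tRNA_Ile
Leu_tRNA,0.2964,0.13117,tRNA_Leu
Lys_tRNA,0.2862,0.14619,tRNA_Lys
Met_tRNA,0.0507,0.14921,tRNA_Met
Phe_tRNA,0.1339,0.16519,tRNA_Phe
Pro_tRNA,0.1647,0.11513,tRNA_Pro
Ser_tRNA,0.1854,0.10509,tRNA_Ser
Thr_tRNA,0.1914,0.11912,tRNA_Thr
Trp_tRNA,0.0284,0.20423,tRNA_Trp
Tyr_tRNA,0.1020,0.18119,tRNA_Tyr
Val_tRNA,0.2646,0.11715,tRNA_Val
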