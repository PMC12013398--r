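species,metabolite_id
Ala,ala__L_c
Arg,arg__L_c
Asn,asn__L_c
Asp,asp__L_c
Cys,cys__L_c
Gln,gln__L_c
Glu,glu__L_c
Gly,gly_c
His,his__L_c
Ile,ile__L_c
Leu,leu__L_c
Lys,lys__L_c
Met,met__L_c
Phe,phe__L_c
Pro,pro__L_c
Ser,ser__L_c
Thr,thr__L_c
Trp,trp__L_c
Tyr,tyr__L_c
Val,val__L_c
GTP,gtp_c
H2O,h2o_c
H,h_c
GDP,gdp_c
Pi,pi_c
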