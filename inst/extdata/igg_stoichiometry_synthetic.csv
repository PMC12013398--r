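species,role,coefficient
Ala,amino_acid,39
Arg,amino_acid,14
Asn,amino_acid,30
Asp,amino_acid,29
Cys,amino_acid,24
Gln,amino_acid,33
Glu,amino_acid,34
Gly,amino_acid,40
His,amino_acid,15
Ile,amino_acid,17
Leu,amino_acid,49
Lys,amino_acid,44
Met,amino_acid,8
Phe,amino_acid,24
Pro,amino_acid,38
Ser,amino_acid,70
Thr,amino_acid,57
Trp,amino_acid,14
Tyr,amino_acid,28
Val,amino_acid,55
GTP,gtp,1324
H2O,h2o,1326
H,byproduct,1326
GDP,byproduct,1324
Pi,byproduct,1324
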