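name,class,measurement_type,internal_standard_id
Ala,amino acids,LC,IS1
Gly,amino acids,LC,IS1
Ser,amino acids,LC,IS1
Val,amino acids,LC,IS1
Leu,amino acids,LC,IS1
PC 01,phosphatidylcholines,FIA,IS2
PC 02,phosphatidylcholines,FIA,IS2
PC 03,phosphatidylcholines,FIA,IS2
PC 04,phosphatidylcholines,FIA,IS2
SM 01,sphingomyelins,FIA,IS3
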