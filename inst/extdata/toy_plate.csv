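sample_id,sample_type,condition,replicate,dilution_factor,Ala,Gly,Ser,Val,Leu,PC 01,PC 02,PC 03,PC 04,SM 01,IS1,IS2,IS3
BLANK_01,BLANK_PBS,,1,,1000,1000,1000,1000,10000,1000,1000,1000,1000,1000,10000,10000,10000
BLANK_02,BLANK_PBS,,2,,1000,1000,1000,1000,20000,1000,1000,1000,1000,1000,10000,10000,10000
BLANK_03,BLANK_PBS,,3,,1000,1000,1000,1000,30000,1000,1000,1000,1000,1000,10000,10000,10000
S_A_R1,SAMPLE,A,1,,100000,30000,25000,15000,50000,100000,50000,30000,25000,40000,10000,10000,10000
S_A_R2,SAMPLE,A,2,,103000,25000,30000,15000,50000,100000,50000,30000,25000,40000,10000,10000,10000
S_A_R3,SAMPLE,A,3,,132000,10000,15000,15000,50000,100000,50000,30000,12000,40000,10000,10000,10000
S_A_R4,SAMPLE,A,4,,91000,40000,18000,15000,50000,100000,50000,15000,12000,40000,10000,10000,10000
S_A_R5,SAMPLE,A,5,,94000,35000,19000,15000,50000,1000000,500000,150000,120000,400000,10000,10000,10000
S_B_R1,SAMPLE,B,1,,100000,50000,25000,15000,100000,80000,50000,30000,25000,40000,10000,10000,10000
S_B_R2,SAMPLE,B,2,,100000,50000,25000,15000,100000,60000,50000,30000,25000,40000,10000,10000,10000
S_B_R3,SAMPLE,B,3,,100000,50000,25000,15000,100000,120000,50000,30000,25000,40000,10000,10000,
S_B_R4,SAMPLE,B,4,,100000,50000,25000,15000,100000,100000,50000,30000,25000,40000,10000,10000,10000
S_B_R5,SAMPLE,B,5,,100000,50000,25000,15000,100000,90000,50000,30000,25000,40000,10000,10000,10000
S_C_R1,SAMPLE,C,1,,100000,30000,25000,15000,100000,80000,50000,30000,25000,40000,10000,10000,10000
S_C_R2,SAMPLE,C,2,,100000,30000,25000,15000,100000,80000,50000,30000,25000,40000,10000,10000,10000
S_C_R3,SAMPLE,C,3,,130000,15000,25000,15000,100000,80000,50000,30000,25000,40000,10000,10000,10000
POOL_01,POOLED_QC,,1,,50000,50000,50000,50000,50000,50000,50000,50000,50000,50000,10000,10000,10000
POOL_02,POOLED_QC,,2,,50000,50000,50000,50000,50000,50000,50000,50000,50000,50000,10000,10000,10000
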