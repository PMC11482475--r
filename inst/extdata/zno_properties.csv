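particle,tem_nm,betsa_m2_g,dls_nm,pdi,zeta_mv
ZnO,110,NA,NA,NA,NA
AM,30,16.3,212,0.12,19.3
SA,20,29,420,0.13,NA
SO,30,14.1,NA,NA,NA
UC-1,30,21.6,223,0.19,23.2
UC-2,40,34.5,278,0.39,23
UC-3,53,11.9,232,0.14,30.5
ZnCl2,NA,NA,NA,NA,NA
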