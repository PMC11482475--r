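particle,cell_type,endpoint,beta_abs
ZnO,A549,ATP,0.120
ZnO,A549,LDH,0.058
ZnO,A549,CTB,0.089
AM,A549,ATP,0.173
AM,A549,LDH,0.014
AM,A549,CTB,0.093
SA,A549,ATP,0.177
SA,A549,LDH,0.008
SA,A549,CTB,0.106
SO,A549,ATP,0.140
SO,A549,LDH,0.003
SO,A549,CTB,0.146
UC-1,A549,ATP,0.160
UC-1,A549,LDH,0.007
UC-1,A549,CTB,0.121
UC-2,A549,ATP,0.213
UC-2,A549,LDH,0.001
UC-2,A549,CTB,0.173
UC-3,A549,ATP,0.152
UC-3,A549,LDH,0.003
UC-3,A549,CTB,0.176
ZnCl2,A549,ATP,0.265
ZnCl2,A549,LDH,0.172
ZnCl2,A549,CTB,0.220
ZnO,J774,ATP,0.348
ZnO,J774,LDH,0.189
ZnO,J774,CTB,0.295
AM,J774,ATP,1.600
AM,J774,LDH,0.170
AM,J774,CTB,0.280
SA,J774,ATP,0.493
SA,J774,LDH,0.174
SA,J774,CTB,0.311
SO,J774,ATP,0.328
SO,J774,LDH,0.172
SO,J774,CTB,0.277
UC-1,J774,ATP,1.233
UC-1,J774,LDH,0.170
UC-1,J774,CTB,0.305
UC-2,J774,ATP,1.381
UC-2,J774,LDH,0.170
UC-2,J774,CTB,0.310
UC-3,J774,ATP,1.258
UC-3,J774,LDH,0.172
UC-3,J774,CTB,0.282
ZnCl2,J774,ATP,1.258
ZnCl2,J774,LDH,0.145
ZnCl2,J774,CTB,0.205
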