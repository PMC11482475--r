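element,ZnO,AM,SA,SO,UC-1,UC-2,UC-3,ZnCl2
As,0.01,0.04,0.02,0,0.01,0.09,0.03,0
Al,2.15,75.47,104.51,41.28,79.88,50.67,20.05,1.20
Ba,0.27,3.60,1.95,1.22,2.28,14.67,0.29,0.06
Bi,0.07,0.02,0.02,0.01,0,0.03,0.01,0.23
Ca,17.92,347.11,876.69,1067.04,641.47,1835.73,20.43,16.67
Cd,11.86,0.42,0.71,0.12,1.09,0.62,3.44,2.22
Ce,0.02,0.03,0.02,0.01,0.01,1.28,1.11,0.41
Co,0,0.15,0.09,0.04,0.11,0.26,0,0
Cr,0.36,0.46,0.46,0.23,0.44,4.21,0.10,0.33
Cs,0,0,0,0,0,0,0.02,0.04
Cu,0.75,3.24,5.24,2.50,3.89,1.63,10.39,0.38
Dy,0,0,0,0,0,0.04,0,0
Er,0,0,0,0,0,0.02,0,0
Eu,0,0,0,0,0,0.01,0,0
Fe,3.35,287.07,19.36,22.20,18.24,167.89,10.18,2.90
Gd,0,0,0,0,0,0.12,0.01,0
Hf,0,0.01,0.02,0,0.01,0,0,0
Ho,0,0,0,0,0,0.01,0,0
K,8.19,14.44,13.80,18.56,11.25,20.21,10.59,7.02
La,0,0.01,0.02,0,0.01,10.67,0.02,0.02
Lu,0,0,0,0,0,0,0,0
Mg,1.21,112.06,173.98,220.07,119.84,538.70,2.47,1.01
Mn,0.17,1.54,4.40,3.65,1.01,64.47,0.13,0.09
Mo,0.02,0,0,0,0.02,0.07,0.01,0.02
Na,7.94,780.06,363.74,1724.20,949.48,217.37,11.68,3.74
Nb,0,0,0.01,0.01,0.02,0,0,0
Nd,0,0.01,0,0,0,1.20,0,0.01
Ni,0.07,0.63,1.24,0.59,0.60,21.68,0.09,0.19
Pr,0,0,0,0,0,0.42,0,0
Rb,0.02,0.02,0.02,0.02,0.02,0.04,0.02,0.02
Sb,0.01,0.01,0.08,0.01,0.03,0.03,0.01,0.01
Sc,0,0.03,0,0.06,0.01,0,0,0
Si,10.46,1173.68,46.21,2718.81,24.77,36.37,27.72,9.04
Sm,0,0,0,0,0,0.05,0,0
Sr,0.02,1.80,5.33,4.32,3.50,13.56,0.02,0.06
Ta,0,0,0,0,0,0,0,0
Tb,0,0,0,0,0,0.01,0,0
Th,0,0.02,0.05,0.01,0.02,0,0.01,0
Ti,0.97,320.69,382.85,489.93,228.36,1.54,1.32,0.66
Tm,0,0,0,0,0,0,0,0
U,0,0,0,0,0,0.13,0,0
V,0.01,0.05,0.04,0.02,0.02,0.07,0.03,0.02
Yb,0,0,0,0,0,0.01,0,0
Zn,770268,763278,715683,721911,760799,718568,753952,616834
Zr,0.05,0.30,0.91,0.12,0.47,0.06,0.02,0.02
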