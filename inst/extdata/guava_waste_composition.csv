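element,unit,dry_mean,dry_sd,fresh_mean,fresh_sd
C,g_kg,289.0,15.2,382.0,5.09
N,g_kg,12.2,1.02,16.5,0.58
P,g_kg,2.20,0.19,2.20,0.16
K,g_kg,2.42,0.22,2.88,0.08
Ca,g_kg,0.86,0.09,0.94,0.13
Mg,g_kg,0.96,0.05,0.96,0.11
S,g_kg,1.26,0.11,1.30,0.07
B,mg_kg,10.8,1.84,6.7,1.8
Cu,mg_kg,10.6,1.14,10.5,1.1
Fe,mg_kg,145.7,9.5,101.7,5.5
Mn,mg_kg,12.2,1.3,9.7,1.1
Zn,mg_kg,28.6,1.8,24.7,1.8
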