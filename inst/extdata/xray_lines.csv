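# Characteristic X-ray emission lines bundled with adxrf.
# energy_kev: line energy; edge_kev: binding energy of the originating
# shell (K edge for K lines, L3/L2 for L lines, M5 for M lines).
# Sources: Bearden (1967) line-energy tabulation and the X-ray Data
# Booklet edge tables, rounded to 0.1 eV. ratio: relative intensity
# within one (element, family) group, normalized to sum to 1.
element,z,family,label,energy_kev,ratio,edge_kev
Na,11,K,Ka1,1.041,0.6493,1.0721
Na,11,K,Ka2,1.041,0.3311,1.0721
Na,11,K,Kb1,1.0711,0.0196,1.0721
Mg,12,K,Ka1,1.2536,0.6493,1.305
Mg,12,K,Ka2,1.2536,0.3311,1.305
Mg,12,K,Kb1,1.3022,0.0196,1.305
Al,13,K,Ka1,1.4867,0.643,1.5596
Al,13,K,Ka2,1.4863,0.3279,1.5596
Al,13,K,Kb1,1.5575,0.0291,1.5596
Si,14,K,Ka1,1.74,0.6368,1.8389
Si,14,K,Ka2,1.7394,0.3248,1.8389
Si,14,K,Kb1,1.8359,0.0385,1.8389
P,15,K,Ka1,2.0137,0.6248,2.1455
P,15,K,Ka2,2.0127,0.3186,2.1455
P,15,K,Kb1,2.1391,0.0566,2.1455
S,16,K,Ka1,2.3078,0.6132,2.472
S,16,K,Ka2,2.3066,0.3127,2.472
S,16,K,Kb1,2.464,0.0741,2.472
Cl,17,K,Ka1,2.6224,0.6076,2.8224
Cl,17,K,Ka2,2.6208,0.3099,2.8224
Cl,17,K,Kb1,2.8156,0.0826,2.8224
Ar,18,K,Ka1,2.9577,0.602,3.2029
Ar,18,K,Ka2,2.9556,0.307,3.2029
Ar,18,K,Kb1,3.1905,0.0909,3.2029
K,19,K,Ka1,3.3138,0.5966,3.6074
K,19,K,Ka2,3.3111,0.3043,3.6074
K,19,K,Kb1,3.5896,0.0991,3.6074
Ca,20,K,Ka1,3.6917,0.5913,4.0381
Ca,20,K,Ka2,3.6881,0.3016,4.0381
Ca,20,K,Kb1,4.0127,0.1071,4.0381
Ti,22,K,Ka1,4.5108,0.5913,4.9664
Ti,22,K,Ka2,4.5049,0.3016,4.9664
Ti,22,K,Kb1,4.9318,0.1071,4.9664
V,23,K,Ka1,4.9522,0.5913,5.4651
V,23,K,Ka2,4.9446,0.3016,5.4651
V,23,K,Kb1,5.4273,0.1071,5.4651
Cr,24,K,Ka1,5.4147,0.5861,5.9892
Cr,24,K,Ka2,5.4055,0.2989,5.9892
Cr,24,K,Kb1,5.9467,0.115,5.9892
Mn,25,K,Ka1,5.8988,0.5861,6.539
Mn,25,K,Ka2,5.8877,0.2989,6.539
Mn,25,K,Kb1,6.4905,0.115,6.539
Fe,26,K,Ka1,6.4038,0.5861,7.112
Fe,26,K,Ka2,6.3908,0.2989,7.112
Fe,26,K,Kb1,7.058,0.115,7.112
Co,27,K,Ka1,6.9303,0.5861,7.7089
Co,27,K,Ka2,6.9153,0.2989,7.7089
Co,27,K,Kb1,7.6494,0.115,7.7089
Ni,28,K,Ka1,7.4782,0.5861,8.3328
Ni,28,K,Ka2,7.4609,0.2989,8.3328
Ni,28,K,Kb1,8.2647,0.115,8.3328
Cu,29,K,Ka1,8.0478,0.5861,8.9789
Cu,29,K,Ka2,8.0278,0.2989,8.9789
Cu,29,K,Kb1,8.9053,0.115,8.9789
Zn,30,K,Ka1,8.6389,0.5809,9.6586
Zn,30,K,Ka2,8.6158,0.2963,9.6586
Zn,30,K,Kb1,9.572,0.1228,9.6586
As,33,K,Ka1,10.5437,0.5759,11.8667
As,33,K,Ka2,10.508,0.2937,11.8667
As,33,K,Kb1,11.7262,0.1304,11.8667
Se,34,K,Ka1,11.2224,0.5759,12.6578
Se,34,K,Ka2,11.1814,0.2937,12.6578
Se,34,K,Kb1,12.4959,0.1304,12.6578
Br,35,K,Ka1,11.9242,0.5759,13.4737
Br,35,K,Ka2,11.8776,0.2937,13.4737
Br,35,K,Kb1,13.2914,0.1304,13.4737
Rb,37,K,Ka1,13.3953,0.5709,15.1997
Rb,37,K,Ka2,13.3358,0.2912,15.1997
Rb,37,K,Kb1,14.9613,0.1379,15.1997
Sr,38,K,Ka1,14.165,0.5709,16.1046
Sr,38,K,Ka2,14.0979,0.2912,16.1046
Sr,38,K,Kb1,15.8357,0.1379,16.1046
Zr,40,K,Ka1,15.7751,0.566,17.9976
Zr,40,K,Ka2,15.6909,0.2887,17.9976
Zr,40,K,Kb1,17.6678,0.1453,17.9976
W,74,L,La1,8.3976,0.45,10.2068
W,74,L,La2,8.3352,0.05,10.2068
W,74,L,Lb1,9.6724,0.3,11.544
W,74,L,Lb2,9.9614,0.12,10.2068
W,74,L,Lg1,11.2859,0.05,11.544
W,74,L,Ll,7.3878,0.03,10.2068
Pt,78,L,La1,9.4423,0.45,11.5637
Pt,78,L,La2,9.3617,0.05,11.5637
Pt,78,L,Lb1,11.0707,0.3,13.2726
Pt,78,L,Lb2,11.2506,0.12,11.5637
Pt,78,L,Lg1,12.942,0.05,13.2726
Pt,78,L,Ll,8.2677,0.03,11.5637
Au,79,L,La1,9.7133,0.45,11.9187
Au,79,L,La2,9.628,0.05,11.9187
Au,79,L,Lb1,11.4423,0.3,13.7336
Au,79,L,Lb2,11.5847,0.12,11.9187
Au,79,L,Lg1,13.3817,0.05,13.7336
Au,79,L,Ll,8.4939,0.03,11.9187
Hg,80,L,La1,9.9888,0.45,12.2839
Hg,80,L,La2,9.8976,0.05,12.2839
Hg,80,L,Lb1,11.8226,0.3,14.2087
Hg,80,L,Lb2,11.9241,0.12,12.2839
Hg,80,L,Lg1,13.8301,0.05,14.2087
Hg,80,L,Ll,8.721,0.03,12.2839
Pb,82,L,La1,10.5515,0.45,13.0352
Pb,82,L,La2,10.4495,0.05,13.0352
Pb,82,L,Lb1,12.6137,0.3,15.2
Pb,82,L,Lb2,12.6226,0.12,13.0352
Pb,82,L,Lg1,14.7644,0.05,15.2
Pb,82,L,Ll,9.1845,0.03,13.0352
W,74,M,Ma1,1.7754,1,1.8092
Pt,78,M,Ma1,2.0505,1,2.1216
Au,79,M,Ma1,2.1229,1,2.2057
Hg,80,M,Ma1,2.1953,1,2.2949
Pb,82,M,Ma1,2.3457,1,2.484
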