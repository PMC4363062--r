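dosimeter_no,mean_dose_mGy,rel_sd_pct,n,reported_u_c_pct
1,0.25,33,6,36
2,0.33,27,6,31
3,0.52,20,6,25
4,0.48,22,6,26
5,0.53,20,6,25
6,0.73,17,6,22
7,0.81,16,6,22
8,3.86,7,6,16
9,4.04,7,6,16
10,7.11,5,6,16
11,6.53,5,6,16
12,10.4,4,6,16
13,7.71,5,6,16
14,4.09,7,6,16
15,4.66,6,6,16
16,4.25,6,6,16
17,6.15,5,6,16
18,6.45,5,6,16
19,7.33,5,6,16
20,3.40,7,6,17
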