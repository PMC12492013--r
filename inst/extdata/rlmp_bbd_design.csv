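run,X1_time_min,X2_ratio_mL_g,X3_power_W,X4_temp_C,X5_particle_mm,yield_pct
1,20,20,180,40,0.25,7.15
2,30,20,180,50,0.85,8.11
3,20,25,180,40,0.55,7.98
4,30,15,180,50,0.55,7.25
5,30,25,160,40,0.55,8.37
6,30,20,200,30,0.55,7.81
7,30,20,180,50,0.25,7.36
8,30,15,180,30,0.55,7.66
9,30,20,180,30,0.85,7.03
10,30,25,180,50,0.55,8.12
11,30,15,180,40,0.85,8.14
12,30,25,180,40,0.25,8.31
13,40,20,160,40,0.55,9.11
14,30,20,180,40,0.55,10.35
15,40,20,180,30,0.55,7.52
16,30,25,180,30,0.55,7.46
17,20,20,180,50,0.55,6.47
18,30,20,180,30,0.25,6.8
19,30,20,180,40,0.55,10.88
20,30,15,200,40,0.55,7.91
21,30,25,180,40,0.85,7.79
22,20,20,200,40,0.55,7.04
23,40,15,180,40,0.55,9.06
24,40,20,180,40,0.85,8.16
25,30,20,180,40,0.55,10.86
26,30,20,180,40,0.55,10.71
27,30,20,160,30,0.55,7.76
28,40,20,180,50,0.55,8.09
29,40,25,180,40,0.55,7.87
30,30,25,200,40,0.55,8.06
31,30,20,200,40,0.85,7.39
32,30,20,160,40,0.85,8.83
33,40,20,180,40,0.25,6.52
34,20,15,180,40,0.55,6.12
35,30,20,200,40,0.25,8.02
36,30,20,180,40,0.55,10.76
37,40,20,200,40,0.55,7.89
38,30,20,160,50,0.55,8.49
39,30,15,180,40,0.25,6.89
40,20,20,180,40,0.85,5.86
41,20,20,180,30,0.55,6.03
42,30,20,200,50,0.55,7.96
43,20,20,160,40,0.55,6.97
44,30,15,160,40,0.55,8.94
45,30,20,180,40,0.55,10.74
46,30,20,160,40,0.25,7.29
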