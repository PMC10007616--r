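subject,mean_hr_bpm,tp,tn,fp,fn,sen,pre,spe,acc
1,61.50,359,349,20,10,97.29,94.72,94.58,95.93
2,77.50,457,464,1,8,98.28,99.78,99.78,99.03
3,76.67,439,427,33,21,95.43,93.01,92.83,94.13
4,77.17,433,425,38,30,93.52,91.93,91.79,92.66
5,73.33,413,422,18,27,93.86,95.82,95.91,94.89
6,70.50,423,386,37,0,100.00,91.96,91.25,95.63
7,59.67,323,336,22,35,90.22,93.62,93.85,92.04
8,72.33,433,403,31,1,99.77,93.32,92.86,96.31
9,68.33,384,370,40,26,93.66,90.57,90.24,91.95
10,59.17,336,319,36,19,94.65,90.32,89.86,92.25
11,61.17,361,347,20,6,98.37,94.75,94.55,96.46
12,67.33,401,388,16,3,99.26,96.16,96.04,97.65
13,63.17,362,342,37,17,95.51,90.73,90.24,92.88
14,67.00,401,360,42,1,99.75,90.52,89.55,94.65
15,73.00,432,419,19,6,98.63,95.79,95.66,97.15
16,63.67,376,360,22,6,98.43,94.47,94.24,96.34
17,86.67,506,511,9,14,97.31,98.25,98.27,97.79
18,76.67,434,446,14,26,94.35,96.88,96.96,95.65
19,80.17,478,463,18,3,99.38,96.37,96.26,97.82
20,62.33,374,349,25,0,100.00,93.73,93.32,96.66
AVG,70.00,406.25,394.30,24.90,12.95,96.88,94.14,93.90,95.39
STD,7.75,47.32,51.57,11.30,11.31,2.79,2.67,2.88,2.14
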