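subject,mean_hr_bpm,tp,tn,fp,fn,sen,pre,spe,acc
1,61.50,365,268,22,4,98.92,94.32,92.41,96.05
2,77.50,445,187,27,20,95.70,94.28,87.38,93.08
3,76.67,446,199,43,14,96.96,91.21,82.23,91.88
4,77.17,457,243,37,6,98.70,92.51,86.79,94.21
5,73.33,411,300,22,29,93.41,94.92,93.17,93.31
6,70.50,365,138,15,58,86.29,96.05,90.20,87.33
7,59.67,345,111,21,13,96.37,94.26,84.09,93.06
8,72.33,346,188,30,88,79.72,92.02,86.24,81.90
9,68.33,369,311,24,41,90.00,93.89,92.84,91.28
10,59.17,305,297,18,50,85.92,94.43,94.29,89.85
11,61.17,366,50,12,1,99.73,96.83,80.65,96.97
12,67.33,374,243,18,30,92.57,95.41,93.10,92.78
13,63.17,355,211,13,24,93.67,96.47,94.20,93.86
14,67.00,365,298,23,37,90.80,94.07,92.83,91.70
15,73.00,394,136,18,44,89.95,95.63,88.31,89.53
16,63.67,351,241,9,31,91.88,97.50,96.40,93.67
17,86.67,519,255,12,1,99.81,97.74,95.51,98.35
18,76.67,423,168,13,37,91.96,97.02,92.82,92.20
19,80.17,432,213,9,49,89.81,97.96,95.95,91.75
20,62.33,372,197,16,2,99.47,95.88,92.49,96.93
AVG,70.00,390.25,212.70,20.10,28.95,93.08,95.12,90.59,92.48
STD,7.75,50.26,69.26,8.95,22.60,5.35,1.89,4.64,3.64
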