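subject,mean_hr_bpm,tp,tn,fp,fn,sen,pre,spe,acc
1,61.50,333,268,11,36,90.24,96.80,96.06,92.75
2,77.50,400,187,26,65,86.02,93.90,87.79,86.58
3,76.67,388,199,43,72,84.35,90.02,82.23,83.62
4,77.17,300,243,86,163,64.79,77.72,73.86,68.56
5,73.33,411,300,11,29,93.41,97.39,96.46,94.67
6,70.50,355,138,36,68,83.92,90.79,79.31,82.58
7,59.67,311,111,16,47,86.87,95.11,87.40,87.01
8,72.33,343,188,34,91,79.03,90.98,84.68,80.95
9,68.33,352,311,24,58,85.85,93.62,92.84,88.99
10,59.17,264,297,24,91,74.37,91.67,92.52,82.99
11,61.17,311,50,16,56,84.74,95.11,75.76,83.37
12,67.33,274,243,55,130,67.82,83.28,81.54,73.65
13,63.17,255,211,60,124,67.28,80.95,77.86,71.69
14,67.00,294,298,56,108,73.13,84.00,84.18,78.31
15,73.00,294,136,88,144,67.12,76.96,60.71,64.95
16,63.67,264,241,78,118,69.11,77.19,75.55,72.04
17,86.67,434,255,54,86,83.46,88.93,82.52,83.11
18,76.67,399,168,23,61,86.74,94.55,87.96,87.10
19,80.17,344,213,54,137,71.52,86.43,79.78,74.47
20,62.33,254,197,34,120,67.91,88.19,85.28,74.55
AVG,70.00,329.00,212.70,41.45,90.20,78.39,88.68,83.22,80.60
STD,7.75,55.88,69.26,24.09,38.51,9.14,6.64,8.45,8.07
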