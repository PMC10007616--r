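subject,mean_hr_bpm,tp,tn,fp,fn,sen,pre,spe,acc
1,61.50,310,268,27,59,84.01,91.99,90.85,87.05
2,77.50,226,187,161,239,48.60,58.40,53.74,50.80
3,76.67,251,199,111,209,54.57,69.34,64.19,58.44
4,77.17,267,243,131,196,57.67,67.09,64.97,60.93
5,73.33,386,300,40,54,87.73,90.61,88.24,87.95
6,70.50,281,138,58,142,66.43,82.89,70.41,67.69
7,59.67,260,111,43,98,72.63,85.81,72.08,72.46
8,72.33,226,188,99,208,52.07,69.54,65.51,57.42
9,68.33,109,311,58,301,26.59,65.27,84.28,53.92
10,59.17,170,297,24,185,47.89,87.63,92.52,69.08
11,61.17,252,50,57,115,68.66,81.55,46.73,63.71
12,67.33,83,243,95,321,20.54,46.63,71.89,43.94
13,63.17,105,211,101,274,27.70,50.97,67.63,45.73
14,67.00,194,298,56,208,48.26,77.60,84.18,65.08
15,73.00,252,136,94,186,57.53,72.83,59.13,58.08
16,63.67,190,241,93,192,49.74,67.14,72.16,60.20
17,86.67,424,255,59,96,81.54,87.78,81.21,81.41
18,76.67,375,168,43,85,81.52,89.71,79.62,80.92
19,80.17,299,213,54,182,62.16,84.70,79.78,68.45
20,62.33,124,197,128,250,33.16,49.21,60.62,45.92
AVG,70.00,239.20,212.70,76.60,180.00,56.45,73.83,72.49,63.96
STD,7.75,94.14,69.26,37.74,77.33,19.68,14.47,12.52,13.18
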