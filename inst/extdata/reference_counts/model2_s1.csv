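subject,mean_hr_bpm,tp,tn,fp,fn,sen,pre,spe,acc
1,61.50,366,310,59,3,99.19,86.12,84.01,91.60
2,77.50,451,427,38,14,96.99,92.23,91.83,94.41
3,76.67,434,403,57,26,94.35,88.39,87.61,90.98
4,77.17,424,420,43,39,91.58,90.79,90.71,91.14
5,73.33,431,412,28,9,97.95,93.90,93.64,95.80
6,70.50,411,368,55,12,97.16,88.20,87.00,92.08
7,59.67,350,332,26,8,97.77,93.09,92.74,95.25
8,72.33,422,401,33,12,97.24,92.75,92.40,94.82
9,68.33,404,367,43,6,98.54,90.38,89.51,94.02
10,59.17,351,317,38,4,98.87,90.23,89.30,94.08
11,61.17,363,340,27,4,98.91,93.08,92.64,95.78
12,67.33,388,386,18,16,96.04,95.57,95.54,95.79
13,63.17,371,346,33,8,97.89,91.83,91.29,94.59
14,67.00,400,359,43,2,99.50,90.29,89.30,94.40
15,73.00,434,400,38,4,99.09,91.95,91.32,95.21
16,63.67,377,357,25,5,98.69,93.78,93.46,96.07
17,86.67,500,507,13,20,96.15,97.47,97.50,96.83
18,76.67,438,449,11,22,95.22,97.55,97.61,96.41
19,80.17,464,464,17,17,96.47,96.47,96.47,96.47
20,62.33,366,348,26,8,97.86,93.37,93.05,95.45
AVG,70.00,407.25,385.65,33.55,11.95,97.27,92.37,91.85,94.56
STD,7.75,40.82,51.19,13.94,9.32,1.93,3.03,3.50,1.79
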