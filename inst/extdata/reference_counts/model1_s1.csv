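subject,mean_hr_bpm,tp,tn,fp,fn,sen,pre,spe,acc
1,61.50,353.00,255.00,114.00,16.00,95.66,75.59,69.11,82.38
2,77.50,453.00,385.00,80.00,12.00,97.42,84.99,82.80,90.11
3,76.67,386.00,322.00,138.00,74.00,83.91,73.66,70.00,76.96
4,77.17,376.00,363.00,100.00,87.00,81.21,78.99,78.40,79.81
5,73.33,419.00,366.00,74.00,21.00,95.23,84.99,83.18,89.20
6,70.50,355.00,300.00,123.00,68.00,83.92,74.27,70.92,77.42
7,59.67,342.00,318.00,40.00,16.00,95.53,89.53,88.83,92.18
8,72.33,411.00,379.00,55.00,23.00,94.70,88.20,87.33,91.01
9,68.33,388.00,315.00,95.00,22.00,94.63,80.33,76.83,85.73
10,59.17,343.00,251.00,104.00,12.00,96.62,76.73,70.70,83.66
11,61.17,318.00,300.00,67.00,49.00,86.65,82.60,81.74,84.20
12,67.33,375.00,362.00,42.00,29.00,92.82,89.93,89.60,91.21
13,63.17,355.00,315.00,64.00,24.00,93.67,84.73,83.11,88.39
14,67.00,399.00,289.00,113.00,3.00,99.25,77.93,71.89,85.57
15,73.00,414.00,367.00,71.00,24.00,94.52,85.36,83.79,89.16
16,63.67,355.00,327.00,55.00,27.00,92.93,86.59,85.60,89.27
17,86.67,488.00,486.00,34.00,32.00,93.85,93.49,93.46,93.65
18,76.67,422.00,438.00,22.00,38.00,91.74,95.05,95.22,93.48
19,80.17,413.00,448.00,33.00,68.00,85.86,92.60,93.14,89.50
20,62.33,355.00,314.00,60.00,19.00,94.92,85.54,83.96,89.44
AVG,70.00,386.00,345.00,74.20,33.20,92.25,84.05,81.98,87.12
STD,7.75,41.77,61.52,33.18,23.47,5.07,6.43,8.24,4.99
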