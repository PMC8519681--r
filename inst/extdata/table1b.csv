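energy_mev,depth_mm,modeled,standard,deviation_pct
6,0,81.45,81.76,-0.38
6,5,96.70,96.35,0.36
6,10,99.95,99.71,0.25
6,15,97.00,95.77,1.29
6,20,76.57,72.44,5.70
6,25,33.84,35.63,-5.02
6,30,9.20,8.74,5.34
6,35,2.92,1.30,124.63
6,40,1.57,0.84,86.20
9,0,76.71,79.83,-3.90
9,5,85.11,85.66,-0.64
9,10,92.18,90.93,1.37
9,15,97.26,96.16,1.15
9,20,99.89,99.70,0.19
9,25,98.10,97.56,0.55
9,30,86.44,85.75,0.80
9,35,58.82,62.81,-6.36
9,40,29.71,35.45,-16.20
9,45,14.04,13.41,4.66
9,50,5.89,3.44,71.55
9,55,2.33,1.25,86.79
9,60,1.33,1.08,22.61
12,0,79.93,83.34,-4.09
12,5,88.65,88.33,0.36
12,10,93.74,91.84,2.07
12,15,97.08,95.01,2.18
12,20,99.17,97.63,1.58
12,25,100.00,99.56,0.44
12,30,99.07,99.53,-0.46
12,35,95.08,94.82,0.28
12,40,85.13,83.98,1.37
12,45,65.55,66.22,-1.01
12,50,40.43,44.03,-8.19
12,55,21.63,23.15,-6.56
12,60,11.25,9.22,22.02
12,65,5.71,3.50,62.96
15,0,86.37,89.98,-4.02
15,5,95.05,94.06,1.05
15,10,97.83,96.45,1.43
15,15,99.20,97.84,1.39
15,20,99.85,98.86,1.01
15,25,99.99,99.66,0.33
15,30,99.63,99.75,-0.12
15,35,98.69,99.24,-0.55
15,40,96.89,97.21,-0.33
15,45,93.64,93.30,0.36
15,50,87.77,86.37,1.62
15,55,77.30,75.88,1.88
15,60,60.60,62.10,-2.42
15,65,40.86,46.10,-11.37
15,70,25.12,30.31,-17.11
15,75,15.51,17.14,-9.53
15,80,10.09,8.70,15.93
15,85,6.20,4.84,28.09
15,90,5.08,3.76,35.11
15,95,3.87,3.54,9.11
15,100,3.05,3.47,-12.00
15,105,2.48,3.38,-26.67
15,110,2.07,3.31,-37.45
18,0,90.84,87.85,3.41
18,5,93.33,92.08,1.36
18,10,95.23,94.29,1.00
18,15,96.74,95.93,0.85
18,20,97.95,97.11,0.86
18,25,98.89,98.34,0.56
18,30,99.56,99.20,0.37
18,35,99.95,99.74,0.20
18,40,99.94,99.98,-0.04
18,45,99.37,99.16,0.21
18,50,97.89,96.86,1.06
18,55,94.76,92.34,2.62
18,60,88.57,84.79,4.46
18,65,76.99,73.93,4.14
18,70,58.70,60.03,-2.22
18,75,38.40,44.28,-13.29
18,80,24.30,29.22,-16.86
18,85,14.39,16.66,-13.62
18,90,9.39,8.74,7.38
18,95,6.49,5.10,27.19
18,100,4.71,4.02,17.23
18,105,3.56,3.76,-5.29
18,110,2.78,3.70,-24.85
18,115,2.22,3.61,-38.41
18,120,1.82,3.53,-48.47
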