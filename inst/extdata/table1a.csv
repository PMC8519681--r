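cone_cm,depth_mm,modeled,standard,deviation_pct
6,0,82.29,83.83,-1.84
6,5,89.59,89.04,0.62
6,10,94.26,92.65,1.74
6,15,97.35,95.69,1.73
6,20,99.3,98.33,0.99
6,25,100,99.88,0.12
6,30,98.92,98.93,-0.01
6,35,94.79,93.35,1.54
6,40,84.52,81.65,3.52
6,45,64.59,63.5,1.72
6,50,39.93,41.84,-4.57
6,55,21.97,22.03,-0.27
6,60,8.87,8.46,4.85
6,65,3.49,3.32,2.71
6,70,2.31,2.16,2.31
6,75,2.13,2.04,4.41
6,80,2.43,2.49,-2.41
10,0,79.93,83.34,-4.09
10,5,88.49,88.27,0.25
10,10,93.68,91.81,2.04
10,15,97.05,95.01,2.15
10,20,99.17,97.63,1.58
10,25,100,99.56,0.44
10,30,99.04,99.47,-0.43
10,35,95.08,94.82,0.27
10,40,85.13,83.98,1.37
10,45,65.55,66.22,-1.01
10,50,43.58,44.39,-1.82
10,55,21.9,23.63,-7.32
10,60,9.25,9.22,0.33
10,65,3.67,3.64,0.82
10,70,2.53,2.31,5.19
10,75,2.15,2.19,-1.83
10,80,2.18,2.14,1.87
15,0,79.93,82.8,-3.47
15,5,88.49,88.12,0.42
15,10,93.68,91.8,2.05
15,15,97.05,94.9,2.27
15,20,99.17,97.76,1.44
15,25,100,99.71,0.29
15,30,99.04,99.11,-0.07
15,35,95.08,93.86,1.30
15,40,85.13,82,3.82
15,45,65.55,63.91,2.57
15,50,40.58,41.83,-2.99
15,55,21.39,21.5,-0.51
15,60,8.25,8.19,0.73
15,65,3.77,3.32,7.53
15,70,2.25,2.23,5.38
15,75,2.25,2.15,4.65
15,80,2.08,2.13,-2.35
20,0,79.93,83.24,-3.98
20,5,88.49,88.29,0.23
20,10,93.68,91.75,2.10
20,15,97.05,94.8,2.37
20,20,99.17,97.57,1.64
20,25,100,99.64,0.36
20,30,99.04,99.19,-0.15
20,35,95.08,94.37,0.75
20,40,85.13,82.56,3.11
20,45,65.55,64.22,2.07
20,50,40.58,42.06,-3.52
20,55,21.9,21.97,-0.32
20,60,8.25,8.54,-3.40
20,65,3.28,3.42,-4.09
20,70,2.25,2.22,1.35
20,75,2.15,2.14,0.47
20,80,2.28,2.31,-1.30
25,0,79.93,83.1,-3.81
25,5,88.49,88.04,0.51
25,10,93.68,91.65,2.21
25,15,97.05,94.63,2.56
25,20,99.17,97.55,1.66
25,25,100,99.61,0.39
25,30,99.04,99.19,-0.15
25,35,95.08,93.78,1.39
25,40,85.13,81.76,4.12
25,45,65.55,62.98,4.08
25,50,40.58,40.81,-0.56
25,55,21.9,20.99,4.34
25,60,8.25,8.09,1.98
25,65,3.18,3.27,-2.75
25,70,2.15,2.14,0.47
25,75,2.25,2.06,9.22
25,80,2.35,2.47,-4.86
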