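index,hue_angle_deg
1,232.5
2,227.5
3,220.5
4,209.0
5,190.0
6,163.0
7,132.5
8,108.8
9,94.0
10,83.2
11,74.7
12,68.0
13,62.3
14,56.6
15,50.7
16,45.0
17,39.7
18,34.9
19,30.5
20,26.3
21,22.3
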