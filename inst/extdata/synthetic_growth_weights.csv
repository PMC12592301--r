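# synthetic reference weights for an unimproved cattle growth curve
# generated from the package default parameters (tau=22, a=0.15, b=0.08)
age,kg
0,22
6,45
12,70
18,92
24,109
30,121
36,129.1
42,134.4
48,137.8
54,139.9
60,141.3
66,142.1
72,142.6
78,142.9
84,143.1
90,143.3
96,143.3
102,143.4
108,143.4
114,143.4
120,143.4
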