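"carbon_n","rt1_min"
8,4
9,5.3
10,6.6
11,7.9
12,9.2
13,10.5
14,11.8
15,13.1
16,14.4
17,15.7
18,17
19,18.3
20,19.6
21,20.9
22,22.2
23,23.5
24,24.8
25,26.1
26,27.4
27,28.7
28,30
29,31.3
30,32.6
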