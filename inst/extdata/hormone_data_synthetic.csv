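day,E2,P4,Inh,LH,FSH
1,42,1.0,2.0,10.5,12.5
2,44,0.9,1.8,10.8,13.0
3,46,0.8,1.7,11.0,13.2
4,49,0.7,1.6,11.2,13.0
5,53,0.7,1.6,11.5,12.5
6,58,0.7,1.7,11.8,11.8
7,65,0.7,1.8,12.0,11.0
8,74,0.7,2.0,12.3,10.3
9,86,0.7,2.2,12.8,9.8
10,102,0.8,2.5,13.5,9.4
11,125,0.8,2.9,14.5,9.2
12,165,0.9,3.4,17.0,9.5
13,237,1.0,4.0,35.0,11.5
14,190,1.2,4.5,123.0,19.6
15,125,1.9,4.2,55.0,13.5
16,95,3.2,4.5,22.0,9.0
17,90,5.5,5.5,15.0,7.5
18,95,8.5,6.8,12.5,6.5
19,103,11.5,8.5,11.0,5.8
20,110,14.5,11.5,10.0,5.3
21,112,17.9,11.2,9.3,5.0
22,110,17.2,10.5,8.8,4.9
23,104,15.5,9.4,8.5,5.0
24,95,13.0,8.0,8.3,5.2
25,84,10.0,6.4,8.3,5.6
26,72,7.2,4.8,8.5,6.5
27,60,4.5,3.4,9.0,8.2
28,50,2.2,2.4,9.8,10.5
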