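tetramer_id,x,y,z,angle_deg,tag_kind
1,0,0,0,0,RFP20
2,30,0,0,0,RFP20
3,60,0,0,0,RFP20
4,90,0,0,0,RFP20
5,120,0,0,0,RFP20
6,0,30,0,0,RFP20
7,30,30,0,0,RFP20
8,90,30,0,0,RFP20
9,120,30,0,0,RFP20
10,150,30,0,0,RFP20
11,60,60,0,0,RFP20
12,90,60,0,0,RFP20
13,120,60,0,0,RFP20
14,150,60,0,0,RFP20
15,0,90,0,0,RFP20
16,30,90,0,0,RFP20
17,60,90,0,0,RFP20
18,90,90,0,0,RFP20
19,120,90,0,0,RFP20
20,150,90,0,0,RFP20
21,0,120,0,0,RFP20
22,30,120,0,0,RFP20
23,60,120,0,0,RFP20
24,90,120,0,0,RFP20
25,120,120,0,0,RFP20
26,150,120,0,0,RFP20
27,0,150,0,0,RFP20
28,30,150,0,0,RFP20
29,60,150,0,0,RFP20
30,90,150,0,0,RFP20
31,150,150,0,0,RFP20
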