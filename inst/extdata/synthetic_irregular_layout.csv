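tetramer_id,x,y,z,angle_deg,tag_kind
1,64,2.8,0.8,30,RFP20
2,93,-3.2,-2.6,49.4,RFP20
3,126.5,3.3,0.3,40.3,RFP20
4,29.4,33.7,1.3,2.4,RFP20
5,126.6,33.6,2.3,76.4,RFP20
6,158.1,27.8,4,29,RFP20
7,-3.8,59.3,-1.7,45.3,RFP20
8,29,65.5,4,13.8,RFP20
9,65.6,58.9,1.5,60.1,RFP20
10,93.5,60.1,-1.9,58.5,RFP20
11,158.2,58.4,4.1,81.1,RFP20
12,184.3,59.5,-0,75.8,RFP20
13,-0.8,93.3,-2.5,0.7,RFP20
14,31.3,93.5,-1.7,62.9,RFP20
15,60.9,92.9,2.4,7.6,RFP20
16,90,91.6,0.2,66.5,RFP20
17,123.2,94.6,-1.9,28.4,RFP20
18,151.8,93.2,5.6,75.4,RFP20
19,3.6,123.3,-5.2,45.4,RFP20
20,30.4,121.1,-4.4,38.4,RFP20
21,65.9,127.2,-2.4,66.2,RFP20
22,93.6,123.9,-4,31.7,RFP20
23,126.3,123.2,1.6,87.8,RFP20
24,158.2,121.1,-4.9,77.2,RFP20
25,186.1,120.2,-5,61,RFP20
26,27.7,157.1,3.3,76.8,RFP20
27,121.9,157.1,4.4,63.1,RFP20
28,157.4,157.2,-4.7,36.4,RFP20
29,59.8,189.1,-2.8,1.8,RFP20
30,93.7,184.6,3.2,53.9,RFP20
31,127.4,183.6,-0.5,26.2,RFP20
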