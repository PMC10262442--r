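mother_id,village_id,w,a,y
1,1,0,low,0
2,1,0,low,0
3,2,0,low,1
4,2,0,medium,0
5,3,0,medium,1
6,3,0,medium,1
7,1,0,high,0
8,2,0,high,1
9,3,0,high,1
10,1,1,low,1
11,1,1,low,0
12,2,1,low,0
13,2,1,medium,0
14,3,1,medium,0
15,3,1,medium,1
16,1,1,high,1
17,2,1,high,1
18,3,1,high,0
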