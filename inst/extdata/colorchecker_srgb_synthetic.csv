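# canopyseg color-checker reference, schema v1 (synthetic 24-patch card)
# columns: index, R, G, B, group; grays drive white balance, named hue groups drive hue calibration
index,R,G,B,group
1,115,82,68,brown
2,170,120,85,brown
3,98,122,157,other
4,87,108,67,green
5,133,128,177,other
6,103,189,170,other
7,214,126,44,other
8,80,91,166,other
9,193,90,99,other
10,94,60,108,other
11,157,188,64,green
12,224,163,46,yellow
13,56,61,150,other
14,70,148,73,green
15,175,54,60,other
16,231,199,31,yellow
17,187,86,149,other
18,8,133,161,other
19,243,243,242,gray
20,200,200,200,gray
21,160,160,160,gray
22,122,122,121,gray
23,85,85,85,gray
24,52,52,52,gray
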