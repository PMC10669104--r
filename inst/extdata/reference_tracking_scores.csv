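id,appear_frame,disappear_frame,ft,fw,rt
1,1,72,72,72,100
2,1,55,55,90,61.11
3,1,44,45,45,100
5,1,90,90,90,100
9,5,31,27,42,64.29
15,6,90,85,85,100
17,8,52,45,83,54.22
24,9,29,11,62,17.74
25,12,90,79,79,100
27,13,90,78,78,100
43,21,90,70,70,100
45,23,66,44,68,64.70
56,25,61,37,37,100
63,25,90,66,66,100
74,28,90,63,63,100
87,28,90,63,63,100
89,54,90,36,36,100
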