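actual,p0,p1,p2,p3,p4
0,3565,36,68,1,3
1,204,87,54,0,1
2,140,47,540,15,10
3,7,0,55,54,7
4,4,1,18,12,71
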