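classical,<=10,20,40,80,160,320,640,1280,2560,5120
<=10,402,2,1,0,0,0,0,0,0,0
20,8,55,1,1,0,0,0,0,0,0
40,0,6,13,3,0,0,0,0,0,0
80,0,0,5,12,2,0,0,0,0,0
160,0,0,0,4,6,1,0,1,0,0
320,0,0,0,0,6,12,7,0,0,0
640,0,0,0,0,2,6,11,5,0,0
1280,0,0,0,0,0,1,4,7,1,0
2560,0,0,0,0,0,0,0,0,1,1
5120,0,0,0,0,0,0,0,0,2,3
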