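age,px,mx,Px,Dx
0,0.5,0,0,4
1,0.5,1,5,4
2,0,1,5,4
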