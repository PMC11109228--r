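scanner,scan,angle_deg
1,1,1.56
1,2,1.40
1,3,1.01
1,4,1.40
1,5,1.16
2,1,1.42
2,2,2.06
2,3,1.23
2,4,0.76
2,5,1.22
3,1,1.03
3,2,1.87
3,3,1.32
3,4,0.92
3,5,0.75
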