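"ee_pct","ratio"
-100,-1
-75,-0.75
-50,-0.5
-25,-0.25
0,0
25,0.25
50,0.5
75,0.75
100,1
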