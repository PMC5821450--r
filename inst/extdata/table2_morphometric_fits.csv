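relationship,form,A,B,r2
h_vs_L,powerI,0.9158,1.0794,0.98
h_vs_m,powerI,0.2168,0.3883,0.99
L_vs_m,powerI,0.2657,0.3570,0.99
DC_vs_L,loglinear,-0.6306,-1.1332,0.72
DC_vs_m,loglinear,-0.2363,-0.7615,0.72
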