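type,term,ndf,ddf,f,p,semi_partial_r2,partial_r2
BS,AL,1,63,12.23,0.00,0.068,0.151
BS,SL,1,63,0.18,0.67,0.001,0.002
BS,AL:SL,1,63,0.23,0.64,0.001,0.003
BS,SID,63,87,4.17,0.00,0.381,0.844
WS,Time,1,61,45.87,0.00,0.072,0.176
WS,C2,1,51,1.51,0.22,0.008,0.019
WS,C1,1,51,3.23,0.08,0.011,0.027
WS,Time:C2,1,87,0.93,0.37,0.001,0.004
WS,Time:C1,1,87,0.35,0.56,0.002,0.001
WS,Time:AL,1,61,0.10,0.75,0.001,0.001
WS,Time:SL,1,61,0.82,0.37,0.000,0.003
WS,Time:AL:SL,1,61,1.44,0.24,0.001,0.005
WS,AL:C2,1,51,0.35,0.56,0.002,0.003
WS,SL:C2,1,51,0.18,0.67,0.001,0.000
WS,AL:SL:C2,1,51,0.04,0.84,0.002,0.000
WS,AL:C1,1,38,0.62,0.44,0.001,0.006
WS,SL:C1,1,38,0.01,0.92,0.000,0.000
WS,AL:SL:C1,1,38,0.03,0.85,0.000,0.002
WS,Time:SID,61,87,1.16,0.26,0.105,0.255
WS,C2:SID,51,87,1.93,0.00,0.108,0.263
WS,C1:SID,38,87,1.83,0.01,0.098,0.235
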