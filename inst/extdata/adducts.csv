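name,polarity,mass_delta,charge
[M]+,positive,0.0000000,1
[M+H]+,positive,1.0072765,1
[M+Na]+,positive,22.9892207,1
[M+NH4]+,positive,18.0338256,1
[M+K]+,positive,38.9631579,1
[M-H]-,negative,-1.0072765,-1
[M+Na-2H]-,negative,20.9746678,-1
[M+NH4-2H]-,negative,16.0192726,-1
[M+Cl]-,negative,34.9694013,-1
[M+K-2H]-,negative,36.9486050,-1
[M+FA-H]-,negative,44.9982029,-1
[M+H2O-H]-,negative,17.0032882,-1
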