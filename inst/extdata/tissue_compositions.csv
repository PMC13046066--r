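tissue,wH,wC,wN,wO,wCa,rho
Adipose 1,11.2,51.7,1.3,35.5,0.0,970
Adipose 2,11.4,59.8,0.7,27.8,0.0,950
Adipose 3,11.6,68.1,0.2,19.8,0.0,930
Muscle 1,10.1,17.1,3.6,68.1,0.0,1050
Muscle 2,10.2,14.3,3.4,71.0,0.0,1050
Muscle 3,10.2,11.2,3.0,74.5,0.0,1050
Cort. bone,3.4,15.5,4.2,43.5,22.5,1920
Red b. m.,10.5,41.4,3.4,43.9,0.0,1030
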