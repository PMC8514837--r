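density_mg_ha_cm3,mean_hu
0,0.4
100,132.7
200,263.1
400,528.9
600,791.5
800,1056.2
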