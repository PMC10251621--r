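,RZM,RZN,RZEo,RZR,RZKm,RZS
RZM,1,0.06,0.06,-0.20,0.05,0.03
RZN,,1,0.14,0.40,0.20,0.46
RZEo,,,1,-0.03,0.03,0.15
RZR,,,,1,0.30,0.13
RZKm,,,,,1,0.11
RZS,,,,,,1
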