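,RZM,RZN,RZEo,RZEn,RZR,RZKm,RZKd,RZH,RZC,RZS
RZM,1,0.13,0.13,0.07,-0.15,0.11,0.07,0.09,-0.02,0.04
RZN,,1,0.23,0.28,0.43,0.25,0.22,0.78,0.13,0.46
RZEo,,,1,0.92,0.02,0.09,-0.05,0.25,-0.10,0.19
RZEn,,,,1,0.06,0.08,-0.03,0.31,-0.10,0.25
RZR,,,,,1,0.32,0.19,0.41,0.04,0.15
RZKm,,,,,,1,0.00,0.25,0.04,0.13
RZKd,,,,,,,1,0.23,0.05,0.10
RZH,,,,,,,,1,0.10,0.57
RZC,,,,,,,,,1,0.02
RZS,,,,,,,,,,1
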