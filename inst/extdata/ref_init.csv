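name,value
RP_LH,10.8378509106
LH,12.220996527104
RP_FSH,0.000682018458322627
FSH,13.1209113129825
RcF,8.00702167318021
GrF,0.999344162630736
DomF,107.122428746029
Sc1,40.0573473036629
Sc2,45.9300794766004
Lut1,51.4365165208922
Lut2,29.4634633707068
Lut3,71.6331101769611
Lut4,41.9208815563871
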