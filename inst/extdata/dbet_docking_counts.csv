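protac,docked,crystal,A1,A2,A3,A4,A5,B1,B2,B3,B4
dBET1,186,0,81,51,17,22,38,68,106,0,0
dBET23,168,1,42,52,87,0,23,104,86,0,0
dBET57,24,0,19,12,0,5,7,17,17,0,0
dBET70,183,0,37,73,73,0,10,96,83,0,0
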