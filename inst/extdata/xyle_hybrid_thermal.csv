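enzyme,t50_c,tm_c,t_half_h
XylE,66.5,56.1,1.2
XylE-M3,71.2,60.8,NA
XylE-M3/M6,70.4,59.7,NA
XylE-M3/M9,70,58.1,NA
XylE-M3/M6/M9,69.5,57.2,NA
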