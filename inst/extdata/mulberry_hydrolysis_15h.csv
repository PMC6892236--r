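enzyme,y_both_umol_ml,y_cellulase_umol_ml,y_xylanase_umol_ml
XylE,3.6,3.2,0.28
XylE-M3/M6,3.9,3.2,0.45
XylE-M3/M6/M9,4.2,3.2,0.36
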