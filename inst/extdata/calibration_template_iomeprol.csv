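concentration,hu
0.02,NA
0.04,NA
0.06,NA
0.08,NA
0.10,NA
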