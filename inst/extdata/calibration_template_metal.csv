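concentration,hu
0.008,NA
0.016,NA
0.024,NA
0.032,NA
0.040,NA
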