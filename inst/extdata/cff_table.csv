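intensity,pcf_1_6,pcf_1_3,pcf_1_2,pcf_2_3,pcf_5_6
5340,58.17,51.83,59.17,52.5,47.00
534,48.0,50.0,50.83,48.7,46.17
53.4,34.67,36.17,36.33,35.2,32.67
5.34,23.17,27.2,5.67,25.2,20.83
0.53,17.17,19.0,17.83,19.0,15.67
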