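>SRSF5_toy SRSF5
A 1 12 1 14 1 1
C 1 1 1 1 1 13
G 1 1 13 1 1 1
T 13 1 1 0 13 1
>SRSF9_toy SRSF9
A 12 1 1 1 13
C 1 1 14 1 1
G 1 13 1 1 1
T 2 1 0 13 1
>PTBP1_toy PTBP1
A 0 1 0 1 1
C 2 13 1 13 1
G 1 1 1 1 1
T 13 1 14 1 13
>RBFOX1_toy RBFOX1
A 1 1 1 13 1 1
C 1 1 13 1 1 1
G 13 1 1 1 1 13
T 1 13 1 1 13 1
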