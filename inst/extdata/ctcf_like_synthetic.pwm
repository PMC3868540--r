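# PWM columns: A C G T
0.8269231	0.0576923	0.0576923	0.0576923
0.0576923	0.0576923	0.8269231	0.0576923
0.0576923	0.0576923	0.8269231	0.0576923
0.0576923	0.0576923	0.0576923	0.8269231
0.0576923	0.8269231	0.0576923	0.0576923
0.0576923	0.0576923	0.8269231	0.0576923
0.0576923	0.8269231	0.0576923	0.0576923
0.0576923	0.0576923	0.0576923	0.8269231
0.8269231	0.0576923	0.0576923	0.0576923
0.0576923	0.0576923	0.8269231	0.0576923
0.0576923	0.0576923	0.8269231	0.0576923
0.0576923	0.0576923	0.0576923	0.8269231
0.0576923	0.0576923	0.8269231	0.0576923
0.0576923	0.8269231	0.0576923	0.0576923
0.0576923	0.0576923	0.0576923	0.8269231
0.8269231	0.0576923	0.0576923	0.0576923
0.0576923	0.0576923	0.8269231	0.0576923
0.0576923	0.8269231	0.0576923	0.0576923
0.8269231	0.0576923	0.0576923	0.0576923
0.0576923	0.0576923	0.0576923	0.8269231
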