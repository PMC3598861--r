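-4.38	-3.53	-1.52	-0.20	-5.05	-2.61	-0.26	-4.69	-3.08	-7.33	-6.45	6.16	5.99	3.23	NaN	3.52	-4.56	3.34
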