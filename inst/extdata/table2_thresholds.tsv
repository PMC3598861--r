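48.31	7.31	15.89	-8.89	-4.70	-3.29	81.05	3.09	-33.86	29.12	-0.29	-74.57	6.77	-11.91	-33.86	13.93	-71.88	48.34
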