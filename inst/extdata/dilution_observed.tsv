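step	observed_vaf	detected
1	3.91	TRUE
2	2.78	TRUE
3	2.32	TRUE
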