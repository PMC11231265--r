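sample_id	variant	vaf_run1	vaf_run2	status_run1	status_run2
R1		78.86	80.25	positive	positive
R2		4.17	2.31	positive	positive
R3		60.77	56.14	positive	positive
R4				negative	negative
R5				negative	negative
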