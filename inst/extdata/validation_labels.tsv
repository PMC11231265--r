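sample_id	ngs	reference	note
V01	positive	positive	
V02	positive	positive	
V03	positive	positive	
V04	positive	positive	
V05	positive	positive	
V06	positive	positive	
V07	positive	positive	
V08	positive	negative	L298R at 3.85% VAF, below the Sanger detection limit
V09	negative	negative	
V10	negative	negative	
V11	negative	negative	
V12	negative	negative	
V13	negative	negative	
V14	negative	negative	
V15	negative	negative	
V16	negative	negative	
V17	negative	negative	
V18	negative	negative	
V19	negative	negative	
V20	negative	negative	
V21	negative	negative	
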