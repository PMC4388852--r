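# attractor specification for the helper T cell network
Th1: TBET=1, GATA3=0, RORGT=0, FOXP3=0
Th2: GATA3=1, TBET=0, RORGT=0, FOXP3=0
Th17: RORGT=1, TBET=0, GATA3=0, FOXP3=0
Treg: FOXP3=1, TBET=0, GATA3=0, RORGT=0
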