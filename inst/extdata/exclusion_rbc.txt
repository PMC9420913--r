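# Hemoglobin subunits: red-blood-cell gating set
HBB
HBE1
HBM
HBZ
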