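Lu AA21004
Brintellix
Vortioxetine Hydrobromide
Vortioxetine
Vortioxetine hbr
1-(2-(2,4-Dimethylphenylsulfanyl)phenyl)piperazine
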