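herb,n_compounds
AR,458
RR,118
CS,74
SM,108
CR,48
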