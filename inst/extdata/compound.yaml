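name: atractylodin
mw: 182.22
log_p: 3.8
pka: 10.0
fu: 0.1
rbp: 1.0
papp: 2.0e-05
solubility: 0.05
extract_fraction: 0.14
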