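lung: 1.0
heart: 1.0
brain: 1.5
muscle: 1.2
adipose: 1.0
skin: 2.0
bone: 1.0
kidney: 1.5
spleen: 1.0
gut: 1.3
liver: 2.5
rest: 1.5
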