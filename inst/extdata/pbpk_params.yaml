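ka: 1.54
f_abs: 0.374
cl_int_hepatic: 4483.0
kp_scalar: 1.11
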