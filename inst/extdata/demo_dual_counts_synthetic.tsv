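condition	n_dual	n_A_only	n_B_only
BICD2_snap	390	305	305
Egl_snap	370	315	315
hairy_rna	140	430	430
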