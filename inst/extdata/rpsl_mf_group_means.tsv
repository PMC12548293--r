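group	mean_mf_x1e5
wt_control	2.37
msh2ko_control	28.88
msh2ko_kbro3	58.26
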