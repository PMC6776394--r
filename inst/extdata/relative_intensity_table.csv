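strain,relative_mruby2_intensity
Ady4,1
Bnr2,11.3
Cnm67,1.9
Cmd1,3.7
Spo74,6.3
Tub4,3.6
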