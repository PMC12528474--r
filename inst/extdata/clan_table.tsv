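name	clan
VH1	1
VH2	2
VH3	3
VH5	3
VH6	1
VH10	3
VH14	2
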