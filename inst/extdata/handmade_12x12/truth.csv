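anchor_row,anchor_col,intended_class
2,11,Riparian
4,4,NRShw
6,4,NRMid
8,4,NRDeep
10,5,Unclassified
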